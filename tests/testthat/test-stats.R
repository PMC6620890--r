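# Independent oracles: the margin-formula chi-square and the O(n^2) pairwise
# Mann-Whitney count, used to cross-check the package implementations.

chi_square_oracle <- function(m) {
  n <- sum(m)
  e <- outer(rowSums(m), colSums(m)) / n
  sum((m - e)^2 / e)
}

mwu_oracle <- function(x, y) {
  u <- 0
  for (xi in x) for (yi in y) {
    u <- u + (xi > yi) + 0.5 * (xi == yi)
  }
  u
}

test_that("chi_square matches hand examples and validates input", {
  res <- chi_square(matrix(10, 2, 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$df, 1)
  expect_equal(res$p_value, 1)
  expect_error(chi_square(matrix(c(1, 0, 2, 0), 2)), "zero margin")
  expect_error(chi_square(matrix(1:4, 1)), ">= 2x2")
})

test_that("chi_square equals the margin-formula oracle and is permutation invariant", {
  set.seed(5)
  for (i in 1:25) {
    m <- matrix(rpois(6, 20) + 1, 2, 3)
    res <- chi_square(m)
    expect_equal(res$statistic, chi_square_oracle(m), tolerance = 1e-10)
    expect_equal(res$df, 2)
    perm <- m[sample(2), sample(3)]
    expect_equal(chi_square(perm)$statistic, res$statistic,
                 tolerance = 1e-12)
  }
})

test_that("welch_t handles summaries and raw vectors equivalently", {
  s <- summary_stats(5, 1, 30)
  expect_equal(welch_t(s, s)$statistic, 0)
  set.seed(8)
  x <- rnorm(40, 1)
  y <- rnorm(35, 0.2, 1.5)
  res <- welch_t(x, y)
  ref <- stats::t.test(x, y)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(res$df, unname(ref$parameter), tolerance = 1e-9)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-9)
  # summary path identical to raw path
  res2 <- welch_t(summary_stats(mean(x), sd(x), length(x)),
                  summary_stats(mean(y), sd(y), length(y)))
  expect_equal(res2$statistic, res$statistic, tolerance = 1e-12)
  # antisymmetry
  res3 <- welch_t(y, x)
  expect_equal(res3$statistic, -res$statistic)
  expect_equal(res3$p_value, res$p_value)
  expect_error(welch_t(summary_stats(1, 0, 5), summary_stats(1, 0, 5)),
               "zero pooled variance")
})

test_that("mann_whitney_u matches the pairwise oracle and wilcox.test", {
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4))$statistic, 0)
  expect_equal(mann_whitney_u(1, 1)$statistic, 0.5)
  set.seed(13)
  for (i in 1:20) {
    x <- sample(0:5, 8, replace = TRUE)
    y <- sample(0:5, 9, replace = TRUE)
    res <- mann_whitney_u(x, y)
    expect_equal(res$statistic, mwu_oracle(x, y), tolerance = 1e-12)
    # U_x + U_y = n_x * n_y
    expect_equal(res$statistic + mann_whitney_u(y, x)$statistic,
                 length(x) * length(y))
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = FALSE))
    expect_equal(res$statistic, unname(ref$statistic))
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-9)
  }
  # exact path (no ties, small samples) agrees with exact wilcox.test
  for (i in 1:10) {
    x <- rnorm(7)
    y <- rnorm(8)
    res <- mann_whitney_u(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("gg_epsilon is exactly 1 at two levels and near 1 under sphericity", {
  set.seed(21)
  d2 <- matrix(rnorm(40), 20, 2)
  g2 <- rep(c("a", "b"), each = 10)
  expect_equal(gg_epsilon(d2, g2), 1, tolerance = 1e-12)
  # compound-symmetric data: shared random intercept + iid noise
  n <- 120
  L <- 6
  d <- matrix(rnorm(n * L), n, L) + rnorm(n, sd = 2)
  g <- rep(c("a", "b"), each = n / 2)
  expect_gte(gg_epsilon(d, g), 0.95)
  eps <- gg_epsilon(matrix(rnorm(60 * 4), 60, 4) %*% diag(c(4, 2, 1, 0.2)),
                    rep(c("a", "b"), each = 30))
  expect_lt(eps, 1)
  expect_gte(eps, 1 / 3)
})

test_that("mixed_anova_gg agrees with car's Greenhouse-Geisser correction", {
  set.seed(31)
  n <- 16
  L <- 4
  d <- matrix(rnorm(n * L), n, L) %*% diag(c(3, 1.5, 1, 0.5))
  d[9:16, 2] <- d[9:16, 2] + 1.5
  g <- factor(rep(c("a", "b"), each = 8))
  res <- mixed_anova_gg(d, g)

  # car's type-3 tests need sum-to-zero contrasts
  withr::local_options(contrasts = c("contr.sum", "contr.poly"))
  idata <- data.frame(level = factor(seq_len(L)))
  mlm <- stats::lm(d ~ g)
  ca <- car::Anova(mlm, idata = idata, idesign = ~level, type = 3)
  cs <- summary(ca)
  expect_equal(res$epsilon, unname(cs$pval.adjustments["level", "GG eps"]),
               tolerance = 1e-8)
  expect_equal(res$level$p_value,
               unname(cs$pval.adjustments["level", "Pr(>F[GG])"]),
               tolerance = 1e-8)
  expect_equal(res$interaction$p_value,
               unname(cs$pval.adjustments["g:level", "Pr(>F[GG])"]),
               tolerance = 1e-8)
  expect_equal(res$group$p_value,
               cs$univariate.tests["g", "Pr(>F)"], tolerance = 1e-8)
})

test_that("mixed_anova_gg interaction is well calibrated under the null", {
  set.seed(45)
  n_sig <- 0
  reps <- 20
  for (i in seq_len(reps)) {
    d <- matrix(rnorm(24 * 5), 24, 5) + rnorm(24)
    g <- rep(c("a", "b"), each = 12)
    res <- mixed_anova_gg(d, g)
    if (res$interaction$p_value < 0.05) n_sig <- n_sig + 1
  }
  expect_lte(n_sig, reps * 0.1)
  expect_error(mixed_anova_gg(matrix(c(1, NA, 2, 3), 2, 2), c("a", "b")),
               "incomplete")
  expect_error(mixed_anova_gg(matrix(rnorm(8), 4, 2), c("a", "a", "a", "b")),
               ">= 2 subjects")
})

test_that("run_comparisons emits the full 22-test battery", {
  st <- small_study()
  cmp <- run_comparisons(st$corpora)
  expect_equal(nrow(cmp), 22)
  expect_setequal(unique(cmp$feature),
                  c("pos", "pronouns", "emotions", "polarity_binary",
                    "polarity_graded", "negations", "characters",
                    "temporal_hour", "temporal_weekday"))
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
  expect_true(all(cmp$p_bonferroni >= cmp$p_value))
  expect_equal(sum(cmp$test == "anova_interaction_gg"), 2)
  # epsilon only reported for the repeated-measures tests, in (0, 1]
  eps <- cmp$epsilon[!is.na(cmp$epsilon)]
  expect_length(eps, 2)
  expect_true(all(eps > 0 & eps <= 1))
})

test_that("identical datasets give null chi-square statistics", {
  st <- small_study()
  cp <- st$corpora$control
  trio <- list(control = cp,
               depressive_users = corpus("depressive_users", cp$tweets,
                                         cp$profiles),
               depressive_tweets = corpus("depressive_tweets", cp$tweets,
                                          cp$profiles))
  cmp <- run_comparisons(trio)
  chis <- cmp[cmp$test == "chi_square", ]
  expect_true(all(abs(chis$statistic) < 1e-9))
  welch <- cmp[cmp$test == "welch_t", ]
  expect_true(all(abs(welch$statistic) < 1e-9))
})
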