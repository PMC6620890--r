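# Statistical comparison layer: Pearson chi-square on contingency tables,
# Welch t from raw values or printed summaries, Mann-Whitney U, and
# split-plot repeated-measures ANOVA with Greenhouse-Geisser correction.

#' A test-result record
#'
#' @param statistic Test statistic.
#' @param df Degrees of freedom (length 2 for F; `NA` where not defined,
#'   e.g. Mann-Whitney U).
#' @param p_value Two-sided p-value in \[0, 1\].
#' @param method Short method label.
#' @param epsilon Optional Greenhouse-Geisser epsilon in (0, 1\].
#' @return A list of class `stat_result`.
#' @export
stat_result <- function(statistic, df, p_value, method,
                        epsilon = NA_real_) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), method = method,
                 epsilon = unname(epsilon)),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat("<stat_result>", x$method, "| statistic:",
      format(x$statistic, digits = 6),
      "| df:", paste(format(x$df, digits = 5), collapse = ", "),
      if (!is.na(x$epsilon)) paste("| GG epsilon:",
                                   format(x$epsilon, digits = 4)) else "",
      "| p:", format.pval(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' Summary statistics of a sample
#'
#' Container for tests computed from printed summaries (mean, SD, n) rather
#' than raw values.
#'
#' @param mean,sd,n Sample mean, standard deviation (>= 0) and size (>= 2
#'   for variance-based tests).
#' @return A list of class `summary_stats`.
#' @export
summary_stats <- function(mean, sd, n) {
  stopifnot(sd >= 0, n >= 1)
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "summary_stats")
}

as_summary_stats <- function(x) {
  if (inherits(x, "summary_stats")) return(x)
  stopifnot(is.numeric(x), length(x) >= 2)
  summary_stats(mean(x), sd(x), length(x))
}

#' Pearson chi-square test on a contingency table
#'
#' Uncorrected Pearson chi-square (no continuity correction): expected counts
#' from the row/column margins, statistic = sum (O-E)^2 / E, df =
#' (rows-1)(cols-1), upper-tail p.
#'
#' @param table Matrix of non-negative counts, at least 2x2, with no all-zero
#'   row or column.
#' @return A `stat_result`.
#' @export
chi_square <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) < 2 || ncol(m) < 2) abort("contingency table must be >= 2x2")
  if (any(m < 0)) abort("contingency table counts must be non-negative")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("contingency table has an all-zero row or column (zero margin)")
  }
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  stat_result(res$statistic, res$parameter, res$p.value, "chi_square")
}

#' Welch two-sample t test
#'
#' Accepts raw numeric vectors or [summary_stats()] on either side, so the
#' printed mean/SD/n triples of a publication can be tested directly.
#' Welch-Satterthwaite degrees of freedom, two-sided p.
#'
#' @param a,b Numeric vector or `summary_stats`.
#' @return A `stat_result`.
#' @export
welch_t <- function(a, b) {
  a <- as_summary_stats(a)
  b <- as_summary_stats(b)
  stopifnot(a$n >= 2, b$n >= 2)
  va <- a$sd^2 / a$n
  vb <- b$sd^2 / b$n
  if (va + vb == 0) abort("zero pooled variance: t undefined")
  t <- (a$mean - b$mean) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  stat_result(t, df, 2 * pt(-abs(t), df), "welch_t")
}

#' Mann-Whitney U test
#'
#' U for the first sample from midrank rank sums. Exact p (via the
#' Wilcoxon distribution) when `n_x * n_y <= exact_max` and there are no
#' ties; otherwise normal approximation with tie-corrected variance.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact_max Product-size cutoff for exact enumeration, default 400.
#' @return A `stat_result` (df is `NA`; not defined for U).
#' @export
mann_whitney_u <- function(x, y, exact_max = 400) {
  stopifnot(length(x) > 0, length(y) > 0)
  nx <- length(x)
  ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- table(c(x, y))
  has_ties <- any(ties > 1)
  if (!has_ties && nx * ny <= exact_max) {
    p <- if (u > nx * ny / 2) {
      2 * stats::pwilcox(u - 1, nx, ny, lower.tail = FALSE)
    } else {
      2 * stats::pwilcox(u, nx, ny)
    }
    p <- min(1, p)
  } else {
    n <- nx + ny
    mu <- nx * ny / 2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
    if (sigma2 == 0) {
      p <- 1
    } else {
      z <- (u - mu) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
  }
  stat_result(u, NA_real_, p, "mann_whitney_u")
}

#' Greenhouse-Geisser epsilon
#'
#' Computed from the eigenvalues of the double-centered pooled within-group
#' covariance matrix of the repeated measures: epsilon = (sum lambda)^2 /
#' ((L-1) * sum lambda^2), which equals 1 under sphericity and reaches its
#' lower bound 1/(L-1) at maximal violation.
#'
#' @param data Numeric matrix, subjects x L levels.
#' @param group Factor of group labels per subject.
#' @return Epsilon in (1/(L-1), 1\].
#' @export
gg_epsilon <- function(data, group) {
  data <- as.matrix(data)
  group <- as.factor(group)
  L <- ncol(data)
  n_g <- table(group)
  pooled <- Reduce(`+`, lapply(levels(group), function(g) {
    xg <- data[group == g, , drop = FALSE]
    (nrow(xg) - 1) * stats::cov(xg)
  })) / (nrow(data) - nlevels(group))
  cm <- colMeans(pooled)
  centered <- pooled - outer(rep(1, L), cm) - outer(cm, rep(1, L)) +
    mean(pooled)
  sum(diag(centered))^2 / ((L - 1) * sum(centered^2))
}

#' Split-plot repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' One between-subject factor (group) and one within-subject factor with L
#' levels (e.g. the 24 hour bins of an activity profile). The within-level
#' and group-by-level F tests are evaluated on Greenhouse-Geisser shrunk
#' degrees of freedom (eps*(L-1), eps*(L-1)*(N-g)); the between-group test
#' needs no sphericity correction.
#'
#' @param data Numeric matrix, subjects x L levels (complete; `NA` is an
#'   error).
#' @param group Group label per subject (>= 2 subjects per group).
#' @return List of `stat_result`s: `group`, `level`, `interaction` (the
#'   headline effect for two-population profile comparisons), plus `epsilon`.
#' @export
mixed_anova_gg <- function(data, group) {
  data <- as.matrix(data)
  if (anyNA(data)) abort("incomplete subject vectors in repeated measures")
  group <- as.factor(group)
  L <- ncol(data)
  N <- nrow(data)
  g <- nlevels(group)
  if (L < 2) abort("need at least 2 within-subject levels")
  if (length(group) != N) abort("one group label per subject required")
  if (any(table(group) < 2)) abort("need >= 2 subjects per group")
  eps <- gg_epsilon(data, group)

  long <- tibble(
    y = as.vector(data),
    subject = factor(rep(seq_len(N), times = L)),
    level = factor(rep(seq_len(L), each = N)),
    group = rep(group, times = L)
  )
  fit <- aov(y ~ group * level + Error(subject), data = long)
  s <- summary(fit)
  between <- s[["Error: subject"]][[1]]
  within <- s[["Error: Within"]][[1]]
  rn_b <- trimws(rownames(between))
  rn_w <- trimws(rownames(within))
  f_group <- between[rn_b == "group", "F value"]
  df_group <- c(between[rn_b == "group", "Df"],
                between[rn_b == "Residuals", "Df"])
  p_group <- between[rn_b == "group", "Pr(>F)"]
  f_level <- within[rn_w == "level", "F value"]
  f_int <- within[rn_w == "group:level", "F value"]
  df_err <- within[rn_w == "Residuals", "Df"]
  df_level <- c(within[rn_w == "level", "Df"], df_err)
  df_int <- c(within[rn_w == "group:level", "Df"], df_err)

  gg_p <- function(f, df) pf(f, eps * df[1], eps * df[2], lower.tail = FALSE)
  list(
    group = stat_result(f_group, df_group, p_group, "anova_between"),
    level = stat_result(f_level, eps * df_level, gg_p(f_level, df_level),
                        "anova_within_gg", epsilon = eps),
    interaction = stat_result(f_int, eps * df_int, gg_p(f_int, df_int),
                              "anova_interaction_gg", epsilon = eps),
    epsilon = eps
  )
}

result_row <- function(comparison, feature, res) {
  tibble(comparison = comparison, feature = feature, test = res$method,
         statistic = res$statistic,
         df1 = res$df[1], df2 = if (length(res$df) > 1) res$df[2]
                                else NA_real_,
         epsilon = res$epsilon, p_value = res$p_value)
}

# Per-corpus feature bundle consumed by run_comparisons.
corpus_features <- function(corpus, tagger = dict_tagger(),
                            negations = negation_lexicon(),
                            emotions = emotion_lexicon_synthetic(),
                            pol_bin = polarity_binary_synthetic(),
                            pol_grad = polarity_graded_synthetic(),
                            t_mod = 0.5) {
  stopifnot(inherits(corpus, "tweet_corpus"))
  list(
    label = corpus$label,
    pos = pos_profile(corpus, tagger),
    pronouns = pronoun_profile(corpus, tagger),
    emotions = emotion_profile(corpus, emotions),
    chars = char_count(corpus$tweets$text),
    negation_counts = negation_counts(corpus, negations),
    polarity_binary = polarity_labels(corpus, "binary", lex = pol_bin),
    polarity_graded = polarity_labels(corpus, "graded", lex = pol_grad,
                                      t_mod = t_mod)
  )
}

label_counts <- function(labels, levels) {
  vapply(levels, function(l) sum(labels == l), integer(1))
}

#' Run the full between-dataset comparison battery
#'
#' Emits one test per dataset contrast of the study design: chi-square on
#' POS, pronoun-person, emotion, binary-polarity and graded-polarity count
#' tables for all three dataset pairs; Welch t on per-tweet character counts
#' (control vs depressive-users, depressive-users vs depressive-tweets);
#' Mann-Whitney U on per-tweet negation counts for the three pairs; and
#' Greenhouse-Geisser repeated-measures ANOVA (group-by-bin interaction as
#' the headline effect) on the hourly and weekday activity profiles of
#' control vs depressive users. 22 comparisons in total. No multiple-testing
#' adjustment is applied to `p_value`; a Bonferroni column is emitted for
#' transparency.
#'
#' @param corpora Named list of the three `tweet_corpus` objects (`control`,
#'   `depressive_users`, `depressive_tweets`).
#' @param tagger A `tv_tagger`.
#' @param t_mod Graded polarity threshold.
#' @param ... Lexicon overrides passed to the feature extractor
#'   (`negations`, `emotions`, `pol_bin`, `pol_grad`).
#' @return Tibble with columns comparison, feature, test, statistic, df1,
#'   df2, epsilon, p_value, p_bonferroni.
#' @export
run_comparisons <- function(corpora, tagger = dict_tagger(), t_mod = 0.5,
                            ...) {
  stopifnot(all(c("control", "depressive_users", "depressive_tweets") %in%
                  names(corpora)))
  feats <- lapply(corpora[c("control", "depressive_users",
                            "depressive_tweets")],
                  corpus_features, tagger = tagger, t_mod = t_mod, ...)
  pairs <- list(c("control", "depressive_users"),
                c("control", "depressive_tweets"),
                c("depressive_users", "depressive_tweets"))
  pair_name <- vapply(pairs, paste, "", collapse = " vs ")

  rows <- list()
  add <- function(row) rows[[length(rows) + 1]] <<- row
  # categories absent from both datasets carry no information and would make
  # the Pearson statistic undefined (zero margin); they are dropped
  chi_nonzero <- function(m) chi_square(m[rowSums(m) > 0, , drop = FALSE])

  for (i in seq_along(pairs)) {
    a <- feats[[pairs[[i]][1]]]
    b <- feats[[pairs[[i]][2]]]
    add(result_row(pair_name[i], "pos",
                   chi_nonzero(cbind(a$pos$n, b$pos$n))))
    add(result_row(pair_name[i], "pronouns",
                   chi_nonzero(cbind(a$pronouns$n, b$pronouns$n))))
    add(result_row(pair_name[i], "emotions",
                   chi_nonzero(cbind(a$emotions$n, b$emotions$n))))
    add(result_row(pair_name[i], "polarity_binary",
                   chi_nonzero(cbind(
                     label_counts(a$polarity_binary,
                                  c("positive", "negative")),
                     label_counts(b$polarity_binary,
                                  c("positive", "negative"))))))
    grad_lvls <- c("positive", "moderate_positive", "moderate_negative",
                   "negative")
    add(result_row(pair_name[i], "polarity_graded",
                   chi_nonzero(cbind(label_counts(a$polarity_graded,
                                                 grad_lvls),
                                    label_counts(b$polarity_graded,
                                                 grad_lvls)))))
    add(result_row(pair_name[i], "negations",
                   mann_whitney_u(a$negation_counts, b$negation_counts)))
  }
  add(result_row(pair_name[1], "characters",
                 welch_t(feats$control$chars,
                         feats$depressive_users$chars)))
  add(result_row(pair_name[3], "characters",
                 welch_t(feats$depressive_users$chars,
                         feats$depressive_tweets$chars)))

  for (by in c("hour", "weekday")) {
    profs <- lapply(corpora[c("control", "depressive_users")], function(cp) {
      if (by == "hour") hourly_profile(cp) else weekday_profile(cp)
    })
    data <- rbind(profs$control$per_user, profs$depressive_users$per_user)
    grp <- rep(c("control", "depressive_users"),
               c(profs$control$n_users, profs$depressive_users$n_users))
    res <- mixed_anova_gg(data, grp)
    add(result_row(pair_name[1], paste0("temporal_", by),
                   res$interaction))
  }

  out <- bind_rows(rows)
  out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  out
}
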