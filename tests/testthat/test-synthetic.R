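test_that("vocabulary bank is deterministic, disjoint and lexicon-covering", {
  b1 <- build_vocabulary(1)
  b2 <- build_vocabulary(99)
  expect_identical(b1$tagged, b2$tagged)
  words <- unlist(b1$inventories, use.names = FALSE)
  expect_equal(anyDuplicated(words), 0)
  # every lexicon term resolves to exactly one POS inventory
  lex_terms <- c(b1$negations, b1$emotions$term, b1$polarity_binary$term,
                 b1$polarity_graded$term, b1$keywords$form,
                 depr_derivations())
  expect_true(all(lex_terms %in% b1$tagged$word))
  # plain inventories carry no lexicon annotation
  plain <- unlist(b1$plain, use.names = FALSE)
  annotated <- c(b1$negations, b1$emotions$term, b1$polarity_binary$term,
                 b1$polarity_graded$term, b1$keywords$form)
  expect_length(intersect(plain, annotated), 0)
})

test_that("expand_keywords expands /a entries to both gendered forms", {
  out <- expand_keywords(c("agobiado/a", "triste"))
  expect_equal(out$form, c("agobiado", "agobiada", "triste"))
  expect_equal(out$canonical, c("agobiado/a", "agobiado/a", "triste"))
})

test_that("generate_user honors degenerate spec settings", {
  bank <- build_vocabulary()
  spec3 <- population_spec(hourly_weights = c(rep(0, 3), 1, rep(0, 20)),
                           negation_rate = 0, retweet_fraction = 0,
                           n_users = 1)
  u <- generate_user(spec3, bank, 1, seed = 5)
  lt <- local_time(u$tweets)
  expect_true(all(lt$hour == 3))
  expect_true(all(u$truth$neg_injected == 0))
  cp <- corpus("control", u$tweets, u$profile)
  expect_equal(sum(negation_counts(cp)), 0)
  # determinism
  u2 <- generate_user(spec3, bank, 1, seed = 5)
  expect_identical(u$tweets, u2$tweets)
  u3 <- generate_user(spec3, bank, 2, seed = 5)
  expect_false(identical(u$tweets$text, u3$tweets$text))
})

test_that("negation injection recovers its Poisson rate", {
  bank <- build_vocabulary()
  spec <- population_spec(n_users = 4, tweets_per_user = c(500, 100),
                          negation_rate = 0.49, retweet_fraction = 0)
  users <- lapply(1:4, function(i) generate_user(spec, bank, i, seed = 12))
  tweets <- dplyr::bind_rows(lapply(users, `[[`, "tweets"))
  cp <- corpus("control", tweets)
  m <- mean(negation_counts(cp))
  n <- nrow(tweets)
  se <- sqrt(0.49 / n)
  expect_lt(abs(m - 0.49), 3 * se)
})

test_that("generate_study assembles disjoint corpora with conserved counts", {
  st <- small_study()
  ids <- lapply(st$corpora, function(cp) cp$tweets$tweet_id)
  expect_length(Reduce(intersect, ids), 0)
  truth <- st$truth$tweets
  # conservation: depressive non-retweets = users dataset + flagged
  dep_nonrt <- sum(truth$population == "depressive" & !truth$retweet)
  expect_equal(dep_nonrt,
               nrow(st$corpora$depressive_users$tweets) +
                 nrow(st$corpora$depressive_tweets$tweets))
  # flagged tweets oversample depression keywords
  flagged_kw <- vapply(st$corpora$depressive_tweets$tweets$text,
                       function(t) length(match_keywords(t)) > 0, logical(1))
  expect_gt(mean(flagged_kw), 0.5)
})

test_that("flagged_fraction 0 yields an empty depressive-tweets corpus", {
  st0 <- generate_study(control_spec(n_users = 2, tweets_per_user = c(20, 5)),
                        depressive_spec(n_users = 2,
                                        tweets_per_user = c(20, 5)),
                        flagged_fraction = 0, seed = 3)
  expect_equal(nrow(st0$corpora$depressive_tweets$tweets), 0)
})

test_that("generate_study writes byte-identical files under the same seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  args <- list(control = control_spec(n_users = 3, tweets_per_user = c(25, 5)),
               depressive = depressive_spec(n_users = 3,
                                            tweets_per_user = c(25, 5)),
               seed = 17)
  do.call(generate_study, c(args, list(out_dir = d1)))
  do.call(generate_study, c(args, list(out_dir = d2)))
  for (f in c("control.jsonl", "depressive_users.jsonl",
              "depressive_tweets.jsonl", "truth.json")) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE),
                     label = f)
  }
})

test_that("screening recovers the depressive population from the synthetic study", {
  st <- small_study()
  profiles <- dplyr::bind_rows(st$corpora$control$profiles,
                               st$corpora$depressive_users$profiles)
  flagged_per_user <- table(st$corpora$depressive_tweets$tweets$user_id)
  counts <- stats::setNames(as.integer(flagged_per_user),
                            names(flagged_per_user))
  dec <- screen_users(profiles, counts, threshold = 10)
  depr_users <- st$corpora$depressive_users$profiles$user_id
  # profile matching recovers exactly the depressive population
  expect_setequal(dec$user_id[dec$profile_matched], depr_users)
  # retention = profile match AND >= 10 flagged, exactly
  expected <- dec$profile_matched & dec$flagged_tweet_count >= 10
  expect_equal(dec$retained, expected)
  expect_true(any(dec$retained))
})

test_that("population presets encode the study contrasts", {
  cs <- control_spec()
  ds <- depressive_spec()
  dts <- depressive_tweets_spec()
  expect_gt(cs$pos_mixture[["noun"]], ds$pos_mixture[["noun"]])
  expect_lt(cs$pos_mixture[["verb"]], ds$pos_mixture[["verb"]])
  expect_equal(unname(cs$pronoun_mixture[["1S"]]), 0.3837)
  expect_equal(unname(dts$pronoun_mixture[["1S"]]), 0.80)
  expect_equal(cs$negation_rate, 0.28)
  expect_equal(ds$negation_rate, 0.49)
  expect_equal(dts$negation_rate, 0.67)
  # night hours (23-6) carry more relative weight for the depressive spec
  night <- c(24, 1:7)
  expect_gt(sum(ds$hourly_weights[night]), sum(cs$hourly_weights[night]))
  # weekend dip only in the control spec
  expect_lt(mean(cs$weekday_weights[6:7]), mean(cs$weekday_weights[1:5]))
  expect_gte(mean(ds$weekday_weights[6:7]), mean(ds$weekday_weights[1:5]))
})
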