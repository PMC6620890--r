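test_that("detect_negations counts listed cues case-insensitively", {
  expect_equal(detect_negations(tokenize_tweet("no quiero nada")), 2L)
  expect_equal(detect_negations(tokenize_tweet("hola")), 0L)
  expect_equal(detect_negations(tokenize_tweet("Nunca jamás")), 2L)
  # the bundled list
  lex <- negation_lexicon()
  expect_setequal(lex$table$term,
                  c("no", "nada", "nadie", "nunca", "jamás", "ni",
                    "ningún", "ninguno", "ninguna", "tampoco", "sin"))
})

test_that("negation_counts matches per-tweet detect_negations and the truth", {
  st <- small_study()
  cp <- st$corpora$depressive_users
  counts <- negation_counts(cp)
  per_tweet <- vapply(cp$tweets$text[1:50], function(t) {
    detect_negations(tokenize_tweet(t))
  }, integer(1))
  expect_equal(counts[1:50], unname(per_tweet))
  truth <- st$truth$tweets
  m <- match(cp$tweets$tweet_id, truth$tweet_id)
  expect_equal(counts, truth$neg_injected[m])
})

test_that("score_emotions increments per matched entry, multi-emotion terms stack", {
  lex <- lexicon(tibble::tibble(term = c("triste", "triste", "raro"),
                                emotion = c("sadness", "fear", "surprise")),
                 "emotion")
  s <- score_emotions(tokenize_tweet("triste triste raro"), lex)
  expect_equal(s[["sadness"]], 2L)
  expect_equal(s[["fear"]], 2L)
  expect_equal(s[["surprise"]], 1L)
  expect_equal(sum(score_emotions(tokenize_tweet("algo raro"), lex)), 1L)
  expect_equal(sum(score_emotions(tokenize_tweet("nada aqui"), lex)), 0L)
})

test_that("emotion_profile equals the sum of tweet-level scores", {
  st <- small_study()
  cp <- st$corpora$control
  prof <- emotion_profile(cp)
  manual <- Reduce(`+`, lapply(cp$tweets$text[1:80], function(t) {
    score_emotions(tokenize_tweet(t))
  }))
  small <- corpus("control", cp$tweets[1:80, ], cp$profiles)
  prof80 <- emotion_profile(small)
  expect_equal(stats::setNames(prof80$n, prof80$emotion), manual)
  expect_equal(sum(prof$share_pct), 100, tolerance = 1e-9)
})

test_that("binary polarity follows the hit-majority rule with configurable ties", {
  lex <- lexicon(tibble::tibble(term = c("bueno", "genial", "malo"),
                                value = c(1, 1, -1)), "polarity_binary")
  expect_equal(score_polarity_binary(tokenize_tweet("día bueno"), lex),
               "positive")
  expect_equal(score_polarity_binary(tokenize_tweet("sin pistas"), lex),
               "none")
  expect_equal(score_polarity_binary(tokenize_tweet("bueno genial malo"),
                                     lex), "positive")
  expect_equal(score_polarity_binary(tokenize_tweet("bueno malo"), lex),
               "none")
  expect_equal(score_polarity_binary(tokenize_tweet("bueno malo"), lex,
                                     tie = "negative"), "negative")
})

test_that("binary polarity flips under global sign inversion of the lexicon", {
  st <- small_study()
  texts <- st$corpora$control$tweets$text[1:100]
  lex <- polarity_binary_synthetic()
  flipped <- lexicon(dplyr::mutate(lex$table, value = -value),
                     "polarity_binary")
  for (t in texts[c(1, 10, 25, 50, 99)]) {
    a <- score_polarity_binary(tokenize_tweet(t), lex)
    b <- score_polarity_binary(tokenize_tweet(t), flipped)
    expected <- c(positive = "negative", negative = "positive",
                  none = "none")[[a]]
    expect_equal(b, expected)
  }
})

test_that("graded polarity thresholds the mean matched value", {
  lex <- lexicon(tibble::tibble(term = c("sublime", "decente", "soso",
                                         "infame"),
                                value = c(1, 0.4, -0.4, -0.6)),
                 "polarity_graded")
  tok <- tokenize_tweet
  expect_equal(score_polarity_graded(tok("sublime"), lex), "positive")
  expect_equal(score_polarity_graded(tok("decente"), lex),
               "moderate_positive")
  expect_equal(score_polarity_graded(tok("soso"), lex), "moderate_negative")
  expect_equal(score_polarity_graded(tok("infame"), lex), "negative")
  expect_equal(score_polarity_graded(tok("nada"), lex), "none")
  # exact cancellation is none
  expect_equal(score_polarity_graded(tok("decente soso"), lex), "none")
  # threshold boundary: s == t_mod is strong
  expect_equal(score_polarity_graded(tok("sublime soso soso"), lex,
                                     t_mod = 0.0667), "moderate_positive")
  expect_error(score_polarity_graded(tok("x"), lex, t_mod = 1.5))
})

test_that("polarity_labels agrees with the per-tweet scorers", {
  st <- small_study()
  cp <- st$corpora$depressive_users
  sub <- corpus("depressive_users", cp$tweets[1:120, ], cp$profiles)
  for (scheme in c("binary", "graded")) {
    labels <- polarity_labels(sub, scheme)
    fn <- if (scheme == "binary") score_polarity_binary
          else score_polarity_graded
    manual <- vapply(sub$tweets$text, function(t) fn(tokenize_tweet(t)),
                     character(1))
    expect_equal(labels, unname(manual), label = scheme)
  }
})

test_that("polarity_prevalence reports prevalence and conditional shares", {
  st <- small_study()
  cp <- st$corpora$control
  pv <- polarity_prevalence(cp, "binary")
  labels <- polarity_labels(cp, "binary")
  expect_equal(pv$prevalence, mean(labels != "none"))
  expect_equal(sum(pv$shares$n), pv$n_polar)
  expect_equal(sum(pv$shares$share_pct), 100, tolerance = 1e-9)
  # all-none corpus
  none <- mini_corpus(c("casa grande", "ver cielo"))
  pv0 <- polarity_prevalence(none, "binary")
  expect_equal(pv0$prevalence, 0)
  expect_equal(nrow(pv0$shares), 0)
})

test_that("lexicon constructor validates annotations", {
  expect_error(lexicon(tibble::tibble(term = "x", value = 0.5),
                       "polarity_binary"), "binary")
  expect_error(lexicon(tibble::tibble(term = "x", value = 2),
                       "polarity_graded"), "graded")
  expect_error(lexicon(tibble::tibble(term = c("a", "a"),
                                      value = c(1, -1)),
                       "polarity_binary"), "duplicate")
  expect_error(lexicon(tibble::tibble(term = "x", emotion = "boredom"),
                       "emotion"), "unknown emotion")
})
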