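test_that("match_keywords finds canonical entries at token level", {
  expect_equal(match_keywords("estoy muy triste hoy"), "triste")
  expect_equal(match_keywords("hoy hace sol"), character())
  expect_setequal(match_keywords("agobiada y cansada"),
                  c("agobiado/a", "cansado/a"))
  # case and punctuation invariance
  expect_equal(match_keywords("TRISTE, triste... (triste)"), "triste")
  # accent-sensitive: unaccented keyword spelling does not match
  expect_equal(match_keywords("depresion"), character())
  expect_equal(match_keywords("tengo depresión"), "depresión")
  # substring of a longer token never matches
  expect_equal(match_keywords("tristeza"), character())
  expect_error(match_keywords("hola", keywords = character()), "empty")
})

test_that("profile_mentions_depr matches the derivation set with the accent relaxation", {
  r <- profile_mentions_depr("Paciente psiquiátrico con depresión crónica")
  expect_true(r$matched)
  expect_equal(r$terms, "depresión")
  expect_false(profile_mentions_depr("")$matched)
  expect_false(profile_mentions_depr(NA_character_)$matched)
  r2 <- profile_mentions_depr("DEPRE total")
  expect_true(r2$matched)
  expect_equal(r2$terms, "depre")
  # unaccented depresion matches via the documented relaxation only
  expect_true(profile_mentions_depr("mi depresion diaria")$matched)
  expect_false(profile_mentions_depr("mi depresion diaria",
                                     accent_relax = FALSE)$matched)
  # token-level: derivation inside a longer word does not count
  expect_false(profile_mentions_depr("antidepresivos")$matched)
})

test_that("retention rule enforces profile match AND flagged-count threshold", {
  expect_true(retain_depressive_user("u", TRUE, 10)$retained)
  expect_false(retain_depressive_user("u", TRUE, 9)$retained)
  expect_false(retain_depressive_user("u", FALSE, 50)$retained)
  expect_error(retain_depressive_user("u", TRUE, 10, threshold = 0))
})

test_that("raising the retention threshold never grows the retained set", {
  set.seed(11)
  profiles <- tibble::tibble(
    user_id = sprintf("u%02d", 1:30),
    description = sample(c("con depresión", "me gusta el cine"), 30, TRUE)
  )
  counts <- stats::setNames(sample(0:25, 30, TRUE), profiles$user_id)
  prev <- NULL
  for (thr in c(1, 5, 10, 20)) {
    dec <- screen_users(profiles, counts, threshold = thr)
    retained <- dec$user_id[dec$retained]
    if (!is.null(prev)) expect_true(all(retained %in% prev))
    expect_true(all(dec$flagged_tweet_count[dec$retained] >= thr))
    expect_true(all(dec$profile_matched[dec$retained]))
    prev <- retained
  }
})

test_that("sample_control_users is reproducible and respects exclusions", {
  pool <- sprintf("u%04d", 1:1000)
  s1 <- sample_control_users(pool, 450, seed = 9)
  s2 <- sample_control_users(pool, 450, seed = 9)
  expect_identical(s1, s2)
  expect_equal(length(unique(s1)), 450)
  s3 <- sample_control_users(pool, 450, seed = 10)
  expect_false(identical(s1, s3))
  excl <- pool[1:600]
  s4 <- sample_control_users(pool, 400, exclusions = excl, seed = 9)
  expect_length(intersect(s4, excl), 0)
  expect_error(sample_control_users(pool, 500, exclusions = excl, seed = 9),
               "too small")
  expect_equal(sample_control_users(pool, 0, seed = 1), character())
  # profile-matching users are excluded automatically
  profs <- tibble::tibble(user_id = pool[1:10],
                          description = c(rep("depre", 5), rep("cine", 5)))
  s5 <- sample_control_users(pool[1:10], 5, seed = 3, profiles = profs)
  expect_setequal(s5, pool[6:10])
})

test_that("assemble_datasets produces disjoint corpora with conserved counts", {
  texts <- sprintf("tweet %d", 1:40)
  rt <- rep(c(FALSE, FALSE, FALSE, TRUE), 10)
  dep_tw <- make_tweets(texts, user_id = rep(sprintf("d%d", 1:5), each = 8),
                        is_retweet = rt, id_prefix = "dep")
  dep <- corpus("depressive_users", dep_tw)
  ctl <- corpus("control",
                make_tweets(sprintf("ctl %d", 1:20),
                            user_id = rep(c("c1", "c2"), each = 10),
                            id_prefix = "ctl"))
  flagged <- dep_tw$tweet_id[!dep_tw$is_retweet][1:7]
  out <- assemble_datasets(dep, flagged, ctl)
  expect_named(out, c("control", "depressive_users", "depressive_tweets"))
  expect_equal(sort(out$depressive_tweets$tweets$tweet_id), sort(flagged))
  ids <- lapply(out, function(cp) cp$tweets$tweet_id)
  expect_length(intersect(ids[[1]], ids[[2]]), 0)
  expect_length(intersect(ids[[1]], ids[[3]]), 0)
  expect_length(intersect(ids[[2]], ids[[3]]), 0)
  # conservation: non-retweet depressive timeline = users ds + flagged
  expect_equal(sum(!dep_tw$is_retweet),
               nrow(out$depressive_users$tweets) + length(flagged))
  expect_error(assemble_datasets(dep, "missing_id", ctl), "not found")
  # no flagged tweets -> empty depressive_tweets corpus
  out0 <- assemble_datasets(dep, character(), ctl)
  expect_equal(nrow(out0$depressive_tweets$tweets), 0)
})
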