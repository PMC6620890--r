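# Shared fixture builders. Everything is constructed in code; no stored data.

options(tuitvig.verbose = FALSE)

`%||%` <- rlang::`%||%`

utc <- function(x) as.POSIXct(x, tz = "UTC")

make_tweets <- function(texts,
                        user_id = "u1",
                        created = utc("2018-06-13 12:00:00") +
                          seq_along(texts) * 60,
                        offset = 3600L,
                        is_retweet = FALSE,
                        lang = "es",
                        id_prefix = "t") {
  n <- length(texts)
  tibble::tibble(
    tweet_id = paste0(id_prefix, seq_len(n)),
    user_id = rep_len(user_id, n),
    text = texts,
    created_at_utc = rep_len(created, n)[seq_len(n)],
    utc_offset_seconds = rep_len(as.integer(offset), n),
    is_retweet = rep_len(is_retweet, n),
    lang = rep_len(lang, n)
  )
}

mini_corpus <- function(texts, label = "control", ...) {
  corpus(label, make_tweets(texts, ...))
}

# A tiny deterministic tagger for hermetic tagging tests.
toy_tagger <- function() {
  dict_tagger(tibble::tibble(
    word = c("yo", "te", "casa", "ver", "triste", "el", "hoy", "de", "y"),
    pos = c("pronoun", "pronoun", "noun", "verb", "adjective", "determiner",
            "adverb", "adposition", "conjunction"),
    person = c("1S", "2S", NA, NA, NA, NA, NA, NA, NA)
  ))
}

# Small-but-not-tiny synthetic study reused by several test files.
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_study(
        control_spec(n_users = 8, tweets_per_user = c(60, 5)),
        depressive_spec(n_users = 8, tweets_per_user = c(60, 5)),
        seed = 42
      )
    }
    cache
  }
})
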