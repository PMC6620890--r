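# Twitter-aware tokenization and surface-feature counting.
#
# Emoji are recognised by explicit Unicode codepoint ranges (Misc Symbols,
# Dingbats, Supplemental Symbols & Pictographs, flags) with variation
# selectors / skin-tone modifiers attached and ZWJ sequences merged into a
# single token, so a family emoji is one token, not four.

EMOJI_BASE <- paste0(
  "[\\x{1F000}-\\x{1F0FF}\\x{1F300}-\\x{1F5FF}\\x{1F600}-\\x{1F64F}",
  "\\x{1F680}-\\x{1F6FF}\\x{1F900}-\\x{1F9FF}\\x{1FA70}-\\x{1FAFF}",
  "\\x{1F1E6}-\\x{1F1FF}\\x{2600}-\\x{26FF}\\x{2700}-\\x{27BF}",
  "\\x{2B00}-\\x{2BFF}\\x{2764}]")
EMOJI_MOD <- "[\\x{FE0F}\\x{1F3FB}-\\x{1F3FF}]"
EMOJI_SEQ <- paste0(EMOJI_BASE, EMOJI_MOD, "*",
                    "(?:\\x{200D}", EMOJI_BASE, EMOJI_MOD, "*)*")

TOKEN_REGEX <- paste(
  "https?://[^\\s]+",
  "t\\.co/[^\\s]+",
  "@[A-Za-z0-9_]+",
  "#[\\p{L}\\p{Nd}_]+",
  EMOJI_SEQ,
  "[\\p{L}\\p{M}]+",
  "\\p{Nd}+(?:[.,]\\p{Nd}+)*",
  "[@#]",
  "[^\\p{L}\\p{Nd}\\s@#]+",
  sep = "|")

TOKEN_KINDS <- c("word", "mention", "hashtag", "url", "emoji", "punctuation",
                 "number")

classify_tokens <- function(surface) {
  kind <- rep("punctuation", length(surface))
  kind[stringi::stri_detect_regex(surface, "^(https?://|t\\.co/)")] <- "url"
  kind[stringi::stri_detect_regex(surface, "^@[A-Za-z0-9_]+$")] <- "mention"
  kind[stringi::stri_detect_regex(surface, "^#[\\p{L}\\p{Nd}_]+$")] <- "hashtag"
  kind[stringi::stri_detect_regex(surface,
                                  paste0("^(?:", EMOJI_SEQ, ")+$"))] <- "emoji"
  kind[stringi::stri_detect_regex(surface, "^[\\p{L}\\p{M}]+$")] <- "word"
  kind[stringi::stri_detect_regex(surface, "^\\p{Nd}")] <- "number"
  kind
}

#' Tokenize many texts at once
#'
#' Vectorized core of the tokenizer: returns one long tibble over all texts,
#' with `doc` indexing the input element. Whitespace is discarded; every other
#' character belongs to exactly one token, so concatenating `surface` within a
#' document reconstructs the text up to whitespace.
#'
#' @param texts Character vector.
#' @return Tibble with columns `doc` (integer), `surface`, `normalized`
#'   (lower-cased surface), `kind` (one of word, mention, hashtag, url,
#'   emoji, punctuation, number).
#' @export
tokenize_texts <- function(texts) {
  stopifnot(is.character(texts))
  if (length(texts) == 0) {
    return(tibble(doc = integer(), surface = character(),
                  normalized = character(), kind = character()))
  }
  hits <- stringi::stri_extract_all_regex(texts, TOKEN_REGEX,
                                          omit_no_match = TRUE)
  lens <- lengths(hits)
  surface <- unlist(hits, use.names = FALSE) %||% character()
  tibble(
    doc = rep(seq_along(texts), lens),
    surface = surface,
    normalized = stringi::stri_trans_tolower(surface),
    kind = classify_tokens(surface)
  )
}

#' Tokenize one tweet
#'
#' @param text A single character string.
#' @return Tibble of tokens (columns `surface`, `normalized`, `kind`), in
#'   text order.
#' @export
tokenize_tweet <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  tokenize_texts(text)[, c("surface", "normalized", "kind")]
}

#' Count entity tokens in a tokenized tweet
#'
#' @param tokens Token tibble from [tokenize_tweet()].
#' @return Tibble with one row: `hashtags`, `links`, `mentions`, `emojis`.
#' @export
count_entities <- function(tokens) {
  tibble(hashtags = sum(tokens$kind == "hashtag"),
         links = sum(tokens$kind == "url"),
         mentions = sum(tokens$kind == "mention"),
         emojis = sum(tokens$kind == "emoji"))
}

#' Per-tweet entity presence rates over a corpus
#'
#' A tweet "includes" an entity class iff it contains at least one token of
#' that kind; rates are the fraction of tweets that do.
#'
#' @param corpus A `tweet_corpus`.
#' @return Tibble with columns `entity`, `tweets_with`, `n_tweets`, `rate`.
#' @export
entity_rates <- function(corpus) {
  stopifnot(inherits(corpus, "tweet_corpus"))
  toks <- tokenize_texts(corpus$tweets$text)
  n <- nrow(corpus$tweets)
  kinds <- c(hashtag = "hashtag", link = "url", mention = "mention",
             emoji = "emoji")
  purrr::map_dfr(names(kinds), function(nm) {
    with_k <- length(unique(toks$doc[toks$kind == kinds[[nm]]]))
    tibble(entity = nm, tweets_with = with_k, n_tweets = n,
           rate = if (n > 0) with_k / n else NA_real_)
  })
}

#' Count Unicode code points of raw tweet text
#'
#' No normalization is applied; URLs and mentions count (a configuration flag
#' excludes them for sensitivity analyses).
#'
#' @param text Character vector.
#' @param exclude_entities If `TRUE`, URL and mention tokens are removed
#'   before counting (whitespace still counts as in the raw text minus the
#'   removed tokens).
#' @return Integer vector of code-point counts.
#' @export
char_count <- function(text, exclude_entities = FALSE) {
  stopifnot(is.character(text))
  if (!exclude_entities) return(nchar(text, type = "chars"))
  stripped <- stringi::stri_replace_all_regex(
    text, "https?://[^\\s]+|t\\.co/[^\\s]+|@[A-Za-z0-9_]+", "")
  nchar(stripped, type = "chars")
}

#' Most frequent words in a corpus
#'
#' Word-kind tokens only, lower-cased, with stopwords removed; ranked by
#' count (descending) with lexicographic tie-breaking for reproducibility.
#'
#' @param corpus A `tweet_corpus`.
#' @param k Maximum number of words returned (default 200, the word-cloud
#'   size).
#' @param stopwords Character vector of words to exclude (default: the
#'   bundled Spanish stopword list).
#' @return Tibble with columns `word` and `count`, at most `k` rows.
#' @export
top_words <- function(corpus, k = 200L, stopwords = spanish_stopwords()) {
  stopifnot(inherits(corpus, "tweet_corpus"), k >= 1)
  toks <- tokenize_texts(corpus$tweets$text)
  words <- toks$normalized[toks$kind == "word"]
  words <- words[!(words %in% stopwords)]
  if (length(words) == 0) return(tibble(word = character(), count = integer()))
  tab <- table(words)
  out <- tibble(word = names(tab), count = as.integer(tab)) %>%
    arrange(desc(.data$count), .data$word)
  head(out, k)
}

#' Bundled Spanish stopword list
#'
#' The 100 most frequent Spanish function words, used both for the control
#' sampling stream filter and for word-cloud pruning.
#'
#' @return Character vector.
#' @export
spanish_stopwords <- function() {
  readLines(tv_extdata("stopwords_es.txt"), encoding = "UTF-8")
}
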