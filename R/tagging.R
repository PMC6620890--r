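# Part-of-speech profiling over eight grammatical categories and
# pronoun person/number classification.
#
# Tagging is a pluggable contract: any object with class `tv_tagger` exposing
# `$tag(normalized_words)` -> tibble(pos, person) can be used. The bundled
# tagger is a deterministic dictionary lookup over a tagged vocabulary,
# which keeps tests hermetic; unknown words tag as "other".

#' Build a dictionary tagger
#'
#' @param vocabulary Either a `tv_vocabulary` bank, a tibble with columns
#'   `word`, `pos` and optionally `person`, or `NULL` for the bundled tagged
#'   vocabulary file.
#' @return A `tv_tagger` object.
#' @export
dict_tagger <- function(vocabulary = NULL) {
  if (is.null(vocabulary)) {
    tab <- read_tagged_vocabulary(tv_extdata("tagged_vocabulary_synthetic.tsv"))
  } else if (inherits(vocabulary, "tv_vocabulary")) {
    tab <- vocabulary$tagged
  } else {
    tab <- as_tibble(vocabulary)
    if (!"person" %in% names(tab)) tab$person <- NA_character_
  }
  stopifnot(all(c("word", "pos") %in% names(tab)))
  bad <- !tab$pos %in% c(POS_CATEGORIES, "other")
  if (any(bad)) {
    abort(paste0("unknown POS categories in vocabulary: ",
                 paste(unique(tab$pos[bad]), collapse = ", ")))
  }
  pos_map <- setNames(tab$pos, tab$word)
  person_map <- setNames(tab$person, tab$word)
  structure(list(
    n_entries = nrow(tab),
    tag = function(words) {
      pos <- unname(pos_map[words])
      pos[is.na(pos)] <- "other"
      person <- unname(person_map[words])
      person[pos != "pronoun"] <- NA_character_
      tibble(pos = pos, person = person)
    }
  ), class = "tv_tagger")
}

#' Read a tagged-vocabulary TSV
#'
#' Format: `word<TAB>pos<TAB>person`, header row, person empty for
#' non-pronouns.
#'
#' @param path File path.
#' @return Tibble with columns `word`, `pos`, `person`.
#' @export
read_tagged_vocabulary <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           fileEncoding = "UTF-8",
                           colClasses = "character", quote = "")
  tab$person[!nzchar(tab$person)] <- NA_character_
  as_tibble(tab)
}

#' Tag tokens with grammatical categories
#'
#' Only word-kind tokens are looked up; every other token kind (and any word
#' the tagger cannot resolve) is tagged `other`.
#'
#' @param tokens Token tibble (from [tokenize_tweet()] / [tokenize_texts()]).
#' @param tagger A `tv_tagger`, default the bundled dictionary tagger.
#' @return `tokens` with `pos` and `pronoun_person` columns appended.
#' @export
tag_tokens <- function(tokens, tagger = dict_tagger()) {
  stopifnot(inherits(tagger, "tv_tagger"))
  pos <- rep("other", nrow(tokens))
  person <- rep(NA_character_, nrow(tokens))
  is_word <- tokens$kind == "word"
  if (any(is_word)) {
    tagged <- tagger$tag(tokens$normalized[is_word])
    pos[is_word] <- tagged$pos
    person[is_word] <- tagged$person
  }
  tokens$pos <- pos
  tokens$pronoun_person <- person
  tokens
}

#' Part-of-speech profile of a corpus
#'
#' Aggregates tagged word tokens into the eight grammatical categories.
#' `other` (unknown words, non-word tokens) is excluded from the total used
#' for percentages, so the eight shares sum to 100.
#'
#' @param corpus A `tweet_corpus`.
#' @param tagger A `tv_tagger`.
#' @return A tibble of class `pos_profile` with columns `category`, `n`,
#'   `pct`, plus attributes `total` (eight-category token total) and
#'   `n_other`.
#' @export
pos_profile <- function(corpus, tagger = dict_tagger()) {
  stopifnot(inherits(corpus, "tweet_corpus"))
  toks <- tag_tokens(tokenize_texts(corpus$tweets$text), tagger)
  counts <- vapply(POS_CATEGORIES, function(cat) sum(toks$pos == cat),
                   integer(1))
  total <- sum(counts)
  out <- tibble(category = POS_CATEGORIES, n = unname(counts),
                pct = if (total > 0) 100 * unname(counts) / total
                      else rep(NA_real_, length(counts)))
  attr(out, "total") <- total
  attr(out, "n_other") <- sum(toks$pos == "other" & toks$kind == "word")
  class(out) <- c("pos_profile", class(out))
  out
}

#' Personal-pronoun person/number profile of a corpus
#'
#' Counts personal pronouns by the six person/number classes (1S, 1P, 2S, 2P,
#' 3S, 3P); shares are computed over the six-class total. Non-personal
#' pronouns count toward the pronoun POS category but not here.
#'
#' @param corpus A `tweet_corpus`.
#' @param tagger A `tv_tagger`.
#' @return A tibble of class `pronoun_profile` with columns `person`, `n`,
#'   `share_pct`, plus attributes `total_personal` and `total_pronouns`.
#' @export
pronoun_profile <- function(corpus, tagger = dict_tagger()) {
  stopifnot(inherits(corpus, "tweet_corpus"))
  toks <- tag_tokens(tokenize_texts(corpus$tweets$text), tagger)
  personal <- toks$pronoun_person[!is.na(toks$pronoun_person)]
  counts <- vapply(PRONOUN_PERSONS, function(p) sum(personal == p),
                   integer(1))
  total <- sum(counts)
  out <- tibble(person = PRONOUN_PERSONS, n = unname(counts),
                share_pct = if (total > 0) 100 * unname(counts) / total
                            else rep(NA_real_, length(counts)))
  attr(out, "total_personal") <- total
  attr(out, "total_pronouns") <- sum(toks$pos == "pronoun")
  class(out) <- c("pronoun_profile", class(out))
  out
}
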