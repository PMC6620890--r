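# Lexicon scoring: negation cues, six basic emotions, and dual sentiment
# polarity (binary-signed and graded real-valued word lists).
#
# The bundled lexicons are small synthetic stand-ins aligned with the
# synthetic vocabulary (the published Spanish resources are not
# redistributable); the loaders accept the real resources in the same
# term<TAB>annotation TSV layout.

#' Load a lexicon
#'
#' @param path TSV file. Negation lists are one term per line (no header);
#'   emotion lexicons have columns `term`, `emotion`; polarity lexicons have
#'   columns `term`, `value` (binary: +-1; graded: real in \[-1, 1\]).
#' @param type One of `"negation"`, `"emotion"`, `"polarity_binary"`,
#'   `"polarity_graded"`.
#' @return A `tv_lexicon` object: list with `type` and `table`.
#' @export
read_lexicon <- function(path, type = c("negation", "emotion",
                                        "polarity_binary",
                                        "polarity_graded")) {
  type <- match.arg(type)
  if (type == "negation") {
    terms <- readLines(path, encoding = "UTF-8")
    terms <- terms[nzchar(trimws(terms))]
    tab <- tibble(term = tolower(terms))
  } else {
    tab <- as_tibble(utils::read.delim(path, sep = "\t", header = TRUE,
                                       fileEncoding = "UTF-8", quote = ""))
    tab$term <- tolower(as.character(tab$term))
  }
  lexicon(tab, type)
}

#' Construct a lexicon from a table
#'
#' @param table Tibble with a `term` column (lower-case, unique) and the
#'   annotation column the type requires (`emotion` or `value`).
#' @param type See [read_lexicon()].
#' @rdname read_lexicon
#' @export
lexicon <- function(table, type = c("negation", "emotion", "polarity_binary",
                                    "polarity_graded")) {
  type <- match.arg(type)
  table <- as_tibble(table)
  stopifnot("term" %in% names(table))
  if (type == "emotion") {
    stopifnot("emotion" %in% names(table))
    bad <- !table$emotion %in% EMOTIONS
    if (any(bad)) {
      abort(paste0("unknown emotion label(s): ",
                   paste(unique(table$emotion[bad]), collapse = ", ")))
    }
    if (anyDuplicated(table[, c("term", "emotion")])) {
      abort("duplicate term/emotion pairs in lexicon")
    }
  } else {
    if (anyDuplicated(table$term)) abort("duplicate terms in lexicon")
  }
  if (type == "polarity_binary" &&
      !all(table$value %in% c(-1, 1))) {
    abort("binary polarity values must be +1 or -1")
  }
  if (type == "polarity_graded" &&
      (any(table$value < -1) || any(table$value > 1))) {
    abort("graded polarity values must lie in [-1, 1]")
  }
  structure(list(type = type, table = table), class = "tv_lexicon")
}

#' Bundled synthetic lexicons and lists
#'
#' Convenience loaders for the stand-in resources shipped under
#' `inst/extdata`.
#'
#' @return A `tv_lexicon` (or character vector for the word lists).
#' @export
negation_lexicon <- function() {
  read_lexicon(tv_extdata("negations.txt"), "negation")
}

#' @rdname negation_lexicon
#' @export
emotion_lexicon_synthetic <- function() {
  read_lexicon(tv_extdata("emotion_lexicon_synthetic.tsv"), "emotion")
}

#' @rdname negation_lexicon
#' @export
polarity_binary_synthetic <- function() {
  read_lexicon(tv_extdata("polarity_binary_synthetic.tsv"), "polarity_binary")
}

#' @rdname negation_lexicon
#' @export
polarity_graded_synthetic <- function() {
  read_lexicon(tv_extdata("polarity_graded_synthetic.tsv"), "polarity_graded")
}

word_tokens <- function(tokens) tokens$normalized[tokens$kind == "word"]

#' Count negation cues in a tokenized tweet
#'
#' @param tokens Token tibble.
#' @param lex A negation `tv_lexicon` (default: bundled list).
#' @return Non-negative integer count of word tokens on the negation list.
#' @export
detect_negations <- function(tokens, lex = negation_lexicon()) {
  stopifnot(inherits(lex, "tv_lexicon"), lex$type == "negation")
  sum(word_tokens(tokens) %in% lex$table$term)
}

#' Per-tweet negation counts over a corpus
#'
#' @param corpus A `tweet_corpus`.
#' @param lex A negation `tv_lexicon`.
#' @return Integer vector, one count per tweet (corpus order).
#' @export
negation_counts <- function(corpus, lex = negation_lexicon()) {
  stopifnot(inherits(corpus, "tweet_corpus"))
  toks <- tokenize_texts(corpus$tweets$text)
  hit <- toks$kind == "word" & toks$normalized %in% lex$table$term
  counts <- rep(0L, nrow(corpus$tweets))
  if (any(hit)) {
    tab <- table(toks$doc[hit])
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  counts
}

#' Score the six basic emotions in a tokenized tweet
#'
#' Each word token matching a lexicon entry increments that entry's emotion;
#' a term listed under several emotions increments each.
#'
#' @param tokens Token tibble.
#' @param lex An emotion `tv_lexicon`.
#' @return Named integer vector over the six emotions.
#' @export
score_emotions <- function(tokens, lex = emotion_lexicon_synthetic()) {
  stopifnot(inherits(lex, "tv_lexicon"), lex$type == "emotion")
  words <- word_tokens(tokens)
  hits <- lex$table[lex$table$term %in% words, ]
  counts <- setNames(rep(0L, length(EMOTIONS)), EMOTIONS)
  if (nrow(hits) > 0) {
    per_term <- table(words)[unique(hits$term)]
    for (i in seq_len(nrow(hits))) {
      counts[hits$emotion[i]] <- counts[hits$emotion[i]] +
        as.integer(per_term[hits$term[i]])
    }
  }
  counts
}

#' Corpus-level emotion profile
#'
#' @param corpus A `tweet_corpus`.
#' @param lex An emotion `tv_lexicon`.
#' @return Tibble with columns `emotion`, `n`, `share_pct` (share of all
#'   emotion hits).
#' @export
emotion_profile <- function(corpus, lex = emotion_lexicon_synthetic()) {
  stopifnot(inherits(corpus, "tweet_corpus"))
  toks <- tokenize_texts(corpus$tweets$text)
  words <- toks$normalized[toks$kind == "word"]
  counts <- setNames(rep(0L, length(EMOTIONS)), EMOTIONS)
  if (length(words) > 0) {
    wtab <- table(words)
    lt <- lex$table[lex$table$term %in% names(wtab), ]
    if (nrow(lt) > 0) {
      add <- tapply(as.integer(wtab[lt$term]), lt$emotion, sum)
      counts[names(add)] <- counts[names(add)] + add
    }
  }
  total <- sum(counts)
  tibble(emotion = EMOTIONS, n = unname(counts),
         share_pct = if (total > 0) 100 * unname(counts) / total
                     else rep(NA_real_, length(EMOTIONS)))
}

#' Binary polarity label of a tokenized tweet
#'
#' Counts positive-entry hits P and negative-entry hits N; P=N=0 gives
#' `none` (the tweet shows no polarity), otherwise the majority sign wins
#' and a non-zero tie resolves by `tie`.
#'
#' @param tokens Token tibble.
#' @param lex A binary polarity `tv_lexicon`.
#' @param tie Label for P=N>0: `"none"` (default), `"positive"` or
#'   `"negative"`.
#' @return One of `"positive"`, `"negative"`, `"none"`.
#' @export
score_polarity_binary <- function(tokens, lex = polarity_binary_synthetic(),
                                  tie = c("none", "positive", "negative")) {
  tie <- match.arg(tie)
  stopifnot(inherits(lex, "tv_lexicon"), lex$type == "polarity_binary")
  words <- word_tokens(tokens)
  vals <- lex$table$value[match(words, lex$table$term)]
  p <- sum(vals > 0, na.rm = TRUE)
  n <- sum(vals < 0, na.rm = TRUE)
  if (p == 0 && n == 0) return("none")
  if (p > n) "positive" else if (n > p) "negative" else tie
}

#' Graded polarity label of a tokenized tweet
#'
#' The mean value of matched entries is thresholded: `s >= t_mod` is
#' positive, `0 < s < t_mod` moderate positive (symmetric for negatives);
#' no match or `s = 0` gives `none`.
#'
#' @param tokens Token tibble.
#' @param lex A graded polarity `tv_lexicon`.
#' @param t_mod Moderate/strong threshold in (0, 1), default 0.5.
#' @return One of `"positive"`, `"moderate_positive"`, `"moderate_negative"`,
#'   `"negative"`, `"none"`.
#' @export
score_polarity_graded <- function(tokens, lex = polarity_graded_synthetic(),
                                  t_mod = 0.5) {
  stopifnot(inherits(lex, "tv_lexicon"), lex$type == "polarity_graded",
            t_mod > 0, t_mod < 1)
  words <- word_tokens(tokens)
  vals <- lex$table$value[match(words, lex$table$term)]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) return("none")
  s <- mean(vals)
  if (s == 0) "none"
  else if (s >= t_mod) "positive"
  else if (s > 0) "moderate_positive"
  else if (s <= -t_mod) "negative"
  else "moderate_negative"
}

#' Polarity labels for every tweet in a corpus
#'
#' Vectorized equivalent of the per-tweet scorers.
#'
#' @param corpus A `tweet_corpus`.
#' @param scheme `"binary"` or `"graded"`.
#' @param lex The corresponding `tv_lexicon` (defaults to the bundled
#'   stand-in).
#' @param t_mod,tie Passed to the per-tweet scorers.
#' @return Character vector of labels, one per tweet.
#' @export
polarity_labels <- function(corpus, scheme = c("binary", "graded"),
                            lex = NULL, t_mod = 0.5, tie = "none") {
  scheme <- match.arg(scheme)
  stopifnot(inherits(corpus, "tweet_corpus"))
  if (is.null(lex)) {
    lex <- if (scheme == "binary") polarity_binary_synthetic()
           else polarity_graded_synthetic()
  }
  toks <- tokenize_texts(corpus$tweets$text)
  is_word <- toks$kind == "word"
  vals <- rep(NA_real_, nrow(toks))
  vals[is_word] <- lex$table$value[match(toks$normalized[is_word],
                                         lex$table$term)]
  n_tw <- nrow(corpus$tweets)
  labels <- rep("none", n_tw)
  hit <- !is.na(vals)
  if (!any(hit)) return(labels)
  docs <- toks$doc[hit]
  v <- vals[hit]
  if (scheme == "binary") {
    p <- tapply(v > 0, docs, sum)
    n <- tapply(v < 0, docs, sum)
    idx <- as.integer(names(p))
    lab <- ifelse(p > n, "positive", ifelse(n > p, "negative", tie))
    labels[idx] <- lab
  } else {
    s <- tapply(v, docs, mean)
    idx <- as.integer(names(s))
    lab <- ifelse(s == 0, "none",
           ifelse(s >= t_mod, "positive",
           ifelse(s > 0, "moderate_positive",
           ifelse(s <= -t_mod, "negative", "moderate_negative"))))
    labels[idx] <- lab
  }
  labels
}

#' Polarity prevalence and label shares of a corpus
#'
#' @param corpus A `tweet_corpus`.
#' @param scheme `"binary"` or `"graded"`.
#' @param ... Passed to [polarity_labels()].
#' @return List with `prevalence` (proportion of tweets with a label other
#'   than `none`), `n_polar`, `n_tweets`, and `shares` (tibble `label`, `n`,
#'   `share_pct`: the conditional distribution among polar tweets; empty when
#'   no tweet is polar).
#' @export
polarity_prevalence <- function(corpus, scheme = c("binary", "graded"), ...) {
  scheme <- match.arg(scheme)
  labels <- polarity_labels(corpus, scheme, ...)
  polar <- labels[labels != "none"]
  lvls <- if (scheme == "binary") c("positive", "negative")
          else c("positive", "moderate_positive", "moderate_negative",
                 "negative")
  n_tw <- length(labels)
  shares <- if (length(polar) > 0) {
    counts <- vapply(lvls, function(l) sum(polar == l), integer(1))
    tibble(label = lvls, n = unname(counts),
           share_pct = 100 * unname(counts) / length(polar))
  } else {
    tibble(label = character(), n = integer(), share_pct = numeric())
  }
  list(prevalence = if (n_tw > 0) length(polar) / n_tw else NA_real_,
       n_polar = length(polar), n_tweets = n_tw, shares = shares)
}
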