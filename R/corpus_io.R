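# Reading, validating and filtering JSON-lines tweet corpora.

CORPUS_LABELS <- c("control", "depressive_users", "depressive_tweets")

#' Construct a tweet corpus
#'
#' A corpus holds one dataset of the study design: the tweets (ordered as
#' supplied) and the profiles of the users they belong to.
#'
#' @param label One of `"control"`, `"depressive_users"`,
#'   `"depressive_tweets"`.
#' @param tweets Tibble with columns `tweet_id`, `user_id`, `text`,
#'   `created_at_utc` (POSIXct, UTC), `utc_offset_seconds` (integer, may be
#'   `NA`), `is_retweet` (logical), `lang` (ISO-639-1 code).
#' @param profiles Tibble with columns `user_id` (unique) and `description`;
#'   defaults to empty descriptions for the users present in `tweets`.
#' @return An object of class `tweet_corpus`.
#' @export
corpus <- function(label, tweets, profiles = NULL) {
  label <- match.arg(label, CORPUS_LABELS)
  tweets <- as_tibble(tweets)
  required <- c("tweet_id", "user_id", "text", "created_at_utc",
                "utc_offset_seconds", "is_retweet", "lang")
  missing_cols <- setdiff(required, names(tweets))
  if (length(missing_cols) > 0) {
    abort(paste0("tweets is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (is.null(profiles)) {
    profiles <- tibble(user_id = unique(tweets$user_id), description = "")
  }
  profiles <- as_tibble(profiles)
  if (anyDuplicated(profiles$user_id)) {
    abort("profiles must have one row per user_id")
  }
  orphan <- setdiff(tweets$user_id, profiles$user_id)
  if (length(orphan) > 0) {
    abort(paste0(length(orphan), " tweet user_id(s) lack a profile"))
  }
  if (nrow(tweets) > 0) {
    if (any(!nzchar(trimws(tweets$text)))) {
      abort("tweet text must be non-empty after stripping whitespace")
    }
    off <- tweets$utc_offset_seconds
    bad <- !is.na(off) & (off < -50400 | off > 50400)
    if (any(bad)) abort("utc_offset_seconds outside [-50400, 50400]")
  }
  structure(list(label = label, tweets = tweets, profiles = profiles),
            class = "tweet_corpus")
}

#' @export
print.tweet_corpus <- function(x, ...) {
  cat("<tweet_corpus> label:", x$label,
      "|", nrow(x$tweets), "tweets |",
      nrow(x$profiles), "profiles\n")
  invisible(x)
}

#' @export
#' @method as_tibble tweet_corpus
as_tibble.tweet_corpus <- function(x, ...) x$tweets

n_tweets <- function(corpus) nrow(corpus$tweets)

#' Field-name schema for JSON-lines corpora
#'
#' Maps canonical field names to (possibly dot-nested) JSON keys. The default
#' is the package's flat storage layout; [schema_twitter_v11()] mirrors the
#' Twitter API v1.1 names.
#'
#' @param tweet_id,user_id,text,created_at,utc_offset,is_retweet,lang,description
#'   JSON key (use `"a.b"` for nesting) or `NA` when absent from the files.
#' @return A named character vector usable as the `schema` argument of
#'   [read_corpus()].
#' @export
corpus_schema <- function(tweet_id = "tweet_id", user_id = "user_id",
                          text = "text", created_at = "created_at",
                          utc_offset = "utc_offset_seconds",
                          is_retweet = "is_retweet", lang = "lang",
                          description = "user_description") {
  c(tweet_id = tweet_id, user_id = user_id, text = text,
    created_at = created_at, utc_offset = utc_offset,
    is_retweet = is_retweet, lang = lang, description = description)
}

#' @rdname corpus_schema
#' @export
schema_twitter_v11 <- function() {
  corpus_schema(tweet_id = "id_str", user_id = "user.id_str",
                text = "full_text", created_at = "created_at",
                utc_offset = "user.utc_offset", is_retweet = "is_retweet",
                lang = "lang", description = "user.description")
}

# Walk a dot-separated path into a parsed JSON object.
json_field <- function(obj, path) {
  if (is.na(path)) return(NULL)
  for (key in strsplit(path, ".", fixed = TRUE)[[1]]) {
    if (!is.list(obj) || is.null(obj[[key]])) return(NULL)
    obj <- obj[[key]]
  }
  obj
}

# Parse timestamps in ISO-8601 or classic Twitter format
# ("Wed Jun 13 12:00:00 +0000 2018") into POSIXct UTC.
parse_created_at <- function(x) {
  x <- as.character(x)
  out <- rep(as.POSIXct(NA, tz = "UTC"), length(x))
  tw <- stringr::str_match(
    x, "^[A-Za-z]{3} ([A-Za-z]{3}) (\\d{2}) (\\d{2}:\\d{2}:\\d{2}) ([+-]\\d{4}) (\\d{4})$")
  is_tw <- !is.na(tw[, 1])
  if (any(is_tw)) {
    months <- c(Jan = "01", Feb = "02", Mar = "03", Apr = "04", May = "05",
                Jun = "06", Jul = "07", Aug = "08", Sep = "09", Oct = "10",
                Nov = "11", Dec = "12")
    iso <- paste0(tw[is_tw, 6], "-", months[tw[is_tw, 2]], "-", tw[is_tw, 3],
                  " ", tw[is_tw, 4])
    tz_off <- as.integer(substr(tw[is_tw, 5], 1, 3)) * 3600 +
      sign(as.integer(substr(tw[is_tw, 5], 1, 3)) + 0.5) *
        as.integer(substr(tw[is_tw, 5], 4, 5)) * 60
    out[is_tw] <- as.POSIXct(iso, tz = "UTC") - tz_off
  }
  rest <- !is_tw & !is.na(x)
  if (any(rest)) {
    iso <- sub("Z$", "", sub("T", " ", x[rest]))
    out[rest] <- as.POSIXct(iso, tz = "UTC",
                            tryFormats = c("%Y-%m-%d %H:%M:%OS",
                                           "%Y-%m-%d %H:%M",
                                           "%Y-%m-%d"))
  }
  out
}

#' Read a JSON-lines tweet corpus
#'
#' One JSON object per line. Malformed lines (unparseable JSON, or missing any
#' of tweet_id / user_id / text / created_at) are counted and skipped with a
#' warning; more than 50% malformed lines is treated as a schema error and is
#' fatal. Duplicate tweet_ids are dropped (first occurrence kept) and logged.
#' Input order is preserved.
#'
#' @param path Path to the JSONL file.
#' @param label Corpus label (see [corpus()]).
#' @param schema Field mapping from [corpus_schema()].
#' @return A `tweet_corpus`. The number of skipped lines is available as
#'   `attr(x, "skipped")`.
#' @export
read_corpus <- function(path, label = "control", schema = corpus_schema()) {
  if (!file.exists(path)) abort(paste0("cannot read corpus file: ", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warn(paste0("empty corpus file: ", path))
    empty <- tibble(tweet_id = character(), user_id = character(),
                    text = character(),
                    created_at_utc = as.POSIXct(character(), tz = "UTC"),
                    utc_offset_seconds = integer(),
                    is_retweet = logical(), lang = character())
    out <- corpus(label, empty)
    attr(out, "skipped") <- 0L
    return(out)
  }
  recs <- lapply(lines, function(ln) {
    obj <- tryCatch(jsonlite::fromJSON(ln, simplifyVector = FALSE),
                    error = function(e) NULL)
    if (is.null(obj)) return(NULL)
    id <- json_field(obj, schema[["tweet_id"]])
    uid <- json_field(obj, schema[["user_id"]])
    txt <- json_field(obj, schema[["text"]])
    ts <- json_field(obj, schema[["created_at"]])
    if (is.null(id) || is.null(uid) || is.null(txt) || is.null(ts)) {
      return(NULL)
    }
    off <- json_field(obj, schema[["utc_offset"]])
    list(tweet_id = as.character(id), user_id = as.character(uid),
         text = as.character(txt), created_at = as.character(ts),
         utc_offset_seconds = if (is.null(off)) NA_integer_
                              else as.integer(off),
         is_retweet = isTRUE(json_field(obj, schema[["is_retweet"]])),
         lang = as.character(json_field(obj, schema[["lang"]]) %||% NA),
         description = as.character(json_field(obj, schema[["description"]]) %||% NA))
  })
  ok <- !vapply(recs, is.null, logical(1))
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    if (n_bad > length(lines) / 2) {
      abort(paste0(n_bad, "/", length(lines), " malformed lines in ", path,
                   ": wrong schema?"))
    }
    warn(paste0("skipped ", n_bad, " malformed line(s) in ", path))
  }
  recs <- recs[ok]
  tweets <- tibble(
    tweet_id = vapply(recs, `[[`, "", "tweet_id"),
    user_id = vapply(recs, `[[`, "", "user_id"),
    text = vapply(recs, `[[`, "", "text"),
    created_at_utc = parse_created_at(vapply(recs, `[[`, "", "created_at")),
    utc_offset_seconds = vapply(recs, `[[`, NA_integer_,
                                "utc_offset_seconds"),
    is_retweet = vapply(recs, `[[`, NA, "is_retweet"),
    lang = vapply(recs, `[[`, "", "lang")
  )
  if (anyDuplicated(tweets$tweet_id)) {
    dup <- sum(duplicated(tweets$tweet_id))
    tv_log("dropping ", dup, " duplicate tweet_id(s) in ", path)
    keep <- !duplicated(tweets$tweet_id)
    tweets <- tweets[keep, ]
    recs <- recs[keep]
  }
  desc <- vapply(recs, `[[`, "", "description")
  profs <- tibble(user_id = tweets$user_id,
                  description = ifelse(is.na(desc), "", desc)) %>%
    distinct(.data$user_id, .keep_all = TRUE)
  out <- corpus(label, tweets, profs)
  attr(out, "skipped") <- n_bad
  out
}

#' Write a corpus as JSON-lines
#'
#' Inverse of [read_corpus()] under the default schema: one flat JSON object
#' per tweet, timestamps in ISO-8601 UTC, with the user's profile description
#' repeated on each line.
#'
#' @param corpus A `tweet_corpus`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "tweet_corpus"))
  tw <- corpus$tweets %>%
    left_join(corpus$profiles, by = "user_id")
  lines <- vapply(seq_len(nrow(tw)), function(i) {
    jsonlite::toJSON(list(
      tweet_id = tw$tweet_id[i], user_id = tw$user_id[i], text = tw$text[i],
      created_at = format(tw$created_at_utc[i], "%Y-%m-%dT%H:%M:%SZ",
                          tz = "UTC"),
      utc_offset_seconds = tw$utc_offset_seconds[i],
      is_retweet = tw$is_retweet[i], lang = tw$lang[i],
      user_description = tw$description[i]
    ), auto_unbox = TRUE, null = "null", na = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Remove retweets from a corpus
#'
#' A tweet is a retweet when its metadata flag is set OR its text starts with
#' the marker `"RT @"` (after stripping leading whitespace); both rules are
#' applied, which is the conservative reading of timeline collections.
#'
#' @param corpus A `tweet_corpus`.
#' @return The corpus restricted to non-retweets; the number removed is in
#'   `attr(x, "removed")`.
#' @export
drop_retweets <- function(corpus) {
  stopifnot(inherits(corpus, "tweet_corpus"))
  marker <- startsWith(stringr::str_trim(corpus$tweets$text, side = "left"),
                       "RT @")
  keep <- !corpus$tweets$is_retweet & !marker
  out <- corpus
  out$tweets <- corpus$tweets[keep, ]
  attr(out, "removed") <- sum(!keep)
  out
}

#' Keep only tweets in a given language
#'
#' @param corpus A `tweet_corpus`.
#' @param lang ISO-639-1 code to keep (exact match), default `"es"`.
#' @return The filtered corpus.
#' @export
filter_language <- function(corpus, lang = "es") {
  stopifnot(inherits(corpus, "tweet_corpus"))
  out <- corpus
  out$tweets <- corpus$tweets[!is.na(corpus$tweets$lang) &
                                corpus$tweets$lang == lang, ]
  out
}

#' Truncate per-user timelines to the most recent tweets
#'
#' Emulates the collection cap of timeline APIs: at most `cap` most-recent
#' tweets are retained per user. Input must already be sorted newest-first
#' within each user; unsorted input signals a caller bug and is an error.
#'
#' @param tweets A tweets tibble (see [corpus()]).
#' @param cap Non-negative integer, default 3200.
#' @return The truncated tweets tibble.
#' @export
truncate_timeline <- function(tweets, cap = 3200L) {
  stopifnot(is.numeric(cap), cap >= 0)
  tweets <- as_tibble(tweets)
  unsorted <- tweets %>%
    group_by(.data$user_id) %>%
    summarise(bad = is.unsorted(rev(.data$created_at_utc)),
              .groups = "drop") %>%
    filter(.data$bad)
  if (nrow(unsorted) > 0) {
    abort(paste0("timelines not sorted newest-first for user(s): ",
                 paste(head(unsorted$user_id, 5), collapse = ", ")))
  }
  tweets %>%
    group_by(.data$user_id) %>%
    slice_head(n = cap) %>%
    ungroup()
}
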