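# User-selection and dataset-assembly rules: keyword matching on tweet text,
# "depr"-derivation matching on profile descriptions, the minimum
# flagged-tweet retention rule, reproducible control sampling, and the
# three-dataset split.

#' Bundled depression keyword list
#'
#' Twenty lemma patterns (lower-case, accent-preserved), some carrying the
#' "/a" gender-variant marker.
#'
#' @return Character vector of keyword entries.
#' @export
depression_keywords <- function() {
  readLines(tv_extdata("depression_keywords.txt"), encoding = "UTF-8")
}

#' Bundled profile derivations of "depr"
#'
#' @return Character vector.
#' @export
depr_derivations <- function() {
  readLines(tv_extdata("depr_derivations.txt"), encoding = "UTF-8")
}

#' Read a one-term-per-line keyword list
#'
#' @param path File path (UTF-8).
#' @return Character vector of entries.
#' @export
read_keyword_list <- function(path) {
  x <- readLines(path, encoding = "UTF-8")
  tolower(x[nzchar(trimws(x))])
}

#' Match depression keywords in tweet text
#'
#' Matching is token-level after tokenization, case-insensitive and
#' accent-sensitive; "/a" entries expand to both gendered forms and report
#' the canonical entry.
#'
#' @param text A single character string.
#' @param keywords Keyword entries (default: bundled list).
#' @return Character vector of matched canonical entries (possibly empty,
#'   unique, in order of first match).
#' @export
match_keywords <- function(text, keywords = depression_keywords()) {
  if (length(keywords) == 0) abort("empty keyword list")
  expanded <- expand_keywords(tolower(keywords))
  toks <- tokenize_tweet(text)
  words <- toks$normalized[toks$kind == "word"]
  hit <- expanded$canonical[match(words, expanded$form)]
  unique(hit[!is.na(hit)])
}

#' Does a profile description mention depression?
#'
#' Token-level, case-insensitive match of the profile description against the
#' closed derivation set of "depr". The accented entry "depresión" also
#' matches its unaccented spelling "depresion" (the one documented
#' relaxation), controlled by `accent_relax`.
#'
#' @param description Profile description string (may be empty).
#' @param derivations Derivation set (default: bundled list).
#' @param accent_relax Apply the "depresion" relaxation (default `TRUE`).
#' @return List with `matched` (logical) and `terms` (matched canonical
#'   derivations).
#' @export
profile_mentions_depr <- function(description,
                                  derivations = depr_derivations(),
                                  accent_relax = TRUE) {
  if (is.na(description) || !nzchar(trimws(description))) {
    return(list(matched = FALSE, terms = character()))
  }
  forms <- tibble(form = tolower(derivations),
                  canonical = tolower(derivations))
  if (accent_relax && "depresión" %in% forms$canonical) {
    forms <- bind_rows(forms,
                       tibble(form = "depresion", canonical = "depresión"))
  }
  toks <- tokenize_tweet(description)
  words <- toks$normalized[toks$kind == "word"]
  hit <- forms$canonical[match(words, forms$form)]
  hit <- unique(hit[!is.na(hit)])
  list(matched = length(hit) > 0, terms = hit)
}

#' Retention decision for a candidate depressive user
#'
#' A user is retained iff the profile matched the derivation set AND at least
#' `threshold` of their tweets were flagged as suggesting signs of
#' depression.
#'
#' @param user_id User identifier.
#' @param profile_matched Logical.
#' @param flagged_tweet_count Non-negative integer.
#' @param matched_derivations Character vector (bookkeeping only).
#' @param threshold Minimum flagged tweets, default 10.
#' @return One-row tibble of class `screening_decision`.
#' @export
retain_depressive_user <- function(user_id, profile_matched,
                                   flagged_tweet_count,
                                   matched_derivations = character(),
                                   threshold = 10L) {
  stopifnot(threshold >= 1, flagged_tweet_count >= 0)
  out <- tibble(
    user_id = as.character(user_id),
    profile_matched = isTRUE(profile_matched),
    matched_derivations = list(matched_derivations),
    flagged_tweet_count = as.integer(flagged_tweet_count),
    retained = isTRUE(profile_matched) && flagged_tweet_count >= threshold
  )
  class(out) <- c("screening_decision", class(out))
  out
}

#' Screen a set of candidate users
#'
#' Applies [profile_mentions_depr()] and the flagged-count rule to every
#' profile.
#'
#' @param profiles Tibble with `user_id`, `description`.
#' @param flagged_counts Named integer vector (names = user_id); users absent
#'   from it count 0 flagged tweets.
#' @param threshold Minimum flagged tweets, default 10.
#' @param derivations Derivation set.
#' @return Tibble of screening decisions, one row per profile.
#' @export
screen_users <- function(profiles, flagged_counts = integer(),
                         threshold = 10L, derivations = depr_derivations()) {
  profiles <- as_tibble(profiles)
  purrr::map_dfr(seq_len(nrow(profiles)), function(i) {
    uid <- profiles$user_id[i]
    m <- profile_mentions_depr(profiles$description[i], derivations)
    fc <- flagged_counts[uid] %0% 0L
    retain_depressive_user(uid, m$matched, as.integer(fc), m$terms,
                           threshold)
  })
}

#' Sample control users reproducibly
#'
#' Uniform sample without replacement from `pool` minus `exclusions`,
#' reproducible given `seed`. The caller is responsible for passing every
#' depression-profile user in `exclusions`; when `profiles` is supplied the
#' exclusion is derived automatically via [profile_mentions_depr()].
#'
#' @param pool Character vector of candidate user ids.
#' @param n Number of users to sample.
#' @param exclusions User ids to exclude.
#' @param seed Integer seed.
#' @param profiles Optional tibble (`user_id`, `description`); matching
#'   profiles are added to the exclusions.
#' @return Character vector of `n` distinct user ids.
#' @export
sample_control_users <- function(pool, n, exclusions = character(),
                                 seed = 1L, profiles = NULL) {
  pool <- unique(as.character(pool))
  if (!is.null(profiles)) {
    profiles <- as_tibble(profiles)
    matches <- vapply(profiles$description,
                      function(d) profile_mentions_depr(d)$matched,
                      logical(1))
    exclusions <- c(exclusions, profiles$user_id[matches])
  }
  eligible <- setdiff(pool, exclusions)
  if (length(eligible) < n) {
    abort(paste0("control pool too small: ", length(eligible),
                 " eligible users for n = ", n))
  }
  if (n == 0) return(character())
  with_seed(seed, sample(eligible, n))
}

#' Assemble the three study datasets
#'
#' Splits the collected material into the three corpora of the study design:
#' the depressive-tweets corpus is exactly the hand-flagged tweets; the
#' depressive-users corpus is the depressive timelines minus the flagged
#' tweets minus retweets; the control corpus is the control timelines minus
#' retweets. The three are pairwise disjoint by tweet_id.
#'
#' @param depressive A `tweet_corpus` of depressive users' timelines.
#' @param flagged_ids Tweet ids of the hand-flagged depressive tweets; every
#'   id must occur in `depressive` (error otherwise).
#' @param control A `tweet_corpus` of control timelines.
#' @return Named list of three `tweet_corpus` objects: `control`,
#'   `depressive_users`, `depressive_tweets`.
#' @export
assemble_datasets <- function(depressive, flagged_ids, control) {
  stopifnot(inherits(depressive, "tweet_corpus"),
            inherits(control, "tweet_corpus"))
  flagged_ids <- unique(as.character(flagged_ids))
  missing_ids <- setdiff(flagged_ids, depressive$tweets$tweet_id)
  if (length(missing_ids) > 0) {
    abort(paste0(length(missing_ids),
                 " flagged tweet id(s) not found in depressive timelines"))
  }
  is_flagged <- depressive$tweets$tweet_id %in% flagged_ids
  dep_tweets <- corpus("depressive_tweets",
                       depressive$tweets[is_flagged, ],
                       depressive$profiles)
  dep_users <- corpus("depressive_users",
                      depressive$tweets[!is_flagged, ],
                      depressive$profiles)
  dep_users <- drop_retweets(dep_users)
  dep_users$label <- "depressive_users"
  ctrl <- drop_retweets(control)
  ctrl$label <- "control"
  overlap <- intersect(ctrl$tweets$tweet_id,
                       c(dep_users$tweets$tweet_id,
                         dep_tweets$tweets$tweet_id))
  if (length(overlap) > 0) {
    abort("control and depressive corpora share tweet ids")
  }
  list(control = ctrl, depressive_users = dep_users,
       depressive_tweets = dep_tweets)
}
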