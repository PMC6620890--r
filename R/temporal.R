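# Timezone-adjusted diurnal and weekly activity profiles.
#
# Local time is created_at_utc + utc_offset_seconds; tweets with no stored
# offset are dropped from temporal analyses by default (configurable).
# Profiles are normalized per user (tweets per bin divided by the user's
# number of distinct observed local days) before averaging across users, so
# heavy users do not dominate the group mean.

#' Local hour and weekday of tweets
#'
#' @param corpus A `tweet_corpus` (or tweets tibble).
#' @param missing_offset `"drop"` (default: exclude tweets with no UTC
#'   offset, logged) or `"utc"` (treat missing offset as zero).
#' @return Tibble with columns `tweet_id`, `user_id`, `hour` (0-23),
#'   `weekday` (1 = Monday ... 7 = Sunday), `local_date`.
#' @export
local_time <- function(corpus, missing_offset = c("drop", "utc")) {
  missing_offset <- match.arg(missing_offset)
  tweets <- if (inherits(corpus, "tweet_corpus")) corpus$tweets
            else as_tibble(corpus)
  off <- tweets$utc_offset_seconds
  if (missing_offset == "drop") {
    n_miss <- sum(is.na(off))
    if (n_miss > 0) {
      tv_log("local_time: dropping ", n_miss, " tweet(s) with no UTC offset")
    }
    tweets <- tweets[!is.na(off), ]
    off <- off[!is.na(off)]
  } else {
    off[is.na(off)] <- 0L
  }
  lt <- tweets$created_at_utc + off
  tibble(
    tweet_id = tweets$tweet_id,
    user_id = tweets$user_id,
    hour = as.integer(format(lt, "%H", tz = "UTC")),
    weekday = as.integer(format(lt, "%u", tz = "UTC")),
    local_date = format(lt, "%Y-%m-%d", tz = "UTC")
  )
}

profile_bins <- function(by) {
  if (by == "hour") 0:23 else 1:7
}

build_profile <- function(corpus, by, include_retweets, missing_offset) {
  stopifnot(inherits(corpus, "tweet_corpus"))
  cp <- if (include_retweets) corpus else drop_retweets(corpus)
  lt <- local_time(cp, missing_offset)
  if (nrow(lt) == 0) abort("no temporally valid tweets in corpus")
  bins <- profile_bins(by)
  key <- if (by == "hour") lt$hour else lt$weekday
  users <- sort(unique(lt$user_id))
  days <- tapply(lt$local_date, lt$user_id,
                 function(d) length(unique(d)))[users]
  counts <- table(factor(lt$user_id, levels = users),
                  factor(key, levels = bins))
  per_user <- sweep(unclass(counts), 1, as.numeric(days), "/")
  grp_mean <- colMeans(per_user)
  grp_sem <- apply(per_user, 2, sd) / sqrt(length(users))
  structure(list(
    by = by, bins = bins, label = cp$label,
    per_user = per_user, mean = unname(grp_mean), sem = unname(grp_sem),
    n_users = length(users)
  ), class = "temporal_profile")
}

#' Hourly activity profile of a corpus
#'
#' Per user, the mean number of tweets in each local-hour bin per observed
#' day (total in bin divided by the user's distinct local days with
#' activity); across users, the group mean and standard error of the mean
#' per bin.
#'
#' @param corpus A `tweet_corpus` with at least one temporally valid tweet.
#' @param include_retweets Include retweets (default `FALSE`).
#' @param missing_offset See [local_time()].
#' @return A `temporal_profile`: list with `by`, `bins`, `per_user` (users x
#'   bins matrix), `mean`, `sem`, `n_users`.
#' @export
hourly_profile <- function(corpus, include_retweets = FALSE,
                           missing_offset = "drop") {
  build_profile(corpus, "hour", include_retweets, missing_offset)
}

#' Weekday activity profile of a corpus
#'
#' As [hourly_profile()] with seven Monday-first bins.
#'
#' @inheritParams hourly_profile
#' @export
weekday_profile <- function(corpus, include_retweets = FALSE,
                            missing_offset = "drop") {
  build_profile(corpus, "weekday", include_retweets, missing_offset)
}

#' @export
print.temporal_profile <- function(x, ...) {
  cat("<temporal_profile>", x$by, "| corpus:", x$label,
      "|", x$n_users, "users\n")
  print(tibble(bin = x$bins, mean = x$mean, sem = x$sem))
  invisible(x)
}

#' @export
#' @method as_tibble temporal_profile
as_tibble.temporal_profile <- function(x, ...) {
  tibble(bin = x$bins, group = x$label, mean = x$mean, sem = x$sem)
}
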