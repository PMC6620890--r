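# Synthetic two-population tweet corpus generator.
#
# Tweets are token sequences drawn from the vocabulary bank, not grammatical
# Spanish: the analysis pipeline operates on token and lexicon statistics, so
# hermetic recovery testing requires exact bookkeeping, not fluency. Every
# lexicon-annotated word in a synthetic tweet is an explicit injection whose
# count and grammatical category are recorded in the truth sidecar.
#
# Preset parameters encode the study contrasts the pipeline is meant to
# detect: the three POS mixtures of the published frequency table; 1S
# pronoun shares 38.37 / 57.59 / 80.00%; negation means 0.28 / 0.49 / 0.67
# per tweet; emotion and polarity rates back-derived from the printed
# prevalences; night-shifted hourly weights and a weekend activity dip
# (x0.6) for controls only. User counts and timeline lengths are scaled to
# study sizes that the recovery and power analyses need (tens of users,
# 10-20k tweets per population).

norm1 <- function(x) x / sum(x)

#' Specify a synthetic tweet population
#'
#' @param label Free-text label.
#' @param n_users Number of users.
#' @param tweets_per_user `c(mean, size)` of a negative binomial (size =
#'   dispersion; larger is less overdispersed), minimum 1 tweet.
#' @param hourly_weights 24 non-negative local-hour weights.
#' @param weekday_weights 7 non-negative weights, Monday first.
#' @param pos_mixture 8 probabilities over the grammatical categories
#'   (noun, verb, pronoun, adjective, determiner, adverb, adposition,
#'   conjunction); normalized internally.
#' @param personal_pronoun_share Probability a drawn pronoun is personal
#'   (the rest are non-personal pronouns).
#' @param pronoun_mixture 6 probabilities over persons (1S, 1P, 2S, 2P, 3S,
#'   3P).
#' @param emotion_rates Per-tweet Bernoulli rates of injecting one word per
#'   emotion, named by emotion.
#' @param negation_rate Mean injected negation cues per tweet (Poisson).
#' @param polarity_mixture Probabilities over per-tweet polarity injection
#'   classes `c(positive, negative, graded, none)`.
#' @param graded_negative_share Probability an injected graded word is
#'   negative-valued.
#' @param graded_moderate_share Probability an injected graded word is
#'   moderate (|value| < 0.5) rather than strong.
#' @param keyword_rate Mean injected depression keywords per tweet
#'   (Poisson); non-zero only for flagged-tweet generation.
#' @param length_tokens `c(mean, sd)` of the base token count per tweet
#'   (truncated at 1).
#' @param entity_rates Per-tweet Bernoulli rates, named `hashtag`, `link`,
#'   `mention`, `emoji`.
#' @param retweet_fraction Fraction of timeline tweets that are retweets.
#' @param utc_offset_seconds User timezone offset.
#' @param missing_offset_fraction Fraction of users with no stored offset.
#' @param profile_type `"control"` or `"depressive"` profile-description
#'   templates.
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(label = "population",
                            n_users = 50L,
                            tweets_per_user = c(mean = 200, size = 5),
                            hourly_weights = rep(1, 24),
                            weekday_weights = rep(1, 7),
                            pos_mixture = rep(1 / 8, 8),
                            personal_pronoun_share = 0.52,
                            pronoun_mixture = rep(1 / 6, 6),
                            emotion_rates = setNames(rep(0.05, 6), EMOTIONS),
                            negation_rate = 0.25,
                            polarity_mixture = c(positive = 0.15,
                                                 negative = 0.15,
                                                 graded = 0.2, none = 0.5),
                            graded_negative_share = 0.5,
                            graded_moderate_share = 0.5,
                            keyword_rate = 0,
                            length_tokens = c(mean = 12, sd = 5),
                            entity_rates = c(hashtag = 0.1, link = 0.2,
                                             mention = 0.2, emoji = 0.1),
                            retweet_fraction = 0.25,
                            utc_offset_seconds = 3600L,
                            missing_offset_fraction = 0,
                            profile_type = c("control", "depressive")) {
  profile_type <- match.arg(profile_type)
  stopifnot(length(hourly_weights) == 24, length(weekday_weights) == 7,
            length(pos_mixture) == 8, length(pronoun_mixture) == 6,
            all(hourly_weights >= 0), all(weekday_weights >= 0),
            negation_rate >= 0, keyword_rate >= 0,
            all(emotion_rates >= 0), all(emotion_rates <= 1),
            personal_pronoun_share >= 0, personal_pronoun_share <= 1,
            graded_negative_share >= 0, graded_negative_share <= 1)
  structure(list(
    label = label, n_users = as.integer(n_users),
    tweets_per_user = tweets_per_user,
    hourly_weights = norm1(hourly_weights),
    weekday_weights = norm1(weekday_weights),
    pos_mixture = setNames(norm1(pos_mixture), POS_CATEGORIES),
    personal_pronoun_share = personal_pronoun_share,
    pronoun_mixture = setNames(norm1(pronoun_mixture), PRONOUN_PERSONS),
    emotion_rates = setNames(as.numeric(emotion_rates), EMOTIONS),
    negation_rate = negation_rate,
    polarity_mixture = setNames(norm1(polarity_mixture),
                                c("positive", "negative", "graded", "none")),
    graded_negative_share = graded_negative_share,
    graded_moderate_share = graded_moderate_share,
    keyword_rate = keyword_rate,
    length_tokens = length_tokens,
    entity_rates = entity_rates,
    retweet_fraction = retweet_fraction,
    utc_offset_seconds = as.integer(utc_offset_seconds),
    missing_offset_fraction = missing_offset_fraction,
    profile_type = profile_type
  ), class = "population_spec")
}

#' Preset population specifications
#'
#' `control_spec()` encodes the control-population conditions;
#' `depressive_spec()` the depressive-user population; and
#' `depressive_tweets_spec()` the generation profile of flagged depressive
#' tweets (used for the flagged subset inside depressive timelines). See the
#' methods vignette for the provenance of each default.
#'
#' @param n_users Number of users.
#' @param tweets_per_user Negative-binomial `c(mean, size)`.
#' @param ... Overrides passed to [population_spec()].
#' @return A `population_spec`.
#' @export
control_spec <- function(n_users = 50L, tweets_per_user = c(200, 5), ...) {
  args <- list(
    label = "control", n_users = n_users,
    tweets_per_user = tweets_per_user,
    hourly_weights = c(2, 1, 0.7, 0.5, 0.4, 0.5, 1, 2, 3.5, 4.5, 5, 5.5,
                       5.5, 5, 4.5, 4.5, 5, 5.5, 6, 7.5, 7, 6.5, 5.5, 3.5),
    weekday_weights = c(1, 1, 1, 1, 1, 0.6, 0.6),
    pos_mixture = c(0.2848, 0.2058, 0.0955, 0.0735, 0.1323, 0.0616,
                    0.1059, 0.0406),
    personal_pronoun_share = 0.5138,
    pronoun_mixture = c(0.3837, 0.05, 0.18, 0.02, 0.27, 0.0963),
    emotion_rates = c(happiness = 0.285, sadness = 0.094, anger = 0.05,
                      fear = 0.04, disgust = 0.02, surprise = 0.045),
    negation_rate = 0.28,
    polarity_mixture = c(positive = 0.189, negative = 0.146,
                         graded = 0.21, none = 0.455),
    graded_negative_share = 0.435,
    keyword_rate = 0,
    length_tokens = c(mean = 14, sd = 5),
    entity_rates = c(hashtag = 0.1313, link = 0.3532, mention = 0.44,
                     emoji = 0.1361),
    retweet_fraction = 0.3755,
    utc_offset_seconds = 7200L,
    profile_type = "control"
  )
  utils::modifyList(args, list(...)) |> do.call(what = population_spec)
}

#' @rdname control_spec
#' @export
depressive_spec <- function(n_users = 50L, tweets_per_user = c(140, 5),
                            ...) {
  args <- list(
    label = "depressive", n_users = n_users,
    tweets_per_user = tweets_per_user,
    hourly_weights = c(6, 5.5, 5, 4.5, 4, 3.8, 4, 3.5, 3, 3, 3, 3.2, 3.2,
                       3, 3, 3, 3.2, 3.5, 3.8, 4, 4.5, 5, 5.5, 6.5),
    weekday_weights = c(1.05, 1, 1, 1, 1, 1.05, 1.05),
    pos_mixture = c(0.1777, 0.2636, 0.1486, 0.0547, 0.1170, 0.0927,
                    0.0815, 0.0642),
    personal_pronoun_share = 0.5516,
    pronoun_mixture = c(0.5759, 0.02, 0.13, 0.01, 0.20, 0.0641),
    emotion_rates = c(happiness = 0.287, sadness = 0.176, anger = 0.09,
                      fear = 0.045, disgust = 0.05, surprise = 0.04),
    negation_rate = 0.49,
    polarity_mixture = c(positive = 0.191, negative = 0.222,
                         graded = 0.293, none = 0.294),
    graded_negative_share = 0.54,
    keyword_rate = 0,
    length_tokens = c(mean = 11, sd = 5),
    entity_rates = c(hashtag = 0.0144, link = 0.1807, mention = 0.0927,
                     emoji = 0.0572),
    retweet_fraction = 0.2569,
    utc_offset_seconds = 7200L,
    profile_type = "depressive"
  )
  utils::modifyList(args, list(...)) |> do.call(what = population_spec)
}

#' @rdname control_spec
#' @export
depressive_tweets_spec <- function(...) {
  args <- list(
    label = "depressive_tweets", n_users = 1L,
    tweets_per_user = c(10, 5),
    pos_mixture = c(0.1507, 0.2877, 0.1380, 0.0499, 0.1139, 0.1146,
                    0.0893, 0.0559),
    personal_pronoun_share = 0.5316,
    pronoun_mixture = c(0.80, 0.004, 0.07, 0.004, 0.09, 0.032),
    emotion_rates = c(happiness = 0.18, sadness = 0.303, anger = 0.15,
                      fear = 0.08, disgust = 0.09, surprise = 0.06),
    negation_rate = 0.67,
    polarity_mixture = c(positive = 0.206, negative = 0.383,
                         graded = 0.333, none = 0.078),
    graded_negative_share = 0.65,
    keyword_rate = 1.2,
    length_tokens = c(mean = 11, sd = 5),
    entity_rates = c(hashtag = 0.01, link = 0.05, mention = 0.05,
                     emoji = 0.05),
    retweet_fraction = 0,
    utc_offset_seconds = 7200L,
    profile_type = "depressive"
  )
  utils::modifyList(args, list(...)) |> do.call(what = population_spec)
}

PROFILE_TEMPLATES <- list(
  depressive = c(
    "Paciente con depresión crónica",
    "Luchando contra la depre cada día",
    "Diagnóstico: depresivo y en tratamiento",
    "Escribo para sobrevivir, deprimida desde hace años",
    "Vivo con depresión y lo cuento aquí"
  ),
  control = c(
    "Amante de la música y los gatos",
    "Fotografía, viajes y café",
    "Estudiante de historia",
    "Fan del fútbol y la buena comida",
    "Aquí por los memes"
  )
)

SYNTH_EMOJIS <- c("\U0001F600", "\U0001F622", "❤️",
                  "\U0001F64C", "\U0001F621")

empty_truth_counts <- function(n) {
  out <- tibble(.rows = n)
  for (cat in POS_CATEGORIES) out[[paste0("pos_", cat)]] <- 0L
  for (p in PRONOUN_PERSONS) out[[paste0("per_", p)]] <- 0L
  for (e in EMOTIONS) out[[paste0("emo_", e)]] <- 0L
  out$neg_injected <- 0L
  out$kw_injected <- 0L
  out$polarity_class <- "none"
  out$n_tokens <- 0L
  out
}

# Generate n tweets of text plus their per-tweet truth counts. Assumes an
# already-seeded RNG stream.
gen_tweet_texts <- function(spec, bank, n) {
  truth <- empty_truth_counts(n)
  if (n == 0) return(list(text = character(), truth = truth))
  lp <- spec$length_tokens
  L <- pmax(1L, as.integer(round(rnorm(n, lp[["mean"]], lp[["sd"]]))))
  tweet_of <- rep(seq_len(n), L)
  cats <- sample(POS_CATEGORIES, sum(L), replace = TRUE,
                 prob = spec$pos_mixture)
  words <- character(length(cats))
  persons <- rep(NA_character_, length(cats))
  for (cat in setdiff(POS_CATEGORIES, "pronoun")) {
    idx <- which(cats == cat)
    if (length(idx) > 0) {
      words[idx] <- sample(bank$plain[[cat]], length(idx), replace = TRUE)
    }
  }
  pr_idx <- which(cats == "pronoun")
  if (length(pr_idx) > 0) {
    personal <- stats::runif(length(pr_idx)) < spec$personal_pronoun_share
    if (any(personal)) {
      pp <- sample(PRONOUN_PERSONS, sum(personal), replace = TRUE,
                   prob = spec$pronoun_mixture)
      words[pr_idx[personal]] <- vapply(pp, function(p) {
        sample(bank$pronouns[[p]], 1)
      }, character(1))
      persons[pr_idx[personal]] <- pp
    }
    if (any(!personal)) {
      words[pr_idx[!personal]] <- sample(bank$nonpersonal_pronouns,
                                         sum(!personal), replace = TRUE)
    }
  }
  tok_tweet <- tweet_of
  tok_word <- words
  tok_cat <- cats
  tok_person <- persons

  add_tokens <- function(tw, wd, ct, pe = NA_character_) {
    tok_tweet <<- c(tok_tweet, tw)
    tok_word <<- c(tok_word, wd)
    tok_cat <<- c(tok_cat, rep(ct, length.out = length(tw)))
    tok_person <<- c(tok_person, rep(pe, length.out = length(tw)))
  }

  pos_of_word <- setNames(bank$tagged$pos, bank$tagged$word)

  # negation cues (Poisson per tweet)
  neg_k <- rpois(n, spec$negation_rate)
  if (sum(neg_k) > 0) {
    tw <- rep(seq_len(n), neg_k)
    wd <- sample(bank$negations, sum(neg_k), replace = TRUE)
    add_tokens(tw, wd, unname(pos_of_word[wd]))
  }
  truth$neg_injected <- as.integer(neg_k)

  # one word per emotion with per-emotion Bernoulli rates
  for (e in EMOTIONS) {
    hit <- rbinom(n, 1, spec$emotion_rates[[e]]) == 1
    if (any(hit)) {
      terms <- bank$emotions$term[bank$emotions$emotion == e]
      wd <- sample(terms, sum(hit), replace = TRUE)
      add_tokens(which(hit), wd, unname(pos_of_word[wd]))
      truth[[paste0("emo_", e)]] <- as.integer(hit)
    }
  }

  # at most one polarity injection per tweet
  pol_class <- sample(names(spec$polarity_mixture), n, replace = TRUE,
                      prob = spec$polarity_mixture)
  truth$polarity_class <- pol_class
  for (cls in c("positive", "negative")) {
    hit <- pol_class == cls
    if (any(hit)) {
      terms <- bank$polarity_binary$term[
        sign(bank$polarity_binary$value) == (if (cls == "positive") 1 else -1)]
      wd <- sample(terms, sum(hit), replace = TRUE)
      add_tokens(which(hit), wd, unname(pos_of_word[wd]))
    }
  }
  gr <- pol_class == "graded"
  if (any(gr)) {
    neg_sign <- stats::runif(sum(gr)) < spec$graded_negative_share
    moderate <- stats::runif(sum(gr)) < spec$graded_moderate_share
    gt <- bank$polarity_graded
    wd <- vapply(seq_len(sum(gr)), function(i) {
      pool <- gt$term[(gt$value < 0) == neg_sign[i] &
                        (abs(gt$value) < 0.5) == moderate[i]]
      sample(pool, 1)
    }, character(1))
    add_tokens(which(gr), wd, unname(pos_of_word[wd]))
  }

  # depression keywords (flagged-tweet generation only)
  if (spec$keyword_rate > 0) {
    kw_k <- rpois(n, spec$keyword_rate)
    if (sum(kw_k) > 0) {
      tw <- rep(seq_len(n), kw_k)
      wd <- sample(bank$keywords$form, sum(kw_k), replace = TRUE)
      add_tokens(tw, wd, unname(pos_of_word[wd]))
    }
    truth$kw_injected <- as.integer(kw_k)
  }

  # entity tokens (not words: invisible to POS/lexicon bookkeeping)
  ent <- spec$entity_rates
  ent_tokens <- list(
    hashtag = function(k) paste0("#", sample(bank$plain$noun, k,
                                             replace = TRUE)),
    link = function(k) paste0("https://t.co/",
                              stringi::stri_rand_strings(k, 8, "[a-z0-9]")),
    mention = function(k) paste0("@usuario",
                                 sample(1:999, k, replace = TRUE)),
    emoji = function(k) sample(SYNTH_EMOJIS, k, replace = TRUE)
  )
  for (nm in names(ent_tokens)) {
    hit <- rbinom(n, 1, ent[[nm]]) == 1
    if (any(hit)) {
      add_tokens(which(hit), ent_tokens[[nm]](sum(hit)), "entity")
    }
  }

  # aggregate truth counts and assemble shuffled texts
  word_mask <- tok_cat != "entity"
  pos_tab <- table(factor(tok_tweet[word_mask], levels = seq_len(n)),
                   factor(tok_cat[word_mask], levels = POS_CATEGORIES))
  for (cat in POS_CATEGORIES) {
    truth[[paste0("pos_", cat)]] <- as.integer(pos_tab[, cat])
  }
  has_person <- !is.na(tok_person)
  per_tab <- table(factor(tok_tweet[has_person], levels = seq_len(n)),
                   factor(tok_person[has_person], levels = PRONOUN_PERSONS))
  for (p in PRONOUN_PERSONS) {
    truth[[paste0("per_", p)]] <- as.integer(per_tab[, p])
  }
  truth$n_tokens <- as.integer(tabulate(tok_tweet, nbins = n))

  ord <- order(tok_tweet, stats::runif(length(tok_tweet)))
  text <- vapply(split(tok_word[ord], factor(tok_tweet[ord],
                                             levels = seq_len(n))),
                 paste, character(1), collapse = " ")
  list(text = unname(text), truth = truth)
}

STUDY_EPOCH <- "2018-01-01"  # a Monday; 26-week generation window

gen_tweet_times <- function(spec, n) {
  wd <- sample(1:7, n, replace = TRUE, prob = spec$weekday_weights)
  week <- sample(0:25, n, replace = TRUE)
  hour <- sample(0:23, n, replace = TRUE, prob = spec$hourly_weights)
  local <- as.POSIXct(STUDY_EPOCH, tz = "UTC") +
    ((week * 7 + wd - 1) * 24 + hour) * 3600 +
    sample(0:3599, n, replace = TRUE)
  local
}

#' Generate one synthetic user and timeline
#'
#' Tweet times are drawn from the hourly-by-weekday weights over a 26-week
#' window in the user's local time and stored in UTC; the token stream and
#' injections follow the population spec; the per-tweet injected counts are
#' returned as the truth record.
#'
#' @param spec A `population_spec`.
#' @param bank A `tv_vocabulary`.
#' @param user_index Index of the user within the population.
#' @param seed Master seed; the user's substream is derived from
#'   `(seed, user_index)`.
#' @param user_id Optional explicit user id.
#' @return List with `profile` (one-row tibble), `tweets` (tweets tibble as
#'   in [corpus()]), `truth` (per-tweet truth tibble).
#' @export
generate_user <- function(spec, bank, user_index = 1L, seed = 1L,
                          user_id = NULL) {
  stopifnot(inherits(spec, "population_spec"),
            inherits(bank, "tv_vocabulary"))
  user_id <- user_id %||% sprintf("%s_u%04d", spec$label, user_index)
  with_seed(substream_seed(seed, user_index), {
    nb <- spec$tweets_per_user
    n <- max(1L, rnbinom(1, size = nb[[2]], mu = nb[[1]]))
    gen <- gen_tweet_texts(spec, bank, n)
    local <- sort(gen_tweet_times(spec, n), decreasing = TRUE)
    offset <- if (stats::runif(1) < spec$missing_offset_fraction) {
      NA_integer_
    } else {
      spec$utc_offset_seconds
    }
    is_rt <- rbinom(n, 1, spec$retweet_fraction) == 1
    tweets <- tibble(
      tweet_id = sprintf("%s_t%05d", user_id, seq_len(n)),
      user_id = user_id,
      text = gen$text,
      created_at_utc = local - (if (is.na(offset)) 0L else offset),
      utc_offset_seconds = offset,
      is_retweet = is_rt,
      lang = "es"
    )
    truth <- gen$truth
    truth$tweet_id <- tweets$tweet_id
    truth$user_id <- user_id
    truth$retweet <- is_rt
    profile <- tibble(
      user_id = user_id,
      description = sample(PROFILE_TEMPLATES[[spec$profile_type]], 1)
    )
    list(profile = profile, tweets = tweets, truth = truth)
  })
}

generate_population <- function(spec, bank, seed, index_offset = 0L) {
  users <- lapply(seq_len(spec$n_users), function(i) {
    generate_user(spec, bank, i, seed = substream_seed(seed, index_offset),
                  user_id = sprintf("%s_u%04d", spec$label, i))
  })
  list(
    profiles = bind_rows(lapply(users, `[[`, "profile")),
    tweets = bind_rows(lapply(users, `[[`, "tweets")),
    truth = bind_rows(lapply(users, `[[`, "truth"))
  )
}

#' Generate a full synthetic study
#'
#' Produces the three assembled corpora (control, depressive users,
#' depressive tweets) plus the truth sidecar. Flagged tweets are a random
#' subset of each depressive user's non-retweet timeline, regenerated from
#' `flagged_spec` (which oversamples depression keywords); their ids are the
#' flagged set, so the assembled corpora satisfy the screening-module
#' disjointness by construction. Identical arguments give identical output.
#'
#' @param control A `population_spec` for the control population.
#' @param depressive A `population_spec` for the depressive population.
#' @param flagged_spec Generation profile of flagged tweets.
#' @param flagged_fraction Binomial fraction of each depressive user's
#'   non-retweet tweets that are flagged (default 0.08, about 11 flagged
#'   tweets per user at the default timeline length).
#' @param seed Master seed.
#' @param bank Vocabulary bank.
#' @param out_dir If non-NULL, writes `control.jsonl`,
#'   `depressive_users.jsonl`, `depressive_tweets.jsonl` and `truth.json`
#'   there.
#' @return List with `corpora` (named list of three `tweet_corpus`),
#'   `truth` (list: `params`, `tweets` per-tweet truth tibble, `flagged_ids`,
#'   `peak_hours` per population).
#' @export
generate_study <- function(control = control_spec(),
                           depressive = depressive_spec(),
                           flagged_spec = depressive_tweets_spec(),
                           flagged_fraction = 0.08,
                           seed = 1L,
                           bank = build_vocabulary(),
                           out_dir = NULL) {
  stopifnot(flagged_fraction >= 0, flagged_fraction <= 1)
  ctrl <- generate_population(control, bank, seed, index_offset = 1L)
  depr <- generate_population(depressive, bank, seed, index_offset = 2L)

  # flag a subset of each depressive user's non-retweet tweets and
  # regenerate their text from the flagged-tweet profile
  flagged_ids <- character()
  depr_users <- unique(depr$tweets$user_id)
  for (ui in seq_along(depr_users)) {
    uid <- depr_users[ui]
    rows <- which(depr$tweets$user_id == uid & !depr$tweets$is_retweet)
    with_seed(substream_seed(seed, 3000000L + ui), {
      n_flag <- rbinom(1, length(rows), flagged_fraction)
      if (n_flag > 0) {
        picked <- sample(rows, n_flag)
        regen <- gen_tweet_texts(flagged_spec, bank, n_flag)
        depr$tweets$text[picked] <- regen$text
        ids <- depr$tweets$tweet_id[picked]
        regen$truth$tweet_id <- ids
        regen$truth$user_id <- uid
        regen$truth$retweet <- FALSE
        keep <- !depr$truth$tweet_id %in% ids
        depr$truth <- bind_rows(depr$truth[keep, ], regen$truth)
        flagged_ids <- c(flagged_ids, ids)
      }
    })
  }

  depr_corpus <- corpus("depressive_users", depr$tweets, depr$profiles)
  ctrl_corpus <- corpus("control", ctrl$tweets, ctrl$profiles)
  corpora <- assemble_datasets(depr_corpus, flagged_ids, ctrl_corpus)

  truth_tweets <- bind_rows(
    mutate(ctrl$truth, population = "control", flagged = FALSE),
    mutate(depr$truth, population = "depressive",
           flagged = .data$tweet_id %in% flagged_ids)
  )
  truth <- list(
    params = list(control = unclass(control),
                  depressive = unclass(depressive),
                  flagged = unclass(flagged_spec),
                  flagged_fraction = flagged_fraction, seed = seed),
    tweets = truth_tweets,
    flagged_ids = flagged_ids,
    # hours carrying >= 90% of the maximal weight: the expected modal set
    peak_hours = list(
      control = which(control$hourly_weights >=
                        0.9 * max(control$hourly_weights)) - 1L,
      depressive = which(depressive$hourly_weights >=
                           0.9 * max(depressive$hourly_weights)) - 1L
    )
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_corpus(corpora$control, file.path(out_dir, "control.jsonl"))
    write_corpus(corpora$depressive_users,
                 file.path(out_dir, "depressive_users.jsonl"))
    write_corpus(corpora$depressive_tweets,
                 file.path(out_dir, "depressive_tweets.jsonl"))
    jsonlite::write_json(
      list(params = truth$params, flagged_ids = truth$flagged_ids,
           peak_hours = truth$peak_hours,
           tweets = truth$tweets),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA,
      POSIXt = "ISO8601")
    tv_log("synthetic study written to ", out_dir)
  }

  list(corpora = corpora, truth = truth)
}

#' Aggregate truth rates for a set of tweets
#'
#' Summarises the generating bookkeeping (actual drawn counts) over a subset
#' of the truth table, for comparison with pipeline-recovered quantities.
#'
#' @param truth_tweets Per-tweet truth tibble from [generate_study()].
#' @param ids Optional tweet ids to restrict to (e.g. the tweets surviving
#'   assembly).
#' @return List with `pos_shares`, `person_shares`, `emotion_rates` (per
#'   tweet), `negation_mean`, `binary_prevalence`, `graded_prevalence`,
#'   `n_tweets`.
#' @export
truth_rates <- function(truth_tweets, ids = NULL) {
  tt <- truth_tweets
  if (!is.null(ids)) tt <- tt[tt$tweet_id %in% ids, ]
  pos <- vapply(POS_CATEGORIES, function(cat) sum(tt[[paste0("pos_", cat)]]),
                numeric(1))
  per <- vapply(PRONOUN_PERSONS, function(p) sum(tt[[paste0("per_", p)]]),
                numeric(1))
  emo <- vapply(EMOTIONS, function(e) mean(tt[[paste0("emo_", e)]]),
                numeric(1))
  list(
    pos_shares = pos / sum(pos),
    person_shares = per / sum(per),
    emotion_rates = emo,
    negation_mean = mean(tt$neg_injected),
    binary_prevalence = mean(tt$polarity_class %in%
                               c("positive", "negative")),
    graded_prevalence = mean(tt$polarity_class == "graded"),
    n_tweets = nrow(tt)
  )
}
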