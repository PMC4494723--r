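#' Configuration for the synthetic tweet-corpus generator
#'
#' Describes the generative conditions the pipeline is exercised under: a
#' population of users, a regional fraction, an inhomogeneous tweeting
#' point process (sinusoidal diurnal cycle times a post-event spike that
#' decays exponentially, regional users only), profile fields drawn from
#' term pools with missingness, geotags inside/outside the region polygons,
#' retweet/hashtag/mention planting, and a homonym confounder location
#' (the Petal / Petaling failure mode). Defaults emulate the 2013
#' Hattiesburg tornado regime: an 11-day span around a 96-hour analysis
#' window, ~30% regional users, ~1.2 tweets/user/day, a 3x spike decaying
#' with a 24 h half-life, and missingness/GPS rates matching the reported
#' profile-completeness figures.
#'
#' @param n_users Number of simulated accounts.
#' @param regional_fraction Fraction of truly regional users.
#' @param span_start,span_end Corpus span, UTC instants.
#' @param event_time Event instant within the span.
#' @param base_rate Baseline tweets per user per day.
#' @param diurnal_amplitude Relative amplitude of the diurnal cycle in
#'   `[0, 1)`.
#' @param event_spike_multiplier Peak post-event intensity multiplier
#'   (>= 1), applied to regional users.
#' @param spike_halflife_h Half-life of the spike decay, hours.
#' @param retweet_fraction,hashtag_fraction Per-tweet planting rates.
#' @param gps_enabled_fraction Fraction of users with geolocation enabled.
#' @param gps_geotag_fraction Per-tweet geotag rate for enabled users.
#' @param gps_noise_outside_fraction Fraction of regional geotags planted
#'   outside the region polygons (travel noise).
#' @param news_mention_fraction Per-tweet probability that a regional user
#'   mentions a regional news handle.
#' @param nonregional_news_mention_fraction Same for non-regional users
#'   (contamination; the rare false positive a QA review would catch).
#' @param nonregional_keyword_fraction Per-tweet probability that a
#'   non-regional user's text carries an event keyword (global trending
#'   chatter the broad extraction filter picks up).
#' @param bio_term_pool,location_term_pool Profile strings for regional
#'   users; must trip the criterion terms for ground-truth recovery.
#' @param news_handle_pool Regional news handles.
#' @param nonregional_bio_pool,nonregional_location_pool Profile strings
#'   for non-regional users; must avoid the criterion terms.
#' @param confounder_locations Homonym location strings given to the
#'   confounder subpopulation.
#' @param confounder_fraction Fraction of non-regional users that are
#'   homonym confounders.
#' @param missing_bio_fraction,missing_location_fraction Regional-user
#'   profile missingness rates.
#' @param local_utc_offset_h Local-time offset used for the diurnal phase.
#' @param seed Integer master seed; generation is namespaced per user so a
#'   corpus is byte-reproducible and stable under unrelated config edits.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(
    n_users = 10000,
    regional_fraction = 0.3,
    span_start = as_utc("2013-02-05T23:00:00Z"),
    span_end = as_utc("2013-02-15T23:00:00Z"),
    event_time = as_utc("2013-02-10T23:00:00Z"),
    base_rate = 1.2,
    diurnal_amplitude = 0.5,
    event_spike_multiplier = 3,
    spike_halflife_h = 24,
    retweet_fraction = 0.33,
    hashtag_fraction = 0.24,
    gps_enabled_fraction = 0.06,
    gps_geotag_fraction = 0.5,
    gps_noise_outside_fraction = 0.03,
    news_mention_fraction = 0.04,
    nonregional_news_mention_fraction = 0.001,
    nonregional_keyword_fraction = 0.05,
    bio_term_pool = c("Proud Mississippi native", "Hattiesburg born and raised",
                      "USM student", "SMTTT all day", "Sweet Home Alabama",
                      "Birmingham foodie", "Ole Miss fan"),
    location_term_pool = c("Hattiesburg, MS", "Petal, MS", "Jackson, Mississippi",
                           "Birmingham, AL", "Mobile, Alabama",
                           "Hattiesburg, MS 39401", "Tuscaloosa, AL"),
    news_handle_pool = default_news_handles(),
    nonregional_bio_pool = c("dreamer", "coffee lover", "living my best life",
                             "sports and music"),
    nonregional_location_pool = c("Springfield, USA", "London, UK",
                                  "Toronto, Canada", "worldwide", "NYC"),
    confounder_locations = "Petaling Jaya, Malaysia",
    confounder_fraction = 0.2,
    missing_bio_fraction = 0.14,
    missing_location_fraction = 0.04,
    local_utc_offset_h = -6,
    seed = 20130210) {
  cfg <- as.list(environment())
  fracs <- c("regional_fraction", "retweet_fraction", "hashtag_fraction",
             "gps_enabled_fraction", "gps_geotag_fraction",
             "gps_noise_outside_fraction", "news_mention_fraction",
             "nonregional_news_mention_fraction", "nonregional_keyword_fraction",
             "confounder_fraction",
             "missing_bio_fraction", "missing_location_fraction")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) abort(paste0(f, " must be in [0, 1]"))
  }
  if (cfg$diurnal_amplitude < 0 || cfg$diurnal_amplitude >= 1) {
    abort("diurnal_amplitude must be in [0, 1)")
  }
  if (cfg$event_spike_multiplier < 1) abort("event_spike_multiplier must be >= 1")
  if (cfg$base_rate <= 0 || cfg$spike_halflife_h <= 0) {
    abort("base_rate and spike_halflife_h must be positive")
  }
  if (!(cfg$span_start < cfg$event_time && cfg$event_time < cfg$span_end)) {
    abort("event_time must lie within the span")
  }
  if (cfg$regional_fraction > 0 &&
      (length(cfg$bio_term_pool) == 0 || length(cfg$location_term_pool) == 0)) {
    abort("regional term pools must be nonempty when regional_fraction > 0")
  }
  if (cfg$n_users < 1) abort("n_users must be >= 1")
  cfg$n_users <- as.integer(cfg$n_users)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "synthetic_config")
}

#' Named generator presets
#'
#' * `"paper_regime"` — the default conditions at full scale (10^4 users,
#'   ~10^5 tweets over the 11-day span).
#' * `"scaled_regime"` — the same conditions at 3,000 users, the size used
#'   by the analysis scripts.
#' * `"demo"` — 500 users for examples and fast tests.
#' * `"noise_free"` — 500 users with profile pools equal to the verbatim
#'   criterion term lists, zero missingness, zero GPS noise, and zero
#'   non-regional news mentions (homonym confounders retained), the regime
#'   under which triangulation must recover ground truth exactly.
#'
#' @param name Preset name.
#' @param ... Overrides forwarded to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
synthetic_profile <- function(name = c("paper_regime", "scaled_regime",
                                       "demo", "noise_free"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    paper_regime = list(),
    scaled_regime = list(n_users = 3000),
    demo = list(n_users = 500),
    noise_free = list(
      n_users = 500,
      bio_term_pool = c("Mississippi", "Alabama", "Hattiesburg", "Birmingham",
                        "USM", "Ole Miss", "SMTTT"),
      location_term_pool = c("Mississippi", "Alabama", "Hattiesburg",
                             "Birmingham", "MS", "AL", "39401", "USM",
                             "Ole Miss", "SMTTT"),
      missing_bio_fraction = 0, missing_location_fraction = 0,
      gps_noise_outside_fraction = 0,
      nonregional_news_mention_fraction = 0)
  )
  do.call(synthetic_config, utils::modifyList(base, list(...)))
}

REGIONAL_TZ <- c("Central Time (US & Canada)", NA, "Mountain Time (US & Canada)",
                 "Eastern Time (US & Canada)", "Pacific Time (US & Canada)",
                 "Quito")
REGIONAL_TZ_P <- c(0.51, 0.27, 0.08, 0.07, 0.03, 0.04)
NONREG_TZ <- c(NA, "Eastern Time (US & Canada)", "Pacific Time (US & Canada)",
               "London", "Kuala Lumpur")
NONREG_TZ_P <- c(0.35, 0.25, 0.15, 0.15, 0.10)
APP_POOL <- c("Twitter for iPhone", "Twitter for Android",
              "Twitter for BlackBerry", "web", "TweetDeck", "Instagram",
              "foursquare", "UberSocial", "Twitterrific", "Echofon")
APP_P <- c(0.33, 0.25, 0.09, 0.18, 0.05, 0.04, 0.02, 0.02, 0.01, 0.01)
REGIONAL_WORDS <- c("tornado", "storm", "shelter", "stay", "safe", "power",
                    "out", "school", "closed", "roof", "damage", "hattiesburg")
NONREG_WORDS <- c("coffee", "game", "music", "lol", "work", "monday",
                  "weekend", "dinner")
CONFOUNDER_WORDS <- c("makan", "jalan", "petaling", "selamat", "pagi", "kerja")
REGIONAL_TAGS <- c("prayforhattiesburg", "tornado", "mstornado", "hburgstrong")
NONREG_TAGS <- c("nowplaying", "love", "jobs", "fail")

#' Generate a ground-truth-labeled synthetic tweet corpus
#'
#' Tweet times come from an inhomogeneous Poisson process simulated by
#' thinning against the maximum intensity: baseline rate x sinusoidal
#' diurnal cycle (peaking mid-afternoon local time) x, for regional users
#' after the event, a multiplicative spike decaying with the configured
#' half-life. Profile fields, geotags, retweets, hashtags and news mentions
#' are planted at the configured rates; each user's randomness is seeded
#' independently from the master seed, so the corpus is byte-reproducible.
#'
#' @param config A [synthetic_config()].
#' @return A list with `records` (a [tweet_records] tibble), `truth` (list:
#'   `users` — per-user labels for users that emitted at least one tweet;
#'   `records` — per-tweet `in_region_geo`; `tallies` — planted per-window
#'   counts for the default analysis window), and `config`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  span_h <- as.numeric(difftime(cfg$span_end, cfg$span_start, units = "hours"))
  ev_h <- as.numeric(difftime(cfg$event_time, cfg$span_start, units = "hours"))
  start_local_hour <- (as.integer(format(cfg$span_start, "%H", tz = "UTC")) +
                         cfg$local_utc_offset_h) %% 24
  lambda0 <- cfg$base_rate / 24  # per hour
  amp <- cfg$diurnal_amplitude
  mult <- cfg$event_spike_multiplier

  per_user <- vector("list", cfg$n_users)
  users_out <- vector("list", cfg$n_users)
  for (u in seq_len(cfg$n_users)) {
    user_seed <- (cfg$seed + u * 7919) %% 2147483647L
    res <- local_seed(user_seed, {
      uid <- sprintf("u%05d", u)
      is_regional <- runif(1) < cfg$regional_fraction
      confounder <- !is_regional && runif(1) < cfg$confounder_fraction
      gps_enabled <- runif(1) < cfg$gps_enabled_fraction

      bio <- if (is_regional) {
        if (runif(1) < cfg$missing_bio_fraction) NA_character_
        else sample(cfg$bio_term_pool, 1)
      } else if (runif(1) < 0.3) NA_character_ else sample(cfg$nonregional_bio_pool, 1)
      loc <- if (is_regional) {
        if (runif(1) < cfg$missing_location_fraction) NA_character_
        else sample(cfg$location_term_pool, 1)
      } else if (confounder) {
        sample(cfg$confounder_locations, 1)
      } else if (runif(1) < 0.2) NA_character_ else sample(cfg$nonregional_location_pool, 1)
      tz <- if (is_regional) sample(REGIONAL_TZ, 1, prob = REGIONAL_TZ_P)
            else sample(NONREG_TZ, 1, prob = NONREG_TZ_P)
      acct <- cfg$span_start - runif(1, 100, 2000) * 86400
      followers <- as.integer(round(exp(rnorm(1, log(300), 1))))
      friends <- as.integer(round(exp(rnorm(1, log(350), 0.8))))
      influence <- round(min(95, max(1, rnorm(1, 33, 10))))
      verified <- runif(1) < 0.002
      language <- sample(c("en", "es", "ms", "fr"), 1,
                         prob = if (is_regional) c(0.97, 0.015, 0.005, 0.01)
                                else c(0.85, 0.05, 0.07, 0.03))
      app <- sample(APP_POOL, 1, prob = APP_P)

      # tweet times by thinning
      m_u <- if (is_regional) mult else 1
      lmax <- lambda0 * (1 + amp) * m_u
      n_cand <- rpois(1, lmax * span_h)
      t_cand <- sort(runif(n_cand, 0, span_h))
      hr_local <- (start_local_hour + t_cand) %% 24
      diurnal <- 1 + amp * sin(2 * pi * (hr_local - 9) / 24)
      spike <- rep(1, n_cand)
      if (is_regional && m_u > 1) {
        after <- t_cand >= ev_h
        spike[after] <- 1 + (m_u - 1) * 2^(-(t_cand[after] - ev_h) / cfg$spike_halflife_h)
      }
      accept <- runif(n_cand) < (diurnal * spike) / ((1 + amp) * m_u)
      t <- t_cand[accept]
      n_t <- length(t)
      if (n_t == 0) {
        list(user = tibble::tibble(user_id = uid, is_regional = is_regional,
                                   confounder = confounder,
                                   gps_enabled = gps_enabled, n_tweets = 0L),
             rec = NULL)
      } else {
        has_tag <- runif(n_t) < cfg$hashtag_fraction
        is_rt <- runif(n_t) < cfg$retweet_fraction
        p_news <- if (is_regional) cfg$news_mention_fraction
                  else cfg$nonregional_news_mention_fraction
        news_mn <- runif(n_t) < p_news
        has_geo <- gps_enabled & runif(n_t) < cfg$gps_geotag_fraction

        tag_pool <- if (is_regional) REGIONAL_TAGS else NONREG_TAGS
        word_pool <- if (is_regional) REGIONAL_WORDS
                     else if (confounder) CONFOUNDER_WORDS else NONREG_WORDS
        tags <- ifelse(has_tag, sample(tag_pool, n_t, replace = TRUE), NA_character_)
        news_handle <- ifelse(news_mn,
                              sample(cfg$news_handle_pool, n_t, replace = TRUE),
                              NA_character_)
        friend_handle <- sprintf("friend_%04d", sample.int(5000, n_t, replace = TRUE))
        rt_user <- rep(NA_character_, n_t)
        if (any(is_rt)) {
          rt_news <- is_rt & is_regional & runif(n_t) < 0.5
          rt_user[is_rt] <- friend_handle[is_rt]
          if (any(rt_news)) {
            rt_user[rt_news] <- sample(cfg$news_handle_pool, sum(rt_news), replace = TRUE)
          }
        }
        geo_lat <- rep(NA_real_, n_t); geo_lon <- rep(NA_real_, n_t)
        in_region_geo <- rep(NA, n_t)
        if (any(has_geo)) {
          k <- sum(has_geo)
          if (is_regional) {
            outside <- runif(k) < cfg$gps_noise_outside_fraction
            lon <- runif(k, -91.5, -85.0); lat <- runif(k, 30.3, 34.9)
            lon[outside] <- runif(sum(outside), -80, -70)
            lat[outside] <- runif(sum(outside), 36, 44)
            inreg <- !outside
          } else if (confounder) {
            lon <- runif(k, 101.5, 101.7); lat <- runif(k, 3.0, 3.2)
            inreg <- rep(FALSE, k)
          } else {
            lon <- runif(k, -80, -70); lat <- runif(k, 36, 44)
            inreg <- rep(FALSE, k)
          }
          geo_lon[has_geo] <- lon; geo_lat[has_geo] <- lat
          in_region_geo[has_geo] <- inreg
        }
        words <- vapply(seq_len(n_t), function(i) {
          paste(sample(word_pool, 4, replace = TRUE), collapse = " ")
        }, character(1))
        # outside chatter occasionally uses event keywords (trending topics),
        # so the broad first-pass filter retains some non-regional records
        if (!is_regional) {
          trending <- runif(n_t) < cfg$nonregional_keyword_fraction
          words[trending] <- paste(words[trending], "tornado")
        }
        text <- words
        text <- ifelse(is.na(tags), text, paste0(text, " #", tags))
        text <- ifelse(is.na(news_handle), text, paste0(text, " @", news_handle))
        text <- ifelse(is_rt, paste0("RT @", rt_user, ": ", text), text)
        hashtags <- lapply(tags, function(x) if (is.na(x)) character(0) else x)
        mentions <- Map(function(nh, rt) unique(c(if (!is.na(nh)) nh,
                                                  if (!is.na(rt)) rt)),
                        news_handle, rt_user)
        mentions <- unname(lapply(mentions, function(x) if (is.null(x)) character(0) else x))

        rec <- tibble::tibble(
          tweet_id = sprintf("t%05d_%04d", u, seq_len(n_t)),
          user_id = uid,
          timestamp = cfg$span_start + round(t * 3600),
          text = text,
          hashtags = hashtags,
          mentions = mentions,
          is_retweet = is_rt,
          retweeted_user = rt_user,
          bio = bio, location_string = loc, time_zone = tz,
          geo_lat = geo_lat, geo_lon = geo_lon,
          source_app = app, language = language, verified = verified,
          followers = followers, friends = friends,
          account_created = acct, influence_score = influence,
          in_region_geo = in_region_geo
        )
        list(user = tibble::tibble(user_id = uid, is_regional = is_regional,
                                   confounder = confounder,
                                   gps_enabled = gps_enabled, n_tweets = n_t),
             rec = rec)
      }
    })
    users_out[[u]] <- res$user
    per_user[[u]] <- res$rec
  }
  users <- dplyr::bind_rows(users_out)
  keep <- per_user[!vapply(per_user, is.null, logical(1))]
  if (length(keep) == 0) {
    records <- empty_tweet_records()
    truth_records <- tibble::tibble(tweet_id = character(0), in_region_geo = logical(0))
  } else {
    all_rec <- dplyr::bind_rows(keep)
    truth_records <- tibble::tibble(tweet_id = all_rec$tweet_id,
                                    in_region_geo = all_rec$in_region_geo)
    records <- all_rec[, TWEET_RECORD_FIELDS]
  }
  validate_tweet_records(records)

  # planted per-window tallies (direct arithmetic, not the analytics module)
  off <- as.numeric(difftime(records$timestamp, cfg$event_time, units = "hours"))
  reg_user <- users$user_id[users$is_regional]
  tally_one <- function(sel) {
    r <- records[sel, , drop = FALSE]
    tibble::tibble(tweets = nrow(r), users = length(unique(r$user_id)),
                   retweets = sum(r$is_retweet),
                   hashtag_tweets = sum(lengths(r$hashtags) > 0),
                   gps_tweets = sum(!is.na(r$geo_lat)))
  }
  tallies <- dplyr::bind_rows(
    pre = tally_one(off >= -50 & off < 0),
    post = tally_one(off >= 0 & off < 46),
    outside = tally_one(off < -50 | off >= 46),
    .id = "window"
  )
  truth <- list(users = users[users$n_tweets > 0, , drop = FALSE],
                records = truth_records, tallies = tallies)
  list(records = records, truth = truth, config = cfg)
}

#' Write tweet records as a JSON-lines corpus
#'
#' Emits the dialect [read_activity_stream()] reads by default (one JSON
#' object per line, ISO-8601 UTC timestamps, `null` for absent fields),
#' byte-reproducibly.
#'
#' @param records A [tweet_records] tibble.
#' @param path Output path.
#' @return Number of lines written, invisibly.
#' @export
write_corpus_jsonl <- function(records, path) {
  validate_tweet_records(records)
  df <- as.data.frame(records)
  df$timestamp <- fmt_utc(records$timestamp)
  df$account_created <- fmt_utc(records$account_created)
  con <- file(path, open = "wb")
  on.exit(close(con))
  jsonlite::stream_out(df, con, na = "null", digits = 10, verbose = FALSE)
  invisible(nrow(records))
}

#' Score pipeline assignments against generator ground truth
#'
#' User-level confusion-matrix quantities for a regional/non-regional
#' classification, relative to the planted labels.
#'
#' @param assignments Output of [classify_users()].
#' @param truth_users The `truth$users` tibble from [generate_corpus()].
#' @return A list: `tp`, `fp`, `fn`, `tn`, `precision`, `recall`.
#'   Precision is `NA` when nothing was predicted regional.
#' @export
evaluate_pipeline <- function(assignments, truth_users) {
  if (!setequal(assignments$user_id, truth_users$user_id)) {
    abort("assignments and ground truth cover different user sets")
  }
  m <- merge(assignments[, c("user_id", "is_regional")],
             truth_users[, c("user_id", "is_regional")],
             by = "user_id", suffixes = c("_pred", "_true"))
  tp <- sum(m$is_regional_pred & m$is_regional_true)
  fp <- sum(m$is_regional_pred & !m$is_regional_true)
  fn <- sum(!m$is_regional_pred & m$is_regional_true)
  tn <- sum(!m$is_regional_pred & !m$is_regional_true)
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}
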