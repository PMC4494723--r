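# Shared fixtures and independent oracles for the test suite.

EVENT_UTC <- as_utc("2013-02-10T23:00:00Z")

make_rec <- function(tweet_id, user_id,
                     timestamp = "2013-02-10T12:00:00Z", text = "hello world",
                     hashtags = character(0), mentions = character(0),
                     is_retweet = FALSE, retweeted_user = NA_character_,
                     bio = NA_character_, location = NA_character_,
                     tz = NA_character_, lat = NA_real_, lon = NA_real_,
                     app = "web", lang = "en", verified = FALSE,
                     followers = 10L, friends = 10L,
                     created = "2011-01-01T00:00:00Z", influence = NA_real_) {
  tibble::tibble(
    tweet_id = tweet_id, user_id = user_id, timestamp = as_utc(timestamp),
    text = text, hashtags = list(hashtags), mentions = list(mentions),
    is_retweet = is_retweet, retweeted_user = retweeted_user,
    bio = bio, location_string = location, time_zone = tz,
    geo_lat = lat, geo_lon = lon, source_app = app, language = lang,
    verified = verified, followers = as.integer(followers),
    friends = as.integer(friends), account_created = as_utc(created),
    influence_score = influence
  )
}

# Randomized records for property tests (valid per the schema, with awkward
# content: embedded tabs/newlines, unicode, missing optionals).
random_records <- function(n, seed) {
  local({
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    words <- c("tornado", "storm", "cat", "coffee", "petal", "petaling",
               "hattiesburg", "café", "rain")
    bios <- c(NA, "Proud Mississippi native", "coffee lover", "USM student",
              "likes MSU", "smttt!")
    locs <- c(NA, "Hattiesburg, MS", "Petaling Jaya", "Springfield, USA",
              "Mobile, Alabama 36601", "worldwide")
    mk_text <- function() {
      base <- paste(sample(words, 3, replace = TRUE), collapse = " ")
      if (runif(1) < 0.2) base <- paste0(base, " #", sample(words, 1))
      if (runif(1) < 0.2) base <- paste0(base, " @wdam")
      if (runif(1) < 0.1) base <- paste0(base, "\tcol\nline \\slash")
      base
    }
    has_geo <- runif(n) < 0.3
    dplyr::bind_rows(lapply(seq_len(n), function(i) {
      make_rec(
        tweet_id = sprintf("rt%05d", i),
        user_id = sprintf("ru%03d", sample.int(max(2, n %/% 3), 1)),
        timestamp = EVENT_UTC + round(runif(1, -80, 80) * 3600),
        text = mk_text(),
        hashtags = if (runif(1) < 0.3) sample(c("tornado", "lol"), 1) else character(0),
        mentions = if (runif(1) < 0.3) sample(c("wdam", "friend_1"), 1) else character(0),
        is_retweet = runif(1) < 0.3,
        bio = sample(bios, 1), location = sample(locs, 1),
        tz = sample(c(NA, "Central Time (US & Canada)", "London"), 1),
        lat = if (has_geo[i]) runif(1, 25, 40) else NA_real_,
        lon = if (has_geo[i]) runif(1, -95, -70) else NA_real_,
        app = sample(c("web", "Twitter for iPhone", NA), 1),
        lang = sample(c("en", "es", NA), 1),
        followers = sample.int(1000, 1), friends = sample.int(1000, 1),
        influence = if (runif(1) < 0.5) round(runif(1, 1, 99)) else NA_real_
      )
    }))
  })
}

# Independent word-boundary term matcher: space-normalized substring search,
# a different mechanism from the package's token-sequence walk.
oracle_term_match <- function(text, term) {
  if (is.na(text)) return(FALSE)
  norm <- function(s) paste0(" ", gsub("[^a-z0-9]+", " ", tolower(s)), " ")
  grepl(norm(term), norm(text), fixed = TRUE)
}

# Naive per-record, per-term extraction matcher (brute force).
oracle_apply_ruleset <- function(records, ruleset, polygons) {
  vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    kw <- any(vapply(ruleset$keyword_terms, oracle_term_match,
                     logical(1), text = r$text))
    ht <- any(ruleset$hashtag_terms %in% r$hashtags[[1]])
    prof <- paste(ifelse(is.na(r$bio), "", r$bio),
                  ifelse(is.na(r$location_string), "", r$location_string))
    bl <- any(vapply(ruleset$bio_location_terms, oracle_term_match,
                     logical(1), text = prof))
    mn <- any(ruleset$news_handles %in% r$mentions[[1]])
    gps <- FALSE
    if (!is.null(ruleset$gps_region) && !is.na(r$geo_lat)) {
      reg <- oracle_point_region(r$geo_lon, r$geo_lat, polygons)
      gps <- !is.na(reg) && reg %in% ruleset$gps_region
    }
    kw || ht || bl || mn || gps
  }, logical(1))
}

# Brute-force containment oracle built on pracma::inpolygon.
oracle_point_region <- function(lon, lat, polygons) {
  for (reg in polygons) {
    inside <- FALSE
    for (ring in reg$rings) {
      hit <- pracma::inpolygon(lon, lat, ring[, 1], ring[, 2], boundary = TRUE)
      inside <- xor(inside, hit)
    }
    if (inside) return(reg$region_id)
  }
  NA_character_
}

# Closed-form Wilson score interval (independent of prop.test).
oracle_wilson <- function(k, n, conf) {
  z <- qnorm((1 + conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(center - half, center + half)
}

# Reported-count GPS fixture: 515 GPS users realizing the published
# confirmation structure (463 in-region, 30 city-listed, 9 state-listed,
# 13 with neither), all regional by construction.
gps_fixture <- function() {
  n <- 515
  recs <- lapply(seq_len(n), function(i) {
    if (i <= 463) {            # geotag inside the MS rectangle
      lat <- 31.3; lon <- -89.3; loc <- NA_character_; bio <- "Proud Mississippi native"
    } else if (i <= 493) {     # outside geotag, city-level location
      lat <- 40.7; lon <- -74.0; loc <- "Hattiesburg, MS"; bio <- NA_character_
    } else if (i <= 502) {     # outside geotag, state-level location
      lat <- 40.7; lon <- -74.0
      loc <- if (i %% 2 == 0) "Mississippi" else "Alabama"
      bio <- NA_character_
    } else {                   # outside geotag, regional via biography only
      lat <- 40.7; lon <- -74.0; loc <- NA_character_; bio <- "USM student"
    }
    make_rec(sprintf("g%04d", i), sprintf("gu%04d", i),
             bio = bio, location = loc, lat = lat, lon = lon)
  })
  dplyr::bind_rows(recs)
}
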