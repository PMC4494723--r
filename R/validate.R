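#' GPS confirmation report for regional users
#'
#' Two-tier validation of the triangulated regional users against region
#' polygons. Users with at least one geotagged record are the GPS
#' population; those with a geotag inside any region polygon are confirmed.
#' Unconfirmed GPS users whose free-text location still matches a
#' location-category criterion row are counted as location-consistent
#' (plausibly travelling residents), and the two groups together give the
#' "likely regional" accuracy.
#'
#' @param assignments Output of [classify_users()]; only regional users are
#'   evaluated.
#' @param records The [tweet_records] covering the analysis span.
#' @param polygons A `region_polygons` object.
#' @param criteria Criterion table; its location-category rows define the
#'   location-consistency check.
#' @return A `validation_report` list: `gps_users`, `gps_confirmed_users`,
#'   `location_consistent_users`, `likely_regional_users`,
#'   `likely_regional_accuracy_pct` (`NA` and flagged when there are no GPS
#'   users), `gps_tweets`, `gps_tweets_in_region`.
#' @export
gps_validation_report <- function(assignments, records, polygons,
                                  criteria = regional_criteria()) {
  regional_ids <- assignments$user_id[assignments$is_regional]
  rec <- records[records$user_id %in% regional_ids, , drop = FALSE]
  geo <- rec[!is.na(rec$geo_lat), , drop = FALSE]
  gps_tweets <- nrow(geo)
  in_reg <- if (gps_tweets > 0) {
    !is.na(point_in_region(geo$geo_lon, geo$geo_lat, polygons))
  } else logical(0)
  gps_users <- unique(geo$user_id)
  confirmed_users <- unique(geo$user_id[in_reg])
  unconfirmed <- setdiff(gps_users, confirmed_users)

  loc_rows <- criteria[criteria$category == "location", , drop = FALSE]
  loc_consistent <- character(0)
  if (length(unconfirmed) > 0 && nrow(loc_rows) > 0) {
    sub <- assignments[assignments$user_id %in% unconfirmed, , drop = FALSE]
    hit <- vapply(sub$matched_rows, function(r) any(loc_rows$row_label %in% r), logical(1))
    loc_consistent <- sub$user_id[hit]
  }
  n_gps <- length(gps_users)
  likely <- length(confirmed_users) + length(loc_consistent)
  rep <- list(
    gps_users = n_gps,
    gps_confirmed_users = length(confirmed_users),
    location_consistent_users = length(loc_consistent),
    likely_regional_users = likely,
    likely_regional_accuracy_pct = if (n_gps > 0) 100 * likely / n_gps else NA_real_,
    gps_tweets = gps_tweets,
    gps_tweets_in_region = sum(in_reg),
    flagged = n_gps == 0
  )
  stopifnot(rep$gps_confirmed_users <= rep$gps_users,
            rep$likely_regional_users <= rep$gps_users,
            rep$gps_tweets_in_region <= rep$gps_tweets)
  structure(rep, class = "validation_report")
}

#' Required survey sample size with finite-population correction
#'
#' Cochran's formula for a proportion: `n0 = z^2 p (1 - p) / moe^2` with `z`
#' the two-sided normal quantile at the given confidence, corrected for a
#' finite population by `n = n0 / (1 + (n0 - 1) / N)`, rounded up and capped
#' at the population size. `p = 0.5` is the worst-case-variance default.
#'
#' @param population Population size `N` (>= 1).
#' @param confidence Confidence level in (0, 1), e.g. `0.99`.
#' @param moe Margin of error in (0, 1), e.g. `0.03`.
#' @param p Anticipated proportion, default `0.5`.
#' @return Integer sample size.
#' @export
required_sample_size <- function(population, confidence, moe, p = 0.5) {
  if (!is.numeric(population) || population < 1) abort("population must be >= 1")
  if (confidence <= 0 || confidence >= 1) abort("confidence must be in (0, 1)")
  if (moe <= 0 || moe >= 1) abort("moe must be in (0, 1)")
  if (p <= 0 || p >= 1) abort("p must be in (0, 1)")
  z <- qnorm((1 + confidence) / 2)
  n0 <- z^2 * p * (1 - p) / moe^2
  n <- min(ceiling(n0 / (1 + (n0 - 1) / population)), population)
  if (n <= .Machine$integer.max) as.integer(n) else n
}

#' Draw a reproducible simple random sample of users
#'
#' Sampling without replacement under a fixed seed, for quality-assessment
#' review. The caller's RNG state is untouched.
#'
#' @param ids Vector of user ids (no duplicates).
#' @param n Sample size, `<= length(ids)`.
#' @param seed Integer seed.
#' @param stratum Label stored on the sample (e.g. `"regional"`).
#' @return A `qa_sample` list: `sampled_user_ids`, `stratum`, `seed`,
#'   `judgments` (initially `NULL`).
#' @export
draw_sample <- function(ids, n, seed, stratum = "regional") {
  if (anyDuplicated(ids)) abort("ids must be unique")
  if (n > length(ids)) abort("sample size exceeds stratum size")
  picked <- local_seed(seed, sample(ids, size = n, replace = FALSE))
  structure(list(sampled_user_ids = picked, stratum = stratum,
                 seed = as.integer(seed), judgments = NULL),
            class = "qa_sample")
}

#' Error rate of a judged QA sample, with Wilson interval
#'
#' @param sample A `qa_sample` whose `judgments` field is a character vector
#'   of `"pass"`/`"fail"` over all sampled users (names optional).
#' @param confidence Confidence level for the two-sided Wilson score
#'   interval.
#' @return A list: `fails`, `size`, `error_rate`, `conf_low`, `conf_high`,
#'   `confidence`.
#' @export
qa_error_rate <- function(sample, confidence = 0.99) {
  stopifnot(inherits(sample, "qa_sample"))
  j <- sample$judgments
  if (is.null(j) || length(j) != length(sample$sampled_user_ids) || anyNA(j)) {
    abort("all judgments must be present before computing an error rate")
  }
  if (!all(j %in% c("pass", "fail"))) abort("judgments must be 'pass' or 'fail'")
  size <- length(j)
  fails <- sum(j == "fail")
  ci <- suppressWarnings(
    prop.test(fails, size, conf.level = confidence, correct = FALSE)$conf.int
  )
  list(fails = fails, size = size, error_rate = fails / size,
       conf_low = ci[[1]], conf_high = ci[[2]], confidence = confidence)
}
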