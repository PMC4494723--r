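#' Event-centered analysis window specification
#'
#' Defines the pre/post windows around an event instant. The default spans
#' 96 hours, from 50 hours before the event to 46 hours after, split at the
#' event itself — a 48 h + 48 h design shifted two hours left so the window
#' leading up to impact is fully captured. A record at exactly the event
#' instant belongs to the post window.
#'
#' @param event_time Event instant, `POSIXct` UTC (default: the Hattiesburg
#'   tornado touchdown, 2013-02-10 17:00 CST = 23:00 UTC).
#' @param pre_start_offset_h Hours before the event at which the pre window
#'   opens (default 50).
#' @param split_offset_h Hours after the event at which pre becomes post
#'   (default 0).
#' @param post_end_offset_h Hours after the event at which the post window
#'   closes (default 46).
#' @return An `event_window_spec` list.
#' @export
event_window_spec <- function(event_time = as_utc("2013-02-10T23:00:00Z"),
                              pre_start_offset_h = 50,
                              split_offset_h = 0,
                              post_end_offset_h = 46) {
  if (!(-pre_start_offset_h < split_offset_h && split_offset_h < post_end_offset_h)) {
    abort("window spec must satisfy -pre_start < split < post_end")
  }
  structure(list(event_time = as_utc(event_time),
                 pre_start_offset_h = pre_start_offset_h,
                 split_offset_h = split_offset_h,
                 post_end_offset_h = post_end_offset_h),
            class = "event_window_spec")
}

rec_offset_h <- function(records, spec) {
  as.numeric(difftime(records$timestamp, spec$event_time, units = "hours"))
}

#' Split records into pre-event, post-event, and outside sets
#'
#' Pre is `[event - pre_start, event + split)`, post is
#' `[event + split, event + post_end)`; everything else is outside. The
#' three sets partition the input exactly.
#'
#' @param records A [tweet_records] tibble.
#' @param spec An [event_window_spec()].
#' @return A list of three [tweet_records] tibbles: `pre`, `post`, `outside`.
#' @export
split_windows <- function(records, spec = event_window_spec()) {
  stopifnot(inherits(spec, "event_window_spec"))
  h <- rec_offset_h(records, spec)
  pre <- h >= -spec$pre_start_offset_h & h < spec$split_offset_h
  post <- h >= spec$split_offset_h & h < spec$post_end_offset_h
  list(pre = records[pre, , drop = FALSE],
       post = records[post, , drop = FALSE],
       outside = records[!pre & !post, , drop = FALSE])
}

#' Descriptive summary of one analysis window
#'
#' Totals over the window's records (distinct users, tweets, retweets,
#' tweets with a hashtag, geotagged tweets, distinct posting applications,
#' verified users, distinct languages) and per-user means (account length in
#' days against the reference time, followers, influence score, friends),
#' each user represented by their latest record in the window.
#'
#' @param records The window's [tweet_records] subset.
#' @param reference_time Instant against which account length is measured
#'   (default: the event time convention is the caller's choice).
#' @return A one-row tibble with the summary fields; an empty window yields
#'   zero counts, `NA` means, and attribute `empty = TRUE`.
#' @export
window_summary <- function(records, reference_time = as_utc("2013-02-10T23:00:00Z")) {
  if (nrow(records) == 0) {
    out <- tibble::tibble(users = 0L, tweets = 0L, retweets = 0L,
                          hashtag_tweets = 0L, gps_tweets = 0L,
                          application_types = 0L, verified_users = 0L,
                          languages = 0L, mean_account_length_days = NA_real_,
                          mean_followers = NA_real_, mean_influence = NA_real_,
                          mean_friends = NA_real_)
    attr(out, "empty") <- TRUE
    return(out)
  }
  ord <- order(records$user_id, records$timestamp)
  rec <- records[ord, , drop = FALSE]
  latest <- rec[!duplicated(rec$user_id, fromLast = TRUE), , drop = FALSE]
  acct_days <- as.numeric(difftime(as_utc(reference_time), latest$account_created,
                                   units = "days"))
  out <- tibble::tibble(
    users = nrow(latest),
    tweets = nrow(rec),
    retweets = sum(rec$is_retweet),
    hashtag_tweets = sum(lengths(rec$hashtags) > 0),
    gps_tweets = sum(!is.na(rec$geo_lat)),
    application_types = length(unique(rec$source_app[!is.na(rec$source_app)])),
    verified_users = sum(latest$verified, na.rm = TRUE),
    languages = length(unique(rec$language[!is.na(rec$language)])),
    mean_account_length_days = mean(acct_days, na.rm = TRUE),
    mean_followers = mean(latest$followers, na.rm = TRUE),
    mean_influence = mean(latest$influence_score, na.rm = TRUE),
    mean_friends = mean(latest$friends, na.rm = TRUE)
  )
  stopifnot(out$retweets <= out$tweets, out$hashtag_tweets <= out$tweets,
            out$gps_tweets <= out$tweets, out$users >= 1)
  attr(out, "empty") <- FALSE
  out
}

#' Combine pre and post window summaries into span totals
#'
#' Sums the additive count fields across the two windows. The summed user
#' figure is a *window-user total*: a user active in both windows is counted
#' twice, so it exceeds the number of distinct individuals (e.g. 3,145 +
#' 7,501 window users = 10,646 window-user total over 8,423 distinct
#' regional users in the motivating event).
#'
#' @param pre,post One-row summaries as from [window_summary()] (or any list
#'   with the additive fields).
#' @return A list: `tweets`, `user_windows`, `retweets`, `hashtag_tweets`,
#'   `gps_tweets`.
#' @export
combined_totals <- function(pre, post) {
  add <- function(f) as.numeric(pre[[f]]) + as.numeric(post[[f]])
  list(tweets = add("tweets"),
       user_windows = add("users"),
       retweets = add("retweets"),
       hashtag_tweets = add("hashtag_tweets"),
       gps_tweets = add("gps_tweets"))
}

#' Hourly activity series across the analysis span
#'
#' Counts records per whole-hour bin relative to the event
#' (`bin = floor((timestamp - event_time) / 1 h)`), over
#' `[-pre_start, post_end)`. Bin sums over a window reproduce the window
#' summary's corresponding total.
#'
#' @param records A [tweet_records] tibble.
#' @param spec An [event_window_spec()].
#' @param metric One of `"tweets"`, `"retweets"`, `"hashtag_tweets"`.
#' @return A tibble `hour_offset`, `count`, with attribute `metric`.
#' @export
hourly_series <- function(records, spec = event_window_spec(),
                          metric = c("tweets", "retweets", "hashtag_tweets")) {
  metric <- match.arg(metric)
  keep <- switch(metric,
                 tweets = rep(TRUE, nrow(records)),
                 retweets = records$is_retweet,
                 hashtag_tweets = lengths(records$hashtags) > 0)
  h <- floor(rec_offset_h(records[keep, , drop = FALSE], spec))
  offsets <- seq(ceiling(-spec$pre_start_offset_h), ceiling(spec$post_end_offset_h) - 1L)
  in_span <- h >= -spec$pre_start_offset_h & h < spec$post_end_offset_h
  counts <- table(factor(h[in_span], levels = offsets))
  out <- tibble::tibble(hour_offset = offsets, count = as.integer(counts))
  attr(out, "metric") <- metric
  out
}

#' Post/pre fold change
#'
#' @param pre_value Pre-window value (> 0).
#' @param post_value Post-window value.
#' @return `post_value / pre_value`.
#' @export
fold_change <- function(pre_value, post_value) {
  if (!is.numeric(pre_value) || pre_value <= 0) {
    abort("fold change undefined: pre-window value must be positive")
  }
  post_value / pre_value
}
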