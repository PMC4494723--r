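#' Reported reference tallies for the 2013 Hattiesburg tornado event
#'
#' The published descriptive tallies for the motivating event — the 2013
#' Hattiesburg EF-4 tornado — encoded as fixtures so the package's
#' arithmetic (combined window totals, GPS-confirmation accounting) can be
#' exercised against reported values without access to the proprietary raw
#' feed. Window columns follow the [window_summary()] field layout; the GPS
#' block carries the counts entering [gps_validation_report()]-style
#' accounting.
#'
#' @return A list with elements `pre` and `post` (one-row window-summary
#'   tibbles), and `gps` (list: `gps_users`, `gps_confirmed_users`,
#'   `location_consistent_users`, `gps_tweets`, `gps_tweets_in_region`,
#'   `regional_users`, `qa_sample_per_stratum`).
#' @export
hattiesburg_reference <- function() {
  pre <- tibble::tibble(
    users = 3145L, tweets = 27927L, retweets = 6551L,
    hashtag_tweets = 5763L, gps_tweets = 758L,
    application_types = 141L, verified_users = 3L, languages = 6L,
    mean_account_length_days = 785, mean_followers = 745,
    mean_influence = 33, mean_friends = 506
  )
  post <- tibble::tibble(
    users = 7501L, tweets = 53514L, retweets = 20758L,
    hashtag_tweets = 13598L, gps_tweets = 1879L,
    application_types = 192L, verified_users = 3L, languages = 8L,
    mean_account_length_days = 846, mean_followers = 779,
    mean_influence = 34, mean_friends = 504
  )
  gps <- list(
    gps_users = 515L, gps_confirmed_users = 463L,
    location_consistent_users = 39L,   # 30 city-level + 9 state-level listings
    gps_tweets = 2353L, gps_tweets_in_region = 2290L,
    regional_users = 8423L, qa_sample_per_stratum = 900L
  )
  list(pre = pre, post = post, gps = gps)
}
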