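#' Tweet record schema
#'
#' The pipeline's canonical flat representation of one tweet: a tibble with
#' one row per tweet and the columns listed below. Hashtags and mentions are
#' list-columns of lowercased tokens without their `#`/`@` prefixes; the
#' geotag is stored as `geo_lat`/`geo_lon` (WGS84 degrees, `NA` when absent).
#'
#' @format Columns, in order:
#' \describe{
#'   \item{tweet_id, user_id}{opaque identifier strings}
#'   \item{timestamp}{posting instant, `POSIXct` UTC}
#'   \item{text}{message text}
#'   \item{hashtags, mentions}{list-columns of character vectors}
#'   \item{is_retweet}{logical; `retweeted_user` holds the source handle}
#'   \item{bio, location_string, time_zone}{free-text profile fields}
#'   \item{geo_lat, geo_lon}{optional geotag, degrees}
#'   \item{source_app, language}{posting client and BCP-47-style code}
#'   \item{verified}{logical account badge}
#'   \item{followers, friends}{nonnegative counts}
#'   \item{account_created}{account creation instant, UTC}
#'   \item{influence_score}{third-party influence metric, consumed as-is}
#' }
#' @name tweet_records
NULL

TWEET_RECORD_FIELDS <- c(
  "tweet_id", "user_id", "timestamp", "text", "hashtags", "mentions",
  "is_retweet", "retweeted_user", "bio", "location_string", "time_zone",
  "geo_lat", "geo_lon", "source_app", "language", "verified",
  "followers", "friends", "account_created", "influence_score"
)

#' Empty tweet-record table
#'
#' @return A zero-row tibble with the full [tweet_records] schema.
#' @export
empty_tweet_records <- function() {
  tibble::tibble(
    tweet_id = character(0), user_id = character(0),
    timestamp = as_utc(character(0)), text = character(0),
    hashtags = list(), mentions = list(),
    is_retweet = logical(0), retweeted_user = character(0),
    bio = character(0), location_string = character(0),
    time_zone = character(0),
    geo_lat = double(0), geo_lon = double(0),
    source_app = character(0), language = character(0),
    verified = logical(0), followers = integer(0), friends = integer(0),
    account_created = as_utc(character(0)), influence_score = double(0)
  )
}

#' Validate a tweet-record table
#'
#' Checks the schema invariants: all columns present, unique `tweet_id`,
#' geotags within coordinate ranges, hashtags/mentions free of whitespace,
#' timestamps resolved.
#'
#' @param records A tibble following the [tweet_records] schema.
#' @return `records`, invisibly, if valid; otherwise an error.
#' @export
validate_tweet_records <- function(records) {
  missing <- setdiff(TWEET_RECORD_FIELDS, names(records))
  if (length(missing) > 0) {
    abort(paste0("records missing columns: ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(records$tweet_id)) abort("tweet_id values must be unique")
  if (any(is.na(records$timestamp))) abort("all timestamps must be parseable")
  lat <- records$geo_lat; lon <- records$geo_lon
  if (any(!is.na(lat) & (lat < -90 | lat > 90))) abort("latitude out of [-90, 90]")
  if (any(!is.na(lon) & (lon < -180 | lon > 180))) abort("longitude out of [-180, 180]")
  if (any(xor(is.na(lat), is.na(lon)))) abort("geo_lat and geo_lon must be both present or both absent")
  for (col in c("hashtags", "mentions")) {
    toks <- unlist(records[[col]], use.names = FALSE)
    if (length(toks) && any(grepl("[[:space:]]", toks))) {
      abort(paste0(col, " tokens must not contain whitespace"))
    }
  }
  invisible(records)
}
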