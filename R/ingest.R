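#' Default field mapping for JSON-lines input
#'
#' Maps [tweet_records] fields to the source keys of a JSON-lines activity
#' stream. Override entries (or set them to `NULL`) to adapt other dialects;
#' absent keys simply yield empty optionals.
#'
#' @return Named list: record field -> source key.
#' @export
default_dialect <- function() {
  keys <- setNames(as.list(TWEET_RECORD_FIELDS), TWEET_RECORD_FIELDS)
  keys
}

json_chr <- function(rec, key) {
  v <- rec[[key]]
  if (is.null(v) || length(v) == 0 || (length(v) == 1 && is.na(v))) NA_character_
  else as.character(v[[1]])
}
json_num <- function(rec, key) {
  v <- rec[[key]]
  if (is.null(v) || length(v) == 0 || (length(v) == 1 && is.na(v))) NA_real_
  else as.numeric(v[[1]])
}
json_lgl <- function(rec, key, default = NA) {
  v <- rec[[key]]
  if (is.null(v) || length(v) == 0 || (length(v) == 1 && is.na(v))) default
  else isTRUE(as.logical(v[[1]]))
}
json_set <- function(rec, key) {
  v <- rec[[key]]
  if (is.null(v)) return(NULL)
  v <- unlist(v, use.names = FALSE)
  if (length(v) == 0) return(character(0))
  unique(tolower(sub("^[#@]", "", as.character(v))))
}

scan_tagged_tokens <- function(text, prefix) {
  if (is.na(text)) return(character(0))
  m <- regmatches(text, gregexpr(paste0("\\", prefix, "[A-Za-z0-9_]+"), text))[[1]]
  unique(tolower(substring(m, 2)))
}

#' Read a JSON-lines activity stream into tweet records
#'
#' Each input line is one JSON object describing a tweet. Structured
#' hashtag/mention arrays are preferred; when absent they are recovered from
#' the text by a `#`/`@` token scan. A native retweet marker is
#' authoritative; the `"RT @handle"` prefix heuristic for pseudo-retweets is
#' opt-in and off by default.
#'
#' @param source Path to a JSON-lines file, or a character vector of lines.
#' @param dialect Field mapping, see [default_dialect()].
#' @param rt_heuristic Treat a leading `"RT @handle:"` as a retweet marker
#'   when no native flag is present.
#' @param on_error `"fail"` stops at the first malformed line (reporting its
#'   number); `"skip"` drops malformed lines and records the count in the
#'   `"skipped"` attribute of the result.
#' @return A [tweet_records] tibble, one row per well-formed line, in input
#'   order, with attribute `skipped` (integer count of dropped lines).
#' @export
read_activity_stream <- function(source, dialect = default_dialect(),
                                 rt_heuristic = FALSE,
                                 on_error = c("fail", "skip")) {
  on_error <- match.arg(on_error)
  lines <- if (length(source) == 1 && file.exists(source)) {
    readLines(source, encoding = "UTF-8", warn = FALSE)
  } else {
    as.character(source)
  }
  lines_keep <- nzchar(trimws(lines))
  line_no <- which(lines_keep)
  lines <- lines[lines_keep]
  n <- length(lines)
  skipped <- 0L
  if (n == 0) {
    out <- empty_tweet_records()
    attr(out, "skipped") <- 0L
    return(out)
  }

  parse_one <- function(i) {
    tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
             error = function(e) {
               if (on_error == "fail") {
                 abort(sprintf("malformed JSON on line %d: %s",
                               line_no[[i]], conditionMessage(e)))
               }
               NULL
             })
  }
  # chunked parse: join lines into JSON arrays, fall back per-line on failure
  recs <- vector("list", n)
  chunk_size <- 2000L
  starts <- seq(1L, n, by = chunk_size)
  for (s in starts) {
    idx <- s:min(s + chunk_size - 1L, n)
    parsed <- tryCatch(
      jsonlite::fromJSON(paste0("[", paste(lines[idx], collapse = ","), "]"),
                         simplifyVector = FALSE),
      error = function(e) NULL)
    if (!is.null(parsed) && length(parsed) == length(idx)) {
      recs[idx] <- parsed
    } else {
      recs[idx] <- lapply(idx, parse_one)
    }
  }
  ok <- !vapply(recs, is.null, logical(1))
  skipped <- sum(!ok)
  recs <- recs[ok]
  d <- dialect

  texts <- vapply(recs, json_chr, character(1), key = d$text)
  hashtags <- lapply(recs, json_set, key = d$hashtags)
  mentions <- lapply(recs, json_set, key = d$mentions)
  no_ht <- vapply(hashtags, is.null, logical(1))
  no_mn <- vapply(mentions, is.null, logical(1))
  hashtags[no_ht] <- lapply(texts[no_ht], scan_tagged_tokens, prefix = "#")
  mentions[no_mn] <- lapply(texts[no_mn], scan_tagged_tokens, prefix = "@")

  is_rt <- vapply(recs, json_lgl, logical(1), key = d$is_retweet, default = NA)
  rt_user <- vapply(recs, json_chr, character(1), key = d$retweeted_user)
  rt_user <- ifelse(is.na(rt_user), rt_user, tolower(sub("^@", "", rt_user)))
  if (rt_heuristic) {
    pseudo <- is.na(is_rt) & grepl("^RT @[A-Za-z0-9_]+", texts, ignore.case = TRUE)
    is_rt[pseudo] <- TRUE
    rt_user[pseudo] <- tolower(sub("^RT @([A-Za-z0-9_]+).*$", "\\1",
                                   texts[pseudo], ignore.case = TRUE))
  }
  is_rt[is.na(is_rt)] <- FALSE

  out <- tibble::tibble(
    tweet_id = vapply(recs, json_chr, character(1), key = d$tweet_id),
    user_id = vapply(recs, json_chr, character(1), key = d$user_id),
    timestamp = as_utc(vapply(recs, json_chr, character(1), key = d$timestamp)),
    text = ifelse(is.na(texts), "", texts),
    hashtags = hashtags,
    mentions = mentions,
    is_retweet = is_rt,
    retweeted_user = rt_user,
    bio = vapply(recs, json_chr, character(1), key = d$bio),
    location_string = vapply(recs, json_chr, character(1), key = d$location_string),
    time_zone = vapply(recs, json_chr, character(1), key = d$time_zone),
    geo_lat = vapply(recs, json_num, double(1), key = d$geo_lat),
    geo_lon = vapply(recs, json_num, double(1), key = d$geo_lon),
    source_app = vapply(recs, json_chr, character(1), key = d$source_app),
    language = vapply(recs, json_chr, character(1), key = d$language),
    verified = vapply(recs, json_lgl, logical(1), key = d$verified, default = FALSE),
    followers = as.integer(pmax(0, vapply(recs, json_num, double(1), key = d$followers), na.rm = FALSE)),
    friends = as.integer(pmax(0, vapply(recs, json_num, double(1), key = d$friends), na.rm = FALSE)),
    account_created = as_utc(vapply(recs, json_chr, character(1), key = d$account_created)),
    influence_score = vapply(recs, json_num, double(1), key = d$influence_score)
  )
  out$followers[is.na(out$followers)] <- 0L
  out$friends[is.na(out$friends)] <- 0L
  if (on_error == "skip" && any(is.na(out$timestamp))) {
    bad <- is.na(out$timestamp)
    skipped <- skipped + sum(bad)
    out <- out[!bad, ]
  }
  validate_tweet_records(out)
  attr(out, "skipped") <- as.integer(skipped)
  out
}

# ---- flat table (tab-delimited) serialization --------------------------------

# Backslash escaping: \\ \t \n \r; NA encoded as the two-character cell "\N".
escape_cell <- function(x) {
  esc <- gsub("\\", "\\\\", x, fixed = TRUE)
  esc <- gsub("\t", "\\t", esc, fixed = TRUE)
  esc <- gsub("\n", "\\n", esc, fixed = TRUE)
  esc <- gsub("\r", "\\r", esc, fixed = TRUE)
  esc[is.na(x)] <- "\\N"
  esc
}

unescape_cell <- function(x) {
  out <- character(length(x))
  is_na <- x == "\\N"
  rest <- !is_na
  y <- x[rest]
  has_esc <- grepl("\\", y, fixed = TRUE)
  # token-wise unescape so "\\t" stays a literal backslash + t
  y[has_esc] <- vapply(y[has_esc], function(s) {
    pieces <- regmatches(s, gregexpr("\\\\.|[^\\\\]+", s))[[1]]
    paste(vapply(pieces, function(p) {
      switch(p, "\\\\" = "\\", "\\t" = "\t", "\\n" = "\n", "\\r" = "\r", p)
    }, character(1)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  out[rest] <- y
  out[is_na] <- NA_character_
  out
}

num_cell <- function(x) ifelse(is.na(x), NA_character_, format(x, digits = 15, trim = TRUE, scientific = FALSE))

#' Write tweet records as a tab-delimited flat table
#'
#' One row per record with a fixed header; embedded tabs/newlines/backslashes
#' are backslash-escaped, absent values are encoded as `\\N`, and hashtag /
#' mention sets are comma-joined. [read_flat_table()] inverts the encoding
#' field-for-field.
#'
#' @param records A [tweet_records] tibble.
#' @param path Output file path (UTF-8).
#' @return The number of data rows written.
#' @export
write_flat_table <- function(records, path) {
  validate_tweet_records(records)
  cols <- list(
    tweet_id = records$tweet_id,
    user_id = records$user_id,
    timestamp = fmt_utc(records$timestamp),
    text = records$text,
    hashtags = vapply(records$hashtags, paste, character(1), collapse = ","),
    mentions = vapply(records$mentions, paste, character(1), collapse = ","),
    is_retweet = ifelse(records$is_retweet, "true", "false"),
    retweeted_user = records$retweeted_user,
    bio = records$bio,
    location_string = records$location_string,
    time_zone = records$time_zone,
    geo_lat = num_cell(records$geo_lat),
    geo_lon = num_cell(records$geo_lon),
    source_app = records$source_app,
    language = records$language,
    verified = ifelse(records$verified, "true", "false"),
    followers = num_cell(records$followers),
    friends = num_cell(records$friends),
    account_created = fmt_utc(records$account_created),
    influence_score = num_cell(records$influence_score)
  )
  esc <- lapply(cols, escape_cell)
  lines <- c(paste(TWEET_RECORD_FIELDS, collapse = "\t"),
             if (nrow(records) > 0) do.call(paste, c(esc, sep = "\t")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  nrow(records)
}

#' Read a flat table written by [write_flat_table()]
#'
#' @param path Path to the tab-delimited file.
#' @return A [tweet_records] tibble.
#' @export
read_flat_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0) abort("flat table has no header row")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (!identical(header, TWEET_RECORD_FIELDS)) {
    abort("flat table header does not match the tweet record schema")
  }
  body <- lines[-1]
  if (length(body) == 0) {
    out <- empty_tweet_records()
    return(out)
  }
  cells <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(cells) != length(header))
  if (length(bad) > 0) abort(sprintf("malformed flat-table row at line %d", bad[1] + 1L))
  m <- matrix(unlist(cells), ncol = length(header), byrow = TRUE)
  col <- function(name) unescape_cell(m[, match(name, header)])
  split_set <- function(x) {
    lapply(x, function(s) if (is.na(s) || !nzchar(s)) character(0)
           else strsplit(s, ",", fixed = TRUE)[[1]])
  }
  out <- tibble::tibble(
    tweet_id = col("tweet_id"),
    user_id = col("user_id"),
    timestamp = as_utc(col("timestamp")),
    text = col("text"),
    hashtags = split_set(col("hashtags")),
    mentions = split_set(col("mentions")),
    is_retweet = col("is_retweet") == "true",
    retweeted_user = col("retweeted_user"),
    bio = col("bio"),
    location_string = col("location_string"),
    time_zone = col("time_zone"),
    geo_lat = as.numeric(col("geo_lat")),
    geo_lon = as.numeric(col("geo_lon")),
    source_app = col("source_app"),
    language = col("language"),
    verified = col("verified") == "true",
    followers = as.integer(col("followers")),
    friends = as.integer(col("friends")),
    account_created = as_utc(col("account_created")),
    influence_score = as.numeric(col("influence_score"))
  )
  validate_tweet_records(out)
  out
}
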