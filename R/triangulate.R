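#' Classify every user in a corpus as regional or not
#'
#' Triangulation: a user is regional iff at least one criterion row matches.
#' The tweet category matches when any of the user's mentions (including
#' handles they retweeted) is a configured news handle; biography and
#' location rows match their terms on word boundaries against the profile
#' fields; ZIP rows match any standalone 5-digit token present in the
#' regional ZIP set. Profile fields may change within the span, so the
#' values attached to the user's most recent record are used.
#'
#' @param records A [tweet_records] tibble covering the observation span.
#' @param criteria Criterion table from [regional_criteria()].
#' @return A tibble of assignments, one row per user: `user_id`,
#'   `matched_rows` (list of row labels), `is_regional`, `n_rows`, and the
#'   user's latest `time_zone`.
#' @export
classify_users <- function(records, criteria = regional_criteria()) {
  if (nrow(criteria) == 0) abort("criteria must be nonempty")
  if (nrow(records) == 0) {
    return(tibble::tibble(user_id = character(0), matched_rows = list(),
                          is_regional = logical(0), n_rows = integer(0),
                          time_zone = character(0)))
  }
  ord <- order(records$user_id, records$timestamp)
  rec <- records[ord, , drop = FALSE]
  last_idx <- !duplicated(rec$user_id, fromLast = TRUE)
  latest <- rec[last_idx, , drop = FALSE]

  mention_sets <- Map(function(m, rt) {
    u <- unique(c(m, if (!is.na(rt)) rt))
    tolower(u)
  }, rec$mentions, rec$retweeted_user)
  all_mentions <- tapply(mention_sets, rec$user_id,
                         function(x) unique(unlist(x, use.names = FALSE)),
                         simplify = FALSE)
  user_ids <- latest$user_id
  all_mentions <- all_mentions[user_ids]

  bio_toks <- tokenize(ifelse(is.na(latest$bio), "", latest$bio))
  loc_toks <- tokenize(ifelse(is.na(latest$location_string), "", latest$location_string))
  loc_zips <- lapply(loc_toks, function(tk) tk[grepl("^[0-9]{5}$", tk)])

  n_users <- length(user_ids)
  matched <- vector("list", n_users)
  for (j in seq_len(nrow(criteria))) {
    terms <- criteria$terms[[j]]
    field <- criteria$field[[j]]
    hit <- switch(field,
      mentions = vapply(all_mentions, function(m) any(terms %in% m), logical(1)),
      bio = {
        tt <- strsplit(terms, "[^a-z0-9]+")
        vapply(bio_toks, function(tk) any(vapply(tt, contains_token_seq, logical(1), toks = tk)), logical(1))
      },
      location = {
        tt <- strsplit(terms, "[^a-z0-9]+")
        vapply(loc_toks, function(tk) any(vapply(tt, contains_token_seq, logical(1), toks = tk)), logical(1))
      },
      zip = vapply(loc_zips, function(z) any(z %in% terms), logical(1)),
      abort(sprintf("unknown criterion field: %s", field))
    )
    for (i in which(hit)) matched[[i]] <- c(matched[[i]], criteria$row_label[[j]])
  }
  matched <- lapply(matched, function(x) if (is.null(x)) character(0) else x)
  tibble::tibble(
    user_id = user_ids,
    matched_rows = matched,
    is_regional = lengths(matched) > 0,
    n_rows = lengths(matched),
    time_zone = latest$time_zone
  )
}

#' Classify a single user's records
#'
#' Single-user convenience wrapper around [classify_users()]; additionally
#' reports each matched row's exclusivity (`"exclusive"` when it is the only
#' matched row, `"inclusive"` when at least one other row also matched).
#'
#' @param user_records All of one user's [tweet_records] in the span.
#' @param criteria Criterion table from [regional_criteria()].
#' @return A list with `user_id`, `matched_rows`, `is_regional`, and
#'   `exclusivity` (named character vector over matched rows).
#' @export
classify_user <- function(user_records, criteria = regional_criteria()) {
  if (nrow(user_records) == 0) abort("user_records must be nonempty")
  if (length(unique(user_records$user_id)) != 1) {
    abort("user_records must all belong to a single user")
  }
  a <- classify_users(user_records, criteria)
  rows <- a$matched_rows[[1]]
  excl <- if (length(rows) == 1) "exclusive" else rep("inclusive", length(rows))
  list(user_id = a$user_id[[1]], matched_rows = rows,
       is_regional = a$is_regional[[1]],
       exclusivity = setNames(excl, rows))
}

#' Inclusive/exclusive user counts per criterion row
#'
#' For each criterion row, `exclusive_users` counts users whose matched set
#' is exactly that row, and `inclusive_users` counts users matched by that
#' row and at least one other. Every regional user is, for each of their
#' matched rows, exactly one of the two.
#'
#' @param assignments Output of [classify_users()] (one row per user).
#' @param criteria Criterion table defining row order.
#' @return A tibble: `category`, `row_label`, `inclusive_users`,
#'   `exclusive_users`.
#' @export
criterion_counts <- function(assignments, criteria = regional_criteria()) {
  if (anyDuplicated(assignments$user_id)) abort("assignments must be one row per user")
  n_rows <- assignments$n_rows
  out <- criteria[, c("category", "row_label")]
  out$inclusive_users <- vapply(criteria$row_label, function(lab) {
    sum(n_rows >= 2 & vapply(assignments$matched_rows, function(r) lab %in% r, logical(1)))
  }, integer(1), USE.NAMES = FALSE)
  out$exclusive_users <- vapply(criteria$row_label, function(lab) {
    sum(n_rows == 1 & vapply(assignments$matched_rows, function(r) identical(r, lab), logical(1)))
  }, integer(1), USE.NAMES = FALSE)
  out
}

#' Share of regional users captured exclusively by each category
#'
#' The percentage of regional users that only a single criterion row caught,
#' summed per category — the users a category contributes that no other
#' criterion would have found. Exclusive users belong to exactly one row, so
#' the per-category sums are already deduplicated.
#'
#' @param counts Output of [criterion_counts()].
#' @param total_regional Total number of regional users (> 0).
#' @return A tibble: `category`, `exclusive_users`, `share_pct`.
#' @export
exclusive_share <- function(counts, total_regional) {
  if (!is.numeric(total_regional) || total_regional <= 0) {
    abort("total_regional must be a positive count")
  }
  agg <- stats::aggregate(exclusive_users ~ category, data = counts, FUN = sum)
  tibble::tibble(
    category = agg$category,
    exclusive_users = as.integer(agg$exclusive_users),
    share_pct = 100 * agg$exclusive_users / total_regional
  )
}

#' Time-zone tabulation of regional users
#'
#' Counts regional users per self-reported time-zone string (taken from each
#' user's latest record), with a `"(null)"` bucket for users who set none.
#'
#' @param assignments Output of [classify_users()].
#' @return A tibble `time_zone`, `users`, sorted by descending count; counts
#'   sum to the number of regional users.
#' @export
timezone_table <- function(assignments) {
  reg <- assignments[assignments$is_regional, , drop = FALSE]
  tz <- ifelse(is.na(reg$time_zone) | !nzchar(reg$time_zone), "(null)", reg$time_zone)
  if (length(tz) == 0) return(tibble::tibble(time_zone = character(0), users = integer(0)))
  tab <- sort(table(tz), decreasing = TRUE)
  tibble::tibble(time_zone = names(tab), users = as.integer(tab))
}
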