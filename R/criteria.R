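#' Regional ZIP-code set for the two target states
#'
#' Contiguous 5-digit ranges covering Mississippi (38600–39799) and Alabama
#' (35000–36999). A convention, not an authoritative ZIP directory; supply
#' your own set to [regional_criteria()] to override.
#'
#' @return Character vector of 5-digit ZIP strings.
#' @export
default_zip_set <- function() {
  sprintf("%05d", c(35000:36999, 38600:39799))
}

#' Default regional news handles
#'
#' Twitter handles of regional news media outlets (TV, radio, press) used by
#' the tweet-category criterion. Editable; the shipped list covers the major
#' Mississippi/Alabama outlets by their public handles.
#'
#' @return Character vector of lowercased handles without `@`.
#' @export
default_news_handles <- function() {
  c("wdam", "wlox", "wjtv", "wapt", "wlbt", "clarionledger",
    "hattiesburgamer", "wbrc", "waff", "wkrg", "whnt", "aldotcom")
}

#' Build the regional criterion table
#'
#' Three evidence categories decide user regionality: a tweet mentioning a
#' regional news outlet, regional terms in the biography, or regional terms
#' / ZIP codes in the free-text location. Each row is one criterion; a user
#' matching exactly one row is *exclusive* to it, a user matching two or
#' more rows is *inclusive* for each.
#'
#' Term matching is word-boundary and case-insensitive, so the short codes
#' `"MS"`/`"AL"` match only as standalone tokens (`"Hattiesburg, MS"` yes,
#' `"MSU"` no). ZIP rows match any standalone 5-digit token found in the
#' configured regional ZIP set.
#'
#' @param news_handles Handles for the tweet-category row.
#' @param zip_set Regional ZIP strings for the location ZIP row.
#' @return A tibble with columns `category` (`tweet`/`biography`/`location`),
#'   `row_label`, `field` (`mentions`, `bio`, `location`, or `zip`), and
#'   `terms` (list-column).
#' @export
regional_criteria <- function(news_handles = default_news_handles(),
                              zip_set = default_zip_set()) {
  place4 <- c("mississippi", "alabama", "hattiesburg", "birmingham")
  tibble::tibble(
    category = c("tweet", rep("biography", 3), rep("location", 5)),
    row_label = c(
      "User Mentioned Regional News",
      "Bio: Mississippi, Alabama, Hattiesburg, Birmingham",
      "Bio: USM, Ole Miss",
      "Bio: SMTTT",
      "Loc: Mississippi, Alabama, Hattiesburg, Birmingham",
      "Loc: MS, AL",
      "Loc: ZIP (MS & AL)",
      "Loc: USM, Ole Miss",
      "Loc: SMTTT"
    ),
    field = c("mentions", "bio", "bio", "bio",
              "location", "location", "zip", "location", "location"),
    terms = list(
      normalize_terms(news_handles, strip_prefix = "@"),
      place4, c("usm", "ole miss"), "smttt",
      place4, c("ms", "al"), normalize_terms(zip_set),
      c("usm", "ole miss"), "smttt"
    )
  )
}
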