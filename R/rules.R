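#' Compile a first-pass extraction rule set
#'
#' Emulates broad commercial-firehose filtering: case-insensitive keywords
#' over tweet text, hashtag terms, profile bio/location terms, local news
#' handles, and a statewide geotag region. Terms are lowercased, trimmed,
#' deduplicated, and stripped of `#`/`@` prefixes where applicable.
#'
#' @param config A named list with any of `keyword_terms`, `hashtag_terms`,
#'   `bio_location_terms`, `news_handles`, `gps_region` (a region id to
#'   match geotags against), or a path to a YAML file with those keys.
#' @return A `ruleset` object.
#' @export
compile_ruleset <- function(config) {
  if (is.character(config) && length(config) == 1 && file.exists(config)) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("ruleset config must be a list or a YAML path")
  rs <- list(
    keyword_terms = normalize_terms(config$keyword_terms %||% character(0)),
    hashtag_terms = normalize_terms(config$hashtag_terms %||% character(0), strip_prefix = "#"),
    bio_location_terms = normalize_terms(config$bio_location_terms %||% character(0)),
    news_handles = normalize_terms(config$news_handles %||% character(0), strip_prefix = "@"),
    gps_region = config$gps_region %||% NULL
  )
  n_terms <- length(rs$keyword_terms) + length(rs$hashtag_terms) +
    length(rs$bio_location_terms) + length(rs$news_handles) +
    length(rs$gps_region)
  if (n_terms == 0) abort("ruleset config is empty: populate at least one category")
  structure(rs, class = "ruleset")
}

#' Default extraction rule set
#'
#' The shipped first-pass filter for the 2013 Hattiesburg tornado setting:
#' tornado/relief keywords and hashtags, state and local place terms for the
#' profile fields, regional news handles, and statewide geotag matching.
#' User-extensible; see `inst/extdata/default_ruleset.yaml`.
#'
#' @return A `ruleset` object.
#' @export
default_ruleset <- function() {
  compile_ruleset(system.file("extdata", "default_ruleset.yaml",
                              package = "crisistri", mustWork = TRUE))
}

#' Apply an extraction rule set to tweet records
#'
#' A record matches iff any keyword matches its text on word boundaries
#' (case-insensitive), any hashtag term is among its hashtags, any
#' bio/location term matches its bio or location string on word boundaries,
#' any news handle is among its mentions, or its geotag falls inside the
#' configured statewide region. `match_mode = "substring"` switches the text
#' and profile matching to plain substring containment — the permissive
#' compatibility mode that admits homonym contamination (a term like
#' `"petal"` then matches `"Petaling"`).
#'
#' @param records A [tweet_records] tibble.
#' @param ruleset A compiled `ruleset`.
#' @param polygons A `region_polygons` object; required when the ruleset has
#'   a `gps_region`.
#' @param match_mode `"token"` (word-boundary, default) or `"substring"`.
#' @return An `extraction_result`: list with `matched` (the matching records
#'   plus `rule_tags` and `matched_terms` list-columns), `purged_count`
#'   (0 at this stage), and `n_input`.
#' @export
apply_ruleset <- function(records, ruleset, polygons = NULL,
                          match_mode = c("token", "substring")) {
  match_mode <- match.arg(match_mode)
  stopifnot(inherits(ruleset, "ruleset"))
  n <- nrow(records)
  if (!is.null(ruleset$gps_region) && is.null(polygons)) {
    abort("ruleset has a gps_region but no polygons were supplied")
  }
  kw_hits <- lapply(records$text, matching_terms,
                    terms = ruleset$keyword_terms, mode = match_mode)
  profile <- paste(ifelse(is.na(records$bio), "", records$bio),
                   ifelse(is.na(records$location_string), "", records$location_string),
                   sep = " § ")
  bl_hits <- lapply(profile, matching_terms,
                    terms = ruleset$bio_location_terms, mode = match_mode)
  ht_hit <- vapply(records$hashtags, function(h) any(ruleset$hashtag_terms %in% h), logical(1))
  mn_hit <- vapply(records$mentions, function(m) any(ruleset$news_handles %in% m), logical(1))
  gps_hit <- rep(FALSE, n)
  if (!is.null(ruleset$gps_region)) {
    reg <- point_in_region(records$geo_lon, records$geo_lat, polygons)
    gps_hit <- !is.na(reg) & reg %in% ruleset$gps_region
  }
  rule_tags <- lapply(seq_len(n), function(i) {
    c(if (length(kw_hits[[i]]) > 0) "keyword",
      if (ht_hit[[i]]) "hashtag",
      if (length(bl_hits[[i]]) > 0) "bio_location",
      if (mn_hit[[i]]) "news_handle",
      if (gps_hit[[i]]) "gps")
  })
  matched_terms <- lapply(seq_len(n), function(i) unique(c(kw_hits[[i]], bl_hits[[i]])))
  keep <- lengths(rule_tags) > 0
  matched <- records[keep, , drop = FALSE]
  matched$rule_tags <- rule_tags[keep]
  matched$matched_terms <- matched_terms[keep]
  structure(list(matched = matched, purged_count = 0L, n_input = n),
            class = "extraction_result")
}

#' Purge homonym-location contamination from an extraction result
#'
#' Drops records whose free-text location contains an exclusion place term
#' as a token (e.g. `"petaling"` in `"Petaling Jaya"`), or whose geotag lies
#' outside every configured region while their only reason for matching was
#' a text term that is a proper prefix of an exclusion term (the
#' `"petal"`-matches-`"Petaling"` failure mode of substring extraction).
#'
#' @param result An `extraction_result` from [apply_ruleset()].
#' @param exclusions Character vector of lowercased homonym place terms.
#' @param polygons Optional `region_polygons` defining the acceptable
#'   geotag envelope for the prefix-match purge.
#' @return An `extraction_result` with offending records removed and
#'   `purged_count` incremented.
#' @export
purge_homonyms <- function(result, exclusions, polygons = NULL) {
  stopifnot(inherits(result, "extraction_result"))
  exclusions <- normalize_terms(exclusions)
  m <- result$matched
  if (length(exclusions) == 0 || nrow(m) == 0) return(result)
  loc_hit <- vapply(m$location_string, function(loc) {
    length(matching_terms(loc, exclusions, mode = "token")) > 0
  }, logical(1), USE.NAMES = FALSE)
  prefix_only <- rep(FALSE, nrow(m))
  if (!is.null(polygons)) {
    has_geo <- !is.na(m$geo_lat)
    outside <- has_geo
    if (any(has_geo)) {
      reg <- point_in_region(m$geo_lon[has_geo], m$geo_lat[has_geo], polygons)
      outside[has_geo] <- is.na(reg)
    }
    term_only <- vapply(seq_len(nrow(m)), function(i) {
      tags <- m$rule_tags[[i]]
      length(tags) > 0 && all(tags %in% c("keyword", "bio_location"))
    }, logical(1))
    prefix_match <- vapply(m$matched_terms, function(tms) {
      length(tms) > 0 && all(vapply(tms, function(tm) {
        any(startsWith(exclusions, tm) & exclusions != tm)
      }, logical(1)))
    }, logical(1))
    prefix_only <- outside & term_only & prefix_match
  }
  drop <- loc_hit | prefix_only
  structure(list(matched = m[!drop, , drop = FALSE],
                 purged_count = result$purged_count + sum(drop),
                 n_input = result$n_input),
            class = "extraction_result")
}
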