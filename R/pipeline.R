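#' Configuration for an end-to-end pipeline run
#'
#' @param corpus_path Path to a JSON-lines corpus.
#' @param output_dir Directory for intermediate artifacts (created if
#'   absent).
#' @param polygons A `region_polygons` object (default: the shipped
#'   synthetic two-state rectangles).
#' @param ruleset A compiled `ruleset` (default: [default_ruleset()]).
#' @param criteria Criterion table (default: [regional_criteria()]).
#' @param window_spec An [event_window_spec()].
#' @param exclusions Homonym purge terms (default `"petaling"`).
#' @param confidence,moe QA sampling standards.
#' @param seed Seed for QA sample draws.
#' @param qa_sample_override Fixed QA sample size per stratum, or `NULL` to
#'   use [required_sample_size()].
#' @param rt_heuristic,match_mode Forwarded to [read_activity_stream()] and
#'   [apply_ruleset()].
#' @return A `run_config` list.
#' @export
run_config <- function(corpus_path, output_dir,
                       polygons = synthetic_regions(),
                       ruleset = default_ruleset(),
                       criteria = regional_criteria(),
                       window_spec = event_window_spec(),
                       exclusions = "petaling",
                       confidence = 0.99, moe = 0.03, seed = 1L,
                       qa_sample_override = NULL,
                       rt_heuristic = FALSE,
                       match_mode = c("token", "substring")) {
  if (!file.exists(corpus_path)) abort(paste0("corpus not found: ", corpus_path))
  structure(list(corpus_path = corpus_path, output_dir = output_dir,
                 polygons = polygons, ruleset = ruleset, criteria = criteria,
                 window_spec = window_spec, exclusions = exclusions,
                 confidence = confidence, moe = moe, seed = as.integer(seed),
                 qa_sample_override = qa_sample_override,
                 rt_heuristic = rt_heuristic,
                 match_mode = match.arg(match_mode)),
            class = "run_config")
}

write_csv0 <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE)
}

#' Run the full extraction-to-report pipeline
#'
#' Stages, in order: ingest the corpus, apply the first-pass extraction
#' rules, purge homonym contamination, triangulate user regionality,
#' GPS-validate the regional users, draw QA samples, and aggregate the
#' event-centered window summaries and hourly series. Every intermediate is
#' persisted as a flat table/CSV/JSON under `output_dir`, and a manifest
#' records the record count at each stage boundary (a monotone filtration
#' funnel).
#'
#' @param config A [run_config()].
#' @return A `run_report` list: `manifest` (stage counts), `assignments`,
#'   `criterion_counts`, `exclusive_share`, `timezone_table`, `validation`,
#'   `qa_samples`, `summaries` (`pre`, `post`, `combined`, `fold_changes`),
#'   `hourly` (one series per metric), `files` (paths written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$output_dir, name)
  files <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  records <- stage("ingest", read_activity_stream(
    config$corpus_path, rt_heuristic = config$rt_heuristic, on_error = "skip"))
  n_raw <- nrow(records) + attr(records, "skipped")

  extracted <- stage("extract", apply_ruleset(
    records, config$ruleset, config$polygons, match_mode = config$match_mode))
  purged <- stage("purge", purge_homonyms(
    extracted, config$exclusions, config$polygons))
  kept <- purged$matched[, TWEET_RECORD_FIELDS]
  files <- c(files, extracted_flat = out("extracted_records.tsv"))
  write_flat_table(kept, out("extracted_records.tsv"))

  assignments <- stage("triangulate", classify_users(kept, config$criteria))
  regional_ids <- assignments$user_id[assignments$is_regional]
  regional_records <- kept[kept$user_id %in% regional_ids, , drop = FALSE]
  counts <- criterion_counts(assignments, config$criteria)
  n_regional <- length(regional_ids)
  shares <- if (n_regional > 0) exclusive_share(counts, n_regional) else NULL
  tz <- timezone_table(assignments)
  assign_df <- tibble::tibble(
    user_id = assignments$user_id,
    is_regional = assignments$is_regional,
    n_rows = assignments$n_rows,
    matched_rows = vapply(assignments$matched_rows, paste, character(1), collapse = "; "),
    time_zone = assignments$time_zone
  )
  write_csv0(assign_df, out("assignments.csv"))
  write_csv0(counts, out("criterion_counts.csv"))
  if (!is.null(shares)) write_csv0(shares, out("exclusive_share.csv"))
  write_csv0(tz, out("timezone_table.csv"))

  validation <- stage("validate", gps_validation_report(
    assignments, kept, config$polygons, config$criteria))
  jsonlite::write_json(unclass(validation), out("validation_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  nonregional_ids <- setdiff(assignments$user_id, regional_ids)
  draw_stratum <- function(ids, label, seed_off) {
    if (length(ids) == 0) return(NULL)
    n <- config$qa_sample_override %||%
      required_sample_size(length(ids), config$confidence, config$moe)
    n <- min(n, length(ids))
    draw_sample(ids, n, seed = config$seed + seed_off, stratum = label)
  }
  qa <- list(regional = stage("qa", draw_stratum(regional_ids, "regional", 0L)),
             nonregional = stage("qa", draw_stratum(nonregional_ids, "nonregional", 1L)))
  for (s in qa) {
    if (!is.null(s)) {
      write_csv0(tibble::tibble(user_id = s$sampled_user_ids, stratum = s$stratum),
                 out(paste0("qa_sample_", s$stratum, ".csv")))
    }
  }

  spec <- config$window_spec
  win <- stage("analyze", split_windows(regional_records, spec))
  pre_sum <- window_summary(win$pre, spec$event_time)
  post_sum <- window_summary(win$post, spec$event_time)
  combined <- combined_totals(pre_sum, post_sum)
  folds <- list(
    tweets = if (pre_sum$tweets > 0) fold_change(pre_sum$tweets, post_sum$tweets) else NA_real_,
    retweets = if (pre_sum$retweets > 0) fold_change(pre_sum$retweets, post_sum$retweets) else NA_real_,
    hashtag_tweets = if (pre_sum$hashtag_tweets > 0)
      fold_change(pre_sum$hashtag_tweets, post_sum$hashtag_tweets) else NA_real_
  )
  hourly <- lapply(setNames(nm = c("tweets", "retweets", "hashtag_tweets")),
                   function(m) hourly_series(regional_records, spec, m))
  summaries_df <- dplyr::bind_rows(pre = pre_sum, post = post_sum, .id = "window")
  write_csv0(summaries_df, out("window_summaries.csv"))
  for (m in names(hourly)) write_csv0(hourly[[m]], out(paste0("hourly_", m, ".csv")))

  manifest <- list(
    n_raw = n_raw,
    n_ingested = nrow(records),
    n_extracted = nrow(extracted$matched),
    n_after_purge = nrow(kept),
    purged_count = purged$purged_count,
    n_regional_records = nrow(regional_records),
    n_users = nrow(assignments),
    n_regional_users = n_regional,
    n_pre = nrow(win$pre), n_post = nrow(win$post), n_outside = nrow(win$outside)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE, digits = NA)

  structure(list(manifest = manifest, assignments = assignments,
                 criterion_counts = counts, exclusive_share = shares,
                 timezone_table = tz, validation = validation,
                 qa_samples = qa,
                 summaries = list(pre = pre_sum, post = post_sum,
                                  combined = combined, fold_changes = folds),
                 hourly = hourly,
                 files = list.files(config$output_dir, full.names = TRUE)),
            class = "run_report")
}
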