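#!/usr/bin/env Rscript
# Step 3 — GPS validation and quality assessment.
#
# Confirms the triangulated regional users against the region polygons by
# point-in-polygon lookup of their geotags, reports the likely-regional
# accuracy, computes the QA sample sizes implied by the 99% / 3.0% sampling
# standard, and scores the drawn QA samples against the planted ground
# truth (the automated stand-in for an independent review team).

library(crisistri)

stopifnot(file.exists("scratch/pipeline/extracted_records.tsv"),
          file.exists("scratch/truth_users.csv"))
kept <- read_flat_table("scratch/pipeline/extracted_records.tsv")
truth <- read.csv("scratch/truth_users.csv", stringsAsFactors = FALSE)

assignments <- classify_users(kept)
v <- gps_validation_report(assignments, kept, synthetic_regions())
cat(sprintf("GPS users %d; confirmed in-region %d; location-consistent %d; likely regional %d (%.1f%%).\n",
            v$gps_users, v$gps_confirmed_users, v$location_consistent_users,
            v$likely_regional_users, v$likely_regional_accuracy_pct))
cat(sprintf("Geotagged tweets in region: %d of %d.\n",
            v$gps_tweets_in_region, v$gps_tweets))
jsonlite::write_json(unclass(v), "results/03_validation_report.json",
                     auto_unbox = TRUE, digits = NA)

truth_regional <- setNames(truth$is_regional, truth$user_id)
qa_rows <- list()
for (stratum in c("regional", "nonregional")) {
  ids <- if (stratum == "regional") assignments$user_id[assignments$is_regional]
         else assignments$user_id[!assignments$is_regional]
  if (length(ids) == 0) next
  n <- min(required_sample_size(length(ids), 0.99, 0.03), length(ids))
  s <- draw_sample(ids, n, seed = 20130210, stratum = stratum)
  # a sampled user "fails" review when the planted label disagrees with the stratum
  truth_reg <- truth_regional[s$sampled_user_ids]
  s$judgments <- ifelse((stratum == "regional") == truth_reg, "pass", "fail")
  er <- qa_error_rate(s)
  cat(sprintf("QA %s stratum: n = %d of %d, %d fail(s), error rate %.4f (99%% CI %.4f-%.4f).\n",
              stratum, er$size, length(ids), er$fails, er$error_rate,
              er$conf_low, er$conf_high))
  qa_rows[[stratum]] <- data.frame(stratum = stratum, population = length(ids),
                                   sample_n = er$size, fails = er$fails,
                                   error_rate = er$error_rate,
                                   conf_low = er$conf_low, conf_high = er$conf_high)
}
write.csv(do.call(rbind, qa_rows), "results/03_qa_error_rates.csv", row.names = FALSE)
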