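#!/usr/bin/env Rscript
# Step 5 — reported-event arithmetic identities.
#
# Applies the package's combination and validation arithmetic to the
# published reference tallies for the 2013 Hattiesburg tornado window,
# checking that the reported 96-hour totals and GPS confirmation figures
# are reproduced exactly from their printed inputs.

library(crisistri)

ref <- hattiesburg_reference()
tot <- combined_totals(ref$pre, ref$post)
cat(sprintf("Combined 96-hour totals: %d tweets, %d window-user total, %d retweets, %d GPS tweets.\n",
            tot$tweets, tot$user_windows, tot$retweets, tot$gps_tweets))

likely <- ref$gps$gps_confirmed_users + ref$gps$location_consistent_users
acc <- 100 * likely / ref$gps$gps_users
cat(sprintf("GPS confirmation: %d of %d confirmed; +%d location-consistent -> %d likely regional (%.1f%%).\n",
            ref$gps$gps_confirmed_users, ref$gps$gps_users,
            ref$gps$location_consistent_users, likely, acc))

n99 <- required_sample_size(1e9, 0.99, 0.03)
n_fpc <- required_sample_size(ref$gps$regional_users, 0.99, 0.03)
cat(sprintf("99%%/3.0%% sampling standard: n = %d (infinite population), %d with FPC at N = %d.\n",
            n99, n_fpc, ref$gps$regional_users))

out <- list(combined_tweets = tot$tweets,
            combined_window_user_total = tot$user_windows,
            combined_retweets = tot$retweets,
            combined_gps_tweets = tot$gps_tweets,
            likely_regional_users = likely,
            likely_regional_accuracy_pct = acc,
            required_sample_size_99_3 = n99,
            required_sample_size_99_3_fpc = n_fpc)
jsonlite::write_json(out, "results/05_reference_identities.json",
                     auto_unbox = TRUE, digits = NA)
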