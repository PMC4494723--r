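test_that("identical configs give byte-identical corpora", {
  cfg <- synthetic_profile("demo", n_users = 80, seed = 99)
  g1 <- generate_corpus(cfg)
  g2 <- generate_corpus(cfg)
  expect_identical(g1$records, g2$records)
  p1 <- withr::local_tempfile(fileext = ".jsonl")
  p2 <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus_jsonl(g1$records, p1)
  write_corpus_jsonl(g2$records, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("per-user seeding keeps users stable under unrelated config edits", {
  g1 <- generate_corpus(synthetic_profile("demo", n_users = 50, seed = 5))
  g2 <- generate_corpus(synthetic_profile("demo", n_users = 60, seed = 5))
  common <- intersect(g1$records$user_id, g2$records$user_id)
  expect_identical(g1$records[g1$records$user_id %in% common, ],
                   g2$records[g2$records$user_id %in% common, ])
})

test_that("regional_fraction 0 yields zero regional users end to end", {
  g <- generate_corpus(synthetic_profile("demo", n_users = 60,
                                         regional_fraction = 0, seed = 2))
  expect_false(any(g$truth$users$is_regional))
  a <- classify_users(g$records)
  # contamination knob still allows rare nonregional news mentions; zero it out
  g0 <- generate_corpus(synthetic_profile("noise_free", n_users = 60,
                                          regional_fraction = 0, seed = 2))
  a0 <- classify_users(g0$records)
  expect_equal(sum(a0$is_regional), 0)
})

test_that("planted tallies equal counts recomputed by the analytics module", {
  g <- generate_corpus(synthetic_profile("demo", n_users = 150, seed = 21))
  w <- split_windows(g$records)
  recount <- function(r) c(nrow(r), length(unique(r$user_id)), sum(r$is_retweet),
                           sum(lengths(r$hashtags) > 0), sum(!is.na(r$geo_lat)))
  for (win in c("pre", "post", "outside")) {
    t <- g$truth$tallies[g$truth$tallies$window == win, ]
    expect_equal(recount(w[[win]]),
                 c(t$tweets, t$users, t$retweets, t$hashtag_tweets, t$gps_tweets))
  }
})

test_that("with no spike, pre/post hourly rates differ only by diurnal phase", {
  # event_spike_multiplier 1: expected intensity integrals over symmetric
  # 24h-multiple windows are equal, so the fold change is ~1.
  folds <- vapply(1:20, function(s) {
    g <- generate_corpus(synthetic_config(
      n_users = 120, event_spike_multiplier = 1, seed = 1000 + s))
    off <- as.numeric(difftime(g$records$timestamp,
                               as_utc("2013-02-10T23:00:00Z"), units = "hours"))
    pre <- sum(off >= -48 & off < 0)
    post <- sum(off >= 0 & off < 48)
    post / pre
  }, double(1))
  expect_equal(mean(folds), 1, tolerance = 0.05)
})

test_that("a strong flat-diurnal spike approaches its closed-form intensity ratio", {
  m <- 5; hl <- 24
  # closed form: post/pre count ratio over [-48,0) vs [0,48) with flat diurnal
  spike_integral <- 48 + (m - 1) * hl / log(2) * (1 - 2^(-48 / hl))
  expected <- spike_integral / 48
  folds <- vapply(1:8, function(s) {
    g <- generate_corpus(synthetic_config(
      n_users = 600, regional_fraction = 1, diurnal_amplitude = 0,
      event_spike_multiplier = m, spike_halflife_h = hl, seed = 2000 + s))
    off <- as.numeric(difftime(g$records$timestamp,
                               as_utc("2013-02-10T23:00:00Z"), units = "hours"))
    sum(off >= 0 & off < 48) / sum(off >= -48 & off < 0)
  }, double(1))
  expect_equal(mean(folds), expected, tolerance = 0.05)
})

test_that("evaluate_pipeline scores perfect and degenerate classifiers correctly", {
  g <- generate_corpus(synthetic_profile("demo", n_users = 100, seed = 9))
  truth <- g$truth$users
  perfect <- tibble::tibble(user_id = truth$user_id,
                            is_regional = truth$is_regional)
  ev <- evaluate_pipeline(perfect, truth)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  none <- tibble::tibble(user_id = truth$user_id,
                         is_regional = FALSE)
  ev0 <- evaluate_pipeline(none, truth)
  expect_equal(ev0$recall, 0)
  expect_true(is.na(ev0$precision))
  expect_error(evaluate_pipeline(perfect[-1, ], truth), "different user sets")
})

test_that("evaluate_pipeline matches hand-computed confusion counts on a 500-user corpus", {
  g <- generate_corpus(synthetic_profile("demo", seed = 777))
  a <- classify_users(g$records)
  ev <- evaluate_pipeline(a, g$truth$users)
  truth_map <- setNames(g$truth$users$is_regional, g$truth$users$user_id)
  pred <- setNames(a$is_regional, a$user_id)[names(truth_map)]
  expect_equal(ev$tp, sum(pred & truth_map))
  expect_equal(ev$fp, sum(pred & !truth_map))
  expect_equal(ev$fn, sum(!pred & truth_map))
  expect_equal(ev$tn, sum(!pred & !truth_map))
  expect_equal(ev$tp + ev$fp + ev$fn + ev$tn, nrow(g$truth$users))
})

test_that("generator rejects invalid configurations", {
  expect_error(synthetic_config(regional_fraction = 1.5), "\\[0, 1\\]")
  expect_error(synthetic_config(event_spike_multiplier = 0.5), ">= 1")
  expect_error(synthetic_config(event_time = as_utc("2014-01-01T00:00:00Z")),
               "within the span")
  expect_error(synthetic_config(regional_fraction = 0.5,
                                bio_term_pool = character(0)), "nonempty")
})
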