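unit_square <- local({
  ring <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1, 0, 0), ncol = 2, byrow = TRUE)
  colnames(ring) <- c("lon", "lat")
  structure(list(SQ = list(region_id = "SQ", rings = list(ring))),
            class = "region_polygons")
})

test_that("containment basics: centroid inside, far point outside, boundary inside", {
  expect_equal(point_in_region(0.5, 0.5, unit_square), "SQ")
  expect_true(is.na(point_in_region(0, 0, synthetic_regions())))
  # boundary points (edge midpoint and vertex) count as inside
  expect_equal(point_in_region(0.5, 0, unit_square), "SQ")
  expect_equal(point_in_region(1, 1, unit_square), "SQ")
})

test_that("holes are supported via even-odd ring nesting", {
  outer <- matrix(c(0, 0, 4, 0, 4, 4, 0, 4, 0, 0), ncol = 2, byrow = TRUE)
  hole <- matrix(c(1, 1, 3, 1, 3, 3, 1, 3, 1, 1), ncol = 2, byrow = TRUE)
  poly <- structure(list(H = list(region_id = "H", rings = list(outer, hole))),
                    class = "region_polygons")
  expect_equal(point_in_region(0.5, 0.5, poly), "H")
  expect_true(is.na(point_in_region(2, 2, poly)))
})

test_that("point_in_region matches the brute-force ray-casting oracle on 1000 points", {
  skip_if_not_installed("pracma")
  polys <- synthetic_regions()
  set.seed(2013)
  lon <- runif(1000, -95, -82)
  lat <- runif(1000, 28, 37)
  mine <- point_in_region(lon, lat, polys)
  theirs <- vapply(seq_along(lon), function(i) {
    oracle_point_region(lon[i], lat[i], polys)
  }, character(1))
  expect_identical(mine, theirs)
})

test_that("translating polygon and points together leaves verdicts unchanged", {
  polys <- synthetic_regions()
  set.seed(7)
  lon <- runif(200, -95, -82); lat <- runif(200, 28, 37)
  base <- point_in_region(lon, lat, polys)
  dx <- 3.5; dy <- -1.25
  shifted <- lapply(polys, function(reg) {
    reg$rings <- lapply(reg$rings, function(r) cbind(r[, 1] + dx, r[, 2] + dy))
    reg
  })
  class(shifted) <- "region_polygons"
  expect_identical(point_in_region(lon + dx, lat + dy, shifted), base)
})

test_that("gps_validation_report reproduces the reported confirmation arithmetic", {
  recs <- gps_fixture()
  a <- classify_users(recs)
  expect_true(all(a$is_regional))
  v <- gps_validation_report(a, recs, synthetic_regions())
  expect_equal(v$gps_users, 515)
  expect_equal(v$gps_confirmed_users, 463)
  expect_equal(v$location_consistent_users, 39)
  expect_equal(v$likely_regional_users, 502)
  expect_equal(v$likely_regional_accuracy_pct, 100 * 502 / 515, tolerance = 1e-12)
})

test_that("all-inside geotags give 100% accuracy; no GPS users flags the report", {
  recs <- dplyr::bind_rows(
    make_rec("t1", "u1", bio = "SMTTT", lat = 31.3, lon = -89.3),
    make_rec("t2", "u2", bio = "SMTTT", lat = 33.0, lon = -86.5)
  )
  a <- classify_users(recs)
  v <- gps_validation_report(a, recs, synthetic_regions())
  expect_equal(v$likely_regional_accuracy_pct, 100)
  no_geo <- make_rec("t3", "u3", bio = "SMTTT")
  v2 <- gps_validation_report(classify_users(no_geo), no_geo, synthetic_regions())
  expect_true(v2$flagged)
  expect_true(is.na(v2$likely_regional_accuracy_pct))
})

test_that("validation counts match generator ground truth on synthetic corpora", {
  g <- generate_corpus(synthetic_profile("demo", n_users = 250, seed = 88))
  a <- classify_users(g$records)
  v <- gps_validation_report(a, g$records, synthetic_regions())
  # ground-truth bookkeeping for regional users' geotags
  reg_ids <- a$user_id[a$is_regional]
  geo <- g$records[!is.na(g$records$geo_lat) & g$records$user_id %in% reg_ids, ]
  truth_geo <- g$truth$records[match(geo$tweet_id, g$truth$records$tweet_id), ]
  expect_equal(v$gps_tweets, nrow(geo))
  expect_equal(v$gps_tweets_in_region, sum(truth_geo$in_region_geo))
  expect_equal(v$gps_users, length(unique(geo$user_id)))
  expect_equal(v$gps_confirmed_users,
               length(unique(geo$user_id[truth_geo$in_region_geo])))
  # report inequalities
  expect_lte(v$gps_confirmed_users, v$gps_users)
  expect_lte(v$likely_regional_users, v$gps_users)
  expect_lte(v$gps_tweets_in_region, v$gps_tweets)
})

test_that("required_sample_size matches the closed-form oracle with FPC", {
  oracle <- function(N, conf, moe, p = 0.5) {
    z <- qnorm((1 + conf) / 2)
    n0 <- z^2 * p * (1 - p) / moe^2
    min(ceiling(n0 / (1 + (n0 - 1) / N)), N)
  }
  grid <- expand.grid(N = c(100, 900, 8423, 41458, 1e6, 1e9),
                      conf = c(0.90, 0.95, 0.99),
                      moe = c(0.01, 0.03, 0.05))
  for (i in seq_len(nrow(grid))) {
    expect_equal(required_sample_size(grid$N[i], grid$conf[i], grid$moe[i]),
                 oracle(grid$N[i], grid$conf[i], grid$moe[i]))
  }
  # the 99%/3% standard on an effectively infinite population
  expect_equal(required_sample_size(1e9, 0.99, 0.03), 1844)
  expect_lte(required_sample_size(100, 0.99, 0.001), 100)
})

test_that("sample size is monotone in moe and confidence and converges without FPC", {
  moes <- c(0.01, 0.02, 0.03, 0.05, 0.1)
  ns <- vapply(moes, function(m) required_sample_size(1e7, 0.95, m), integer(1))
  expect_true(all(diff(ns) <= 0))
  confs <- c(0.8, 0.9, 0.95, 0.99, 0.995)
  ns2 <- vapply(confs, function(cl) required_sample_size(1e7, cl, 0.03), integer(1))
  expect_true(all(diff(ns2) >= 0))
  # N -> Inf converges to the uncorrected n0
  z <- qnorm(0.995); n0 <- ceiling(z^2 * 0.25 / 0.03^2)
  expect_equal(required_sample_size(1e12, 0.99, 0.03), n0)
  expect_error(required_sample_size(100, 1.2, 0.03))
})

test_that("draw_sample is a reproducible SRS without replacement", {
  ids <- sprintf("u%03d", 1:40)
  expect_setequal(draw_sample(ids, 40, 1)$sampled_user_ids, ids)
  s1 <- draw_sample(ids, 10, 7); s2 <- draw_sample(ids, 10, 7)
  expect_identical(s1$sampled_user_ids, s2$sampled_user_ids)
  expect_false(anyDuplicated(s1$sampled_user_ids) > 0)
  expect_error(draw_sample(ids, 41, 1), "exceeds")
})

test_that("inclusion frequency over repeated draws approximates n/N", {
  ids <- sprintf("u%02d", 1:20)
  hits <- setNames(numeric(20), ids)
  for (s in 1:4000) {
    picked <- draw_sample(ids, 5, s)$sampled_user_ids
    hits[picked] <- hits[picked] + 1
  }
  freq <- hits / 4000
  expect_true(all(abs(freq - 0.25) < 0.03))
})

test_that("qa_error_rate computes the proportion with a Wilson interval", {
  mk <- function(n, fails) {
    s <- draw_sample(sprintf("u%04d", 1:n), n, 1)
    s$judgments <- c(rep("fail", fails), rep("pass", n - fails))
    s
  }
  zero <- qa_error_rate(mk(900, 0))
  expect_equal(zero$error_rate, 0)
  two <- qa_error_rate(mk(900, 2))
  expect_equal(two$error_rate, 2 / 900)
  expect_equal(c(two$conf_low, two$conf_high),
               oracle_wilson(2, 900, 0.99), tolerance = 1e-9)
  one <- qa_error_rate(mk(1, 1))
  expect_equal(one$error_rate, 1)
  missing <- draw_sample("u1", 1, 1)
  expect_error(qa_error_rate(missing), "judgments")
})
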