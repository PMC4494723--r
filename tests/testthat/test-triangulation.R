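test_that("biography term yields a single exclusive row match", {
  rec <- make_rec("t1", "u1", bio = "Proud Mississippi native")
  a <- classify_user(rec)
  expect_true(a$is_regional)
  expect_equal(a$matched_rows, "Bio: Mississippi, Alabama, Hattiesburg, Birmingham")
  expect_equal(unname(a$exclusivity), "exclusive")
})

test_that("a location matching two rows makes both inclusive", {
  rec <- make_rec("t1", "u1", location = "Hattiesburg, MS")
  a <- classify_user(rec)
  expect_setequal(a$matched_rows,
                  c("Loc: Mississippi, Alabama, Hattiesburg, Birmingham",
                    "Loc: MS, AL"))
  expect_true(all(a$exclusivity == "inclusive"))
})

test_that("short codes match only as standalone tokens and ZIPs via the configured set", {
  expect_false(classify_user(make_rec("t1", "u1", bio = "MSU fan",
                                      location = "MSU campus"))$is_regional)
  a <- classify_user(make_rec("t2", "u2", location = "somewhere 39401"))
  expect_equal(a$matched_rows, "Loc: ZIP (MS & AL)")
  expect_false(classify_user(make_rec("t3", "u3", location = "somewhere 90210"))$is_regional)
})

test_that("news mentions (including retweeted handles) trip the tweet category", {
  a <- classify_user(make_rec("t1", "u1", mentions = "wdam"))
  expect_equal(a$matched_rows, "User Mentioned Regional News")
  b <- classify_user(make_rec("t2", "u2", is_retweet = TRUE, retweeted_user = "wlox"))
  expect_equal(b$matched_rows, "User Mentioned Regional News")
  # a plain-text outlet name without a mention token does not count
  expect_false(classify_user(make_rec("t3", "u3", text = "watching wdam news"))$is_regional)
})

test_that("a user with no evidence in any channel is not regional", {
  rec <- make_rec("t1", "u1", text = "cat photos", bio = "dreamer",
                  location = "London, UK")
  expect_false(classify_user(rec)$is_regional)
  expect_error(classify_user(dplyr::bind_rows(make_rec("a", "u1"),
                                              make_rec("b", "u2"))),
               "single user")
})

test_that("profile fields are taken from the user's most recent record", {
  recs <- dplyr::bind_rows(
    make_rec("t1", "u1", timestamp = "2013-02-09T10:00:00Z", bio = "USM student"),
    make_rec("t2", "u1", timestamp = "2013-02-11T10:00:00Z", bio = "moved on")
  )
  expect_false(classify_users(recs)$is_regional)
  expect_true(classify_users(recs[1, ])$is_regional)
})

test_that("criterion_counts matches hand enumeration and handles edge cases", {
  crit <- tibble::tibble(category = c("biography", "location"),
                         row_label = c("row1", "row2"),
                         field = c("bio", "location"),
                         terms = list("alpha", "beta"))
  recs <- dplyr::bind_rows(
    make_rec("t1", "A", bio = "alpha"),
    make_rec("t2", "B", bio = "alpha", location = "beta"),
    make_rec("t3", "C", text = "nothing")
  )
  counts <- criterion_counts(classify_users(recs, crit), crit)
  expect_equal(counts$exclusive_users, c(1L, 0L))
  expect_equal(counts$inclusive_users, c(1L, 1L))

  empty <- criterion_counts(classify_users(empty_tweet_records(), crit), crit)
  expect_true(all(empty$exclusive_users == 0) && all(empty$inclusive_users == 0))

  all_match <- dplyr::bind_rows(
    make_rec("t4", "D", bio = "alpha", location = "beta"),
    make_rec("t5", "E", bio = "alpha", location = "beta")
  )
  cm <- criterion_counts(classify_users(all_match, crit), crit)
  expect_true(all(cm$exclusive_users == 0))
  expect_true(all(cm$inclusive_users == 2))
})

test_that("exclusive_share divides deduplicated exclusive users by the regional total", {
  counts <- tibble::tibble(category = c("tweet", "location", "location"),
                           row_label = c("r1", "r2", "r3"),
                           inclusive_users = c(5L, 2L, 1L),
                           exclusive_users = c(25L, 10L, 5L))
  sh <- exclusive_share(counts, 100)
  expect_equal(sh$share_pct[sh$category == "tweet"], 25)
  expect_equal(sh$share_pct[sh$category == "location"], 15)
  expect_error(exclusive_share(counts, 0), "positive")
})

test_that("timezone_table counts regional users per zone with a null bucket", {
  recs <- dplyr::bind_rows(
    make_rec("t1", "u1", bio = "SMTTT", tz = "Central Time (US & Canada)"),
    make_rec("t2", "u2", bio = "SMTTT", tz = "Central Time (US & Canada)"),
    make_rec("t3", "u3", bio = "SMTTT"),
    make_rec("t4", "u4", text = "not regional", tz = "London")
  )
  a <- classify_users(recs)
  tz <- timezone_table(a)
  expect_equal(tz$users[tz$time_zone == "Central Time (US & Canada)"], 2L)
  expect_equal(tz$users[tz$time_zone == "(null)"], 1L)
  expect_equal(sum(tz$users), sum(a$is_regional))
  expect_equal(nrow(timezone_table(a[!a$is_regional, ])), 0)
})

test_that("exclusive/inclusive partition and conservation hold on synthetic corpora", {
  crit <- regional_criteria()
  for (seed in c(3, 17)) {
    g <- generate_corpus(synthetic_profile("demo", n_users = 120, seed = seed))
    a <- classify_users(g$records, crit)
    counts <- criterion_counts(a, crit)
    n_regional <- sum(a$is_regional)
    # partition: each matched row of each user is exclusive xor inclusive
    expect_true(all(counts$exclusive_users >= 0 & counts$inclusive_users >= 0))
    expect_lte(sum(counts$exclusive_users), n_regional)
    # sum of exclusive users + distinct inclusive users = total regional
    n_inclusive_users <- sum(a$n_rows >= 2)
    expect_equal(sum(counts$exclusive_users) + n_inclusive_users, n_regional)
    # equality of exclusive sum with total iff nobody is inclusive
    if (n_inclusive_users == 0) {
      expect_equal(sum(counts$exclusive_users), n_regional)
    }
  }
})

test_that("triangulation recovers planted labels on a noise-free corpus", {
  g <- generate_corpus(synthetic_profile("noise_free", seed = 404))
  a <- classify_users(g$records)
  ev <- evaluate_pipeline(a, g$truth$users)
  expect_equal(ev$recall, 1.0)
  expect_equal(ev$precision, 1.0)
  # homonym confounders are present and stay excluded under token matching
  expect_gt(sum(g$truth$users$confounder), 0)
})

test_that("near-miss strings embedded in longer words do not match (precision guard)", {
  recs <- dplyr::bind_rows(
    make_rec("t1", "u1", bio = "alabamama dreaming", location = "Mississippians anonymous"),
    make_rec("t2", "u2", location = "Petaling Jaya, Malaysia"),
    make_rec("t3", "u3", bio = "USMC veteran")
  )
  a <- classify_users(recs)
  expect_false(any(a$is_regional))
})
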