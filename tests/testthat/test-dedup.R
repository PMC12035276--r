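test_that("fingerprints collapse to minute-rounded (timestamp, value) sets", {
  s <- make_series(c(100, 110, 120), step_min = 5)
  fp <- fingerprint_series(s)
  expect_length(fp$pairs, 3)
  # two readings rounding to the same minute with the same value collapse
  t0 <- as.POSIXct("2021-03-01 08:00:10", tz = "UTC")
  s2 <- glucose_series("p", c(t0, t0 + 10, t0 + 300), c(100, 100, 110),
                       quiet = TRUE)
  expect_length(fingerprint_series(s2)$pairs, 2)
  # date set follows the calendar dates present
  s3 <- make_series(rep(100, 4), start = "2021-03-01 23:50:00", step_min = 10)
  expect_length(fingerprint_series(s3)$dates, 2)
  empty <- make_series(numeric(0))
  expect_error(fingerprint_series(empty), "empty")
})

test_that("pair distance is the normalized symmetric difference", {
  a <- fingerprint_series(make_series(c(100, 110, 120)))
  expect_equal(pair_distance(a, a)$distance, 0)
  expect_equal(pair_distance(a, a)$n_common, 3)
  b <- fingerprint_series(make_series(c(200, 210, 220),
                                      start = "2022-01-01 00:00:00"))
  expect_equal(pair_distance(a, b)$distance, 1)
  expect_equal(pair_distance(a, b)$n_common, 0)
  # |A|=|B|=100 with 50 shared pairs: distance 100/150
  v <- 101:250
  full <- make_series(v)
  fa <- fingerprint_series(make_series(v[1:100]))
  fb <- glucose_series("b", full$time[51:150], v[51:150], quiet = TRUE)
  d <- pair_distance(fa, fingerprint_series(fb))
  expect_equal(d$n_common, 50)
  expect_equal(d$distance, 2 / 3)
})

test_that("pair distance is symmetric and agrees with brute-force set arithmetic", {
  set.seed(42)
  for (i in 1:25) {
    va <- random_cgm_values(30)
    vb <- random_cgm_values(30)
    # overlap a random prefix so intersections vary
    k <- sample(0:20, 1)
    if (k > 0) vb[seq_len(k)] <- va[seq_len(k)]
    fa <- fingerprint_series(make_series(va))
    fb <- fingerprint_series(make_series(vb, start = if (k > 0)
      "2021-03-01 00:00:00" else "2021-06-01 00:00:00"))
    d_ab <- pair_distance(fa, fb)
    d_ba <- pair_distance(fb, fa)
    expect_equal(d_ab$distance, d_ba$distance)
    expect_equal(d_ab$n_common, d_ba$n_common)
    oracle <- oracle_pair_distance(fa$pairs, fb$pairs)
    expect_equal(d_ab$distance, oracle$distance)
    expect_equal(d_ab$n_common, oracle$n_common)
  }
})

test_that("planted duplicates are recovered with perfect precision and recall", {
  cfg <- sim_config(n_participants = 12, days_per_participant = 4, seed = 101)
  co_a <- simulate_cohort(cfg)
  ca <- clean_cohort(co_a)$cohort
  res <- plant_duplicates(co_a, n_dup = 4, subsample_rate = 0.8, seed = 9)
  cb <- clean_cohort(res$cohort)$cohort
  matches <- find_duplicates(ca, cb)
  flagged <- matches[matches$is_duplicate, c("id_a", "id_b")]
  truth <- res$truth[order(res$truth$id_a), ]
  flagged <- flagged[order(flagged$id_a), ]
  expect_equal(nrow(flagged), 4)
  expect_equal(flagged$id_a, truth$id_a)
  expect_equal(flagged$id_b, truth$id_b)
  # matches are sorted by distance and one-to-one
  expect_false(is.unsorted(matches$distance))
  expect_false(any(duplicated(flagged$id_a)))
  expect_false(any(duplicated(flagged$id_b)))
})

test_that("threshold zero admits only exact copies and independent cohorts have no duplicates", {
  cfg <- sim_config(n_participants = 8, days_per_participant = 3, seed = 55)
  co_a <- simulate_cohort(cfg)
  res <- plant_duplicates(co_a, n_dup = 3, subsample_rate = 0.7, seed = 2,
                          n_new = 0)
  m <- find_duplicates(co_a, res$cohort, threshold = 0, min_common = 1)
  expect_equal(sum(m$is_duplicate), 0)
  other <- simulate_cohort(sim_config(n_participants = 8,
                                      days_per_participant = 3, seed = 56))
  m2 <- find_duplicates(co_a, other)
  expect_equal(sum(m2$is_duplicate), 0)
  expect_warning(find_duplicates(simulate_cohort(sim_config(n_participants = 0)),
                                 co_a), "empty")
})

test_that("lowering the subsample rate never decreases a planted pair's distance", {
  cfg <- sim_config(n_participants = 4, days_per_participant = 4,
                    gap_rate = 0, seed = 77)
  co <- simulate_cohort(cfg)
  donor <- names(co$series)[1]
  fa <- fingerprint_series(co$series[[donor]])
  dists <- sapply(c(1, 0.8, 0.5, 0.3), function(rate) {
    set.seed(123)
    res <- plant_duplicates(co, n_dup = 4, subsample_rate = rate,
                            seed = 11, n_new = 0)
    row <- res$truth[res$truth$id_a == donor, ]
    fb <- fingerprint_series(res$cohort$series[[row$id_b]])
    pair_distance(fa, fb)$distance
  })
  expect_false(is.unsorted(dists))
})

test_that("mapping files carry matched IDs and their covered dates", {
  cfg <- sim_config(n_participants = 5, days_per_participant = 2, seed = 31)
  co <- simulate_cohort(cfg)
  res <- plant_duplicates(co, n_dup = 2, seed = 3)
  m <- find_duplicates(co, res$cohort)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_mapping(m, co, res$cohort, f1, f2)
  map <- read.csv(f1, colClasses = "character")
  expect_equal(nrow(map), 2)
  expect_setequal(map$id_a, res$truth$id_a)
  dates <- read.csv(f2, colClasses = "character")
  expect_true(all(grepl("^\\d{4}-\\d{2}-\\d{2}(;\\d{4}-\\d{2}-\\d{2})*$",
                        dates$dates_a)))
  # unmatched participants are absent from the mapping
  expect_false(any(setdiff(names(co$series), res$truth$id_a) %in% map$id_a))
  # dropping duplicates removes exactly the matched IDs from cohort b
  dedup_b <- drop_duplicates(res$cohort, m)
  expect_setequal(names(dedup_b$series),
                  setdiff(names(res$cohort$series), res$truth$id_b))
})
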