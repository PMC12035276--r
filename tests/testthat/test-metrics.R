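test_that("time in ranges uses inclusive [70, 180] bounds and partitions the readings", {
  expect_equal(unname(time_in_ranges(make_series(c(60, 100, 150, 200)))),
               c(50, 25, 25))
  expect_equal(unname(time_in_ranges(make_series(rep(100, 5)))), c(100, 0, 0))
  expect_equal(unname(time_in_ranges(make_series(c(70, 180)))), c(100, 0, 0))
  expect_error(time_in_ranges(make_series(numeric(0))), "empty")
})

test_that("SD of rate of change matches hand arithmetic and applies the gap rule", {
  s <- make_series(c(100, 110, 100), step_min = 5)
  # rates 2 and -2 mg/dL/min; sample SD = 2*sqrt(2)
  expect_equal(sd_roc(s), 2 * sqrt(2))
  expect_equal(sd_roc(make_series(rep(120, 10))), 0)
  # a 60-minute gap is excluded from the rates under max_gap = 15
  t0 <- as.POSIXct("2021-01-01 00:00:00", tz = "UTC")
  gap <- glucose_series("p", t0 + c(0, 300, 600, 4200, 4500, 4800) ,
                        c(100, 110, 100, 500, 510, 500), quiet = TRUE)
  expect_equal(sd_roc(gap, max_gap = 15), sd(c(2, -2, 2, -2)))
  expect_error(sd_roc(make_series(c(1, 2))), "at least 3")
  two_rates <- glucose_series("p", t0 + c(0, 300, 7200, 7500),
                              c(100, 110, 100, 90), quiet = TRUE)
  expect_equal(sd_roc(two_rates), sd(c(2, -2)))
})

test_that("LBGI and HBGI split at the risk-neutral glucose and are zero off-branch", {
  # root of the symmetrized scale: (ln g)^1.084 = 5.381
  g_star <- exp(5.381^(1 / 1.084))
  s <- make_series(rep(g_star, 4))
  bg <- lbgi_hbgi(s)
  expect_lt(bg["lbgi"], 1e-10)
  expect_lt(bg["hbgi"], 1e-10)
  high <- make_series(c(150, 200, 300))
  expect_equal(unname(lbgi_hbgi(high)["lbgi"]), 0)
  expect_gt(lbgi_hbgi(high)["hbgi"], 0)
  low <- make_series(c(50, 70, 100))
  expect_equal(unname(lbgi_hbgi(low)["hbgi"]), 0)
  expect_gt(lbgi_hbgi(low)["lbgi"], 0)
})

test_that("shifting all readings upward never raises LBGI nor lowers HBGI", {
  set.seed(7)
  for (i in 1:10) {
    v <- random_cgm_values(200)
    s0 <- make_series(v)
    s1 <- make_series(v + 20)
    expect_lte(lbgi_hbgi(s1)["lbgi"], lbgi_hbgi(s0)["lbgi"])
    expect_gte(lbgi_hbgi(s1)["hbgi"], lbgi_hbgi(s0)["hbgi"])
  }
})

test_that("J-index and GMI closed forms evaluate correctly", {
  expect_equal(j_index(100, 0), 10)
  expect_equal(j_index(132.20, 43.34), 0.001 * (132.20 + 43.34)^2,
               tolerance = 1e-12)
  expect_equal(round(j_index(132.20, 43.34), 2), 30.81)
  expect_gt(j_index(132, 50), j_index(132, 25))
  expect_equal(round(gmi(132.20), 2), 6.47)
  expect_equal(round(gmi(134.48), 2), 6.53)
  expect_equal(round(gmi(130.75), 2), 6.44)
  # GMI is affine: the GMI of a mean equals the mean of GMIs
  set.seed(2)
  means <- runif(50, 90, 250)
  expect_equal(gmi(mean(means)), mean(gmi(means)), tolerance = 1e-12)
})

test_that("pooled mean, SD and CV follow the sample definitions", {
  expect_equal(unname(interday_sd_cv(make_series(c(100, 100)))), c(100, 0, 0))
  out <- interday_sd_cv(make_series(c(90, 110)))
  expect_equal(unname(out), c(100, sqrt(200), 100 * sqrt(200) / 100))
  v <- c(88, 132, 190, 75)
  cv1 <- interday_sd_cv(make_series(v))["cv"]
  cv2 <- interday_sd_cv(make_series(2 * v))["cv"]
  expect_equal(cv1, cv2)
  expect_error(interday_sd_cv(make_series(100)), "2 readings")
})

test_that("compute_all assembles every metric consistently on closed-form cases", {
  s <- make_series(rep(100, 300))
  m <- compute_all(s)
  expect_equal(m$tir, 100)
  expect_equal(m$interday_sd, 0)
  expect_equal(m$interday_cv, 0)
  expect_equal(m$sd_roc, 0)
  expect_gt(m$lbgi, 0)  # 100 mg/dL sits below the risk-neutral point
  expect_equal(m$hbgi, 0)
  expect_equal(m$j_index, 10)
  expect_equal(m$gmi, 3.31 + 2.392)
  expect_equal(m$n_days, 2)  # 300 readings at 5 min span past midnight
  high <- make_series(rep(250, 10))
  mh <- compute_all(high)
  expect_equal(mh$tor_above_180, 100)
  expect_equal(mh$lbgi, 0)
})

test_that("every metric matches naive-loop recomputation on random series", {
  set.seed(99)
  for (i in 1:30) {
    n <- sample(200:1000, 1)
    v <- random_cgm_values(n)
    # random gaps in the grid so the ROC gap rule is exercised
    keep <- runif(n) > 0.1
    t0 <- as.POSIXct("2021-05-01 00:00:00", tz = "UTC")
    time <- (t0 + (seq_len(n) - 1) * 300)[keep]
    s <- glucose_series("p", time, v[keep], quiet = TRUE)
    m <- compute_all(s)
    expect_equal(m$mean, oracle_mean(s$value), tolerance = 1e-9)
    expect_equal(m$interday_sd, oracle_sd(s$value), tolerance = 1e-9)
    expect_equal(m$interday_cv, 100 * oracle_sd(s$value) / oracle_mean(s$value),
                 tolerance = 1e-9)
    expect_equal(m$sd_roc, oracle_sd_roc(s$time, s$value), tolerance = 1e-9)
    tr <- oracle_tir(s$value)
    expect_equal(m$tir, unname(tr["tir"]), tolerance = 1e-9)
    expect_equal(m$tor_below_70, unname(tr["tor_below_70"]), tolerance = 1e-9)
    expect_equal(m$tor_above_180, unname(tr["tor_above_180"]), tolerance = 1e-9)
    bg <- oracle_lbgi_hbgi(s$value)
    expect_equal(m$lbgi, unname(bg["lbgi"]), tolerance = 1e-9)
    expect_equal(m$hbgi, unname(bg["hbgi"]), tolerance = 1e-9)
    # partition invariant
    expect_equal(m$tir + m$tor_below_70 + m$tor_above_180, 100,
                 tolerance = 1e-9)
  }
})

test_that("sd_roc is invariant under time reversal", {
  set.seed(5)
  for (i in 1:10) {
    v <- random_cgm_values(300)
    s <- make_series(v)
    rev_s <- make_series(rev(v))
    expect_equal(sd_roc(s), sd_roc(rev_s), tolerance = 1e-12)
  }
})
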