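toy_tables <- function(n = 50, seed = 1) {
  set.seed(seed)
  demo <- data.frame(participant_id = sprintf("p%02d", 1:n),
                     age = round(runif(n, 20, 70)),
                     gender = sample(c("male", "female"), n, TRUE),
                     height = round(rnorm(n, 172, 9)),
                     weight = round(rnorm(n, 75, 12)))
  tor_lo <- rep(3, n)
  tir <- runif(n, 60, 95)
  metrics <- data.frame(participant_id = demo$participant_id,
                        tor_below_70 = tor_lo,
                        tir = tir,
                        tor_above_180 = 100 - tor_lo - tir,
                        sd_roc = runif(n, 0.8, 2.2))
  list(demo = demo, metrics = metrics)
}

test_that("correlation matrices are symmetric with unit diagonal and honor linear identities", {
  tt <- toy_tables()
  cm <- correlation_matrix(tt$demo, tt$metrics)
  expect_equal(unname(diag(cm)), rep(1, ncol(cm)))
  expect_equal(unclass(cm), t(unclass(cm)))
  # tor_below_70 is constant here, so its off-diagonal entries are undefined
  expect_true(all(is.na(cm["tor_below_70", -which(colnames(cm) == "tor_below_70")])))
  off <- cm[!is.na(cm)]
  expect_true(all(off >= -1 - 1e-12 & off <= 1 + 1e-12))
  # with tor_below_70 constant, tir and tor_above_180 are exact complements
  expect_equal(cm["tir", "tor_above_180"], -1, tolerance = 1e-12)
  expect_error(correlation_matrix(tt$demo[1:2, ], tt$metrics[1:2, ]),
               "at least 3")
  expect_error(correlation_matrix(tt$demo, tt$metrics,
                                  variables = c("age", "nope")), "nope")
})

test_that("independently generated variables are near-uncorrelated at large n", {
  set.seed(77)
  n <- 1000
  demo <- data.frame(participant_id = as.character(1:n),
                     age = rnorm(n), height = rnorm(n), weight = rnorm(n))
  metrics <- data.frame(participant_id = as.character(1:n),
                        tor_below_70 = rnorm(n), tir = rnorm(n),
                        tor_above_180 = rnorm(n), sd_roc = rnorm(n))
  cm <- correlation_matrix(demo, metrics)
  off <- cm[upper.tri(cm)]
  expect_true(all(abs(off) < 0.1))
})

test_that("absolute matrix differences behave entrywise", {
  tt <- toy_tables(seed = 3)
  cm <- correlation_matrix(tt$demo, tt$metrics)
  z <- matrix_abs_diff(cm, cm)
  expect_true(all(z[!is.na(z)] == 0))
  expect_equal(is.na(z), is.na(unclass(cm)))
  a <- matrix(c(1, 0.51, 0.51, 1), 2, 2,
              dimnames = list(c("sd_roc", "tor_above_180"),
                              c("sd_roc", "tor_above_180")))
  b <- matrix(c(1, 0.33, 0.33, 1), 2, 2, dimnames = dimnames(a))
  d <- matrix_abs_diff(a, b)
  expect_equal(d["sd_roc", "tor_above_180"], 0.18)
  expect_equal(unname(diag(d)), c(0, 0))
  expect_true(all(d >= 0 & d <= 2))
  colnames(b) <- rownames(b) <- c("sd_roc", "other")
  expect_error(matrix_abs_diff(a, b), "mismatch")
})

test_that("cross-data-set comparison reuses the two-sample tests per metric", {
  cfg <- sim_config(n_participants = 10, days_per_participant = 2, seed = 88)
  m <- cohort_metrics(clean_cohort(simulate_cohort(cfg))$cohort)
  same <- suppressWarnings(dataset_gv_comparison(m, m))
  expect_true(all(!same$sig_z & !same$sig_ks & !same$sig_mw))
  expect_equal(same$mean_a, same$mean_b)
  cfg2 <- sim_config(n_participants = 10, days_per_participant = 2,
                     base_mean = 175, seed = 89)
  m2 <- cohort_metrics(clean_cohort(simulate_cohort(cfg2))$cohort)
  diff <- suppressWarnings(dataset_gv_comparison(m, m2))
  expect_true(diff$sig_z[diff$metric_name == "gmi"])
  expect_error(dataset_gv_comparison(m, m2[0, ]), "non-empty")
  expect_warning(dataset_gv_comparison(m, m2[, !(names(m2) == "gmi")]),
                 "skipped")
})

test_that("the end-to-end pipeline removes planted duplicates and is deterministic", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  config <- list(
    seed = 7,
    cohort_a = list(simulate = list(n_participants = 12,
                                    days_per_participant = 3, seed = 7)),
    cohort_b = list(plant_duplicates = list(n_dup = 3, subsample_rate = 0.9,
                                            seed = 8)),
    filter = list(min_readings = 288),
    clustering = list(k_range = c(2, 5))
  )
  res1 <- suppressWarnings(suppressMessages(run_pipeline(config, out1, quiet = TRUE)))
  # planted duplicates are removed from cohort b before comparison
  expect_equal(res1$log$duplicates_removed, 3)
  expect_false(any(res1$truth$id_b %in% names(res1$cohort_b$series)))
  expect_true(file.exists(file.path(out1, "id_mapping.csv")))
  expect_true(file.exists(file.path(out1, "dataset_comparison.csv")))
  expect_true(file.exists(file.path(out1, "run_log.json")))
  # rerun: byte-identical outputs
  suppressWarnings(suppressMessages(run_pipeline(config, out2, quiet = TRUE)))
  for (f in list.files(out1)) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }
})

test_that("a single-cohort pipeline run skips dedup and comparison", {
  out <- withr::local_tempdir()
  config <- list(seed = 3,
                 cohort_a = list(simulate = list(n_participants = 8,
                                                 days_per_participant = 2)))
  res <- suppressWarnings(suppressMessages(run_pipeline(config, out, quiet = TRUE)))
  expect_null(res$matches)
  expect_null(res$comparison)
  expect_match(res$log$dedup, "skipped")
  expect_false(file.exists(file.path(out, "id_mapping.csv")))
  expect_true(file.exists(file.path(out, "metrics_a.csv")))
})
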