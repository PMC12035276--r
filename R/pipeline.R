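#' Run the full glycemic-variability analysis pipeline
#'
#' Executes ingest (or simulation) -> cleaning -> participant filter ->
#' cross-data-set deduplication (two-cohort runs only; duplicates are
#' removed from the second cohort) -> per-participant metrics -> summary and
#' gender tables -> calendar-binned time series -> profile clustering ->
#' correlation matrices and cross-cohort comparison, writing every table as
#' CSV plus a JSON run log with seeds, parameters and exclusion counts.
#' Reruns with the same config produce byte-identical outputs.
#'
#' @param config Either a named list or the path to a YAML file. Recognized
#'   entries:
#'   \describe{
#'     \item{seed}{Master seed applied to simulated cohorts lacking one.}
#'     \item{cohort_a, cohort_b}{Each either
#'       `list(simulate = <sim_config arguments>)`,
#'       `list(entries_dir = ..., demographics = ...)`, or for cohort_b
#'       `list(plant_duplicates = list(n_dup=, date_shift=, subsample_rate=, seed=))`
#'       to derive it from cohort_a. `cohort_b` is optional.}
#'     \item{filter}{Criteria list for [filter_participants()]; default
#'       `list(min_readings = 288)` (about one day of 5-minute data).}
#'     \item{dedup}{`list(threshold=, min_common=)`.}
#'     \item{alpha, max_gap}{Significance level and ROC gap rule.}
#'     \item{clustering}{`list(k_range = c(lo, hi), silhouette_threshold=,
#'       mode=)`.}
#'     \item{bins}{Calendar bin kinds for the time-series stage.}
#'   }
#' @param out_dir Output directory for CSV/JSON artifacts (created).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with every computed object (`cohorts`,
#'   `metrics`, `summary`, `gender`, `timeseries`, `clusters`,
#'   `correlations`, `comparison`, `matches`, `log`).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  seed <- as.integer(config$seed %||% 1L)
  alpha <- config$alpha %||% 0.05
  max_gap <- config$max_gap %||% 15
  filt <- config$filter %||% list(min_readings = 288)
  log <- list(seed = seed, alpha = alpha, max_gap = max_gap,
              package_version = as.character(utils::packageVersion("cgmvar")))

  load_cohort <- function(spec, default_seed) {
    if (!is.null(spec$simulate)) {
      args <- spec$simulate
      if (is.null(args$seed)) args$seed <- default_seed
      simulate_cohort(do.call(sim_config, args))
    } else if (!is.null(spec$entries_dir)) {
      read_cohort(spec$entries_dir,
                  spec$demographics %||% file.path(spec$entries_dir, "demographics.csv"))
    } else {
      stop("cohort spec needs `simulate` or `entries_dir`", call. = FALSE)
    }
  }

  say("stage: ingest")
  cohort_a <- stage("ingest", load_cohort(config$cohort_a, seed))
  two <- !is.null(config$cohort_b)
  cohort_b <- NULL
  truth <- NULL
  if (two) {
    cohort_b <- stage("ingest", {
      bspec <- config$cohort_b
      if (!is.null(bspec$plant_duplicates)) {
        pd <- bspec$plant_duplicates
        res <- plant_duplicates(cohort_a,
                                n_dup = pd$n_dup %||% 0,
                                date_shift = pd$date_shift %||% 0,
                                subsample_rate = pd$subsample_rate %||% 1,
                                seed = pd$seed %||% (seed + 1L),
                                n_new = pd$n_new, config = attr(cohort_a, "config"))
        truth <<- res$truth
        res$cohort
      } else {
        load_cohort(bspec, seed + 1L)
      }
    })
  }

  say("stage: clean")
  ca <- stage("clean", clean_cohort(cohort_a))
  cohort_a <- ca$cohort
  log$cleaning_a <- as.list(ca$report)
  if (two) {
    cb <- stage("clean", clean_cohort(cohort_b))
    cohort_b <- cb$cohort
    log$cleaning_b <- as.list(cb$report)
  }

  say("stage: filter")
  n_before <- cohort_size(cohort_a)
  cohort_a <- stage("filter", filter_participants(cohort_a, filt, quiet = TRUE))
  log$excluded_a <- n_before - cohort_size(cohort_a)
  if (two) {
    n_before <- cohort_size(cohort_b)
    cohort_b <- stage("filter", filter_participants(cohort_b, filt, quiet = TRUE))
    log$excluded_b <- n_before - cohort_size(cohort_b)
  }

  matches <- NULL
  if (two) {
    say("stage: dedup")
    dd <- config$dedup %||% list()
    matches <- stage("dedup",
      find_duplicates(cohort_a, cohort_b,
                      threshold = dd$threshold %||% 0.5,
                      min_common = dd$min_common %||% 288))
    stage("dedup", write_mapping(matches, cohort_a, cohort_b,
                                 file.path(out_dir, "id_mapping.csv"),
                                 file.path(out_dir, "id_mapping_dates.csv")))
    log$duplicates_removed <- sum(matches$is_duplicate)
    cohort_b <- drop_duplicates(cohort_b, matches)
  } else {
    log$dedup <- "skipped (single-cohort run)"
    log$comparison <- "skipped (single-cohort run)"
  }

  say("stage: metrics")
  metrics_a <- stage("metrics", cohort_metrics(cohort_a, max_gap = max_gap))
  utils::write.csv(metrics_a, file.path(out_dir, "metrics_a.csv"), row.names = FALSE)
  metrics_b <- NULL
  if (two) {
    metrics_b <- stage("metrics", cohort_metrics(cohort_b, max_gap = max_gap))
    utils::write.csv(metrics_b, file.path(out_dir, "metrics_b.csv"), row.names = FALSE)
  }

  say("stage: summaries")
  summary_a <- stage("summaries", metric_summary_table(metrics_a))
  utils::write.csv(summary_a, file.path(out_dir, "summary_a.csv"), row.names = FALSE)
  gender_a <- stage("summaries",
    gender_table(metrics_a, cohort_a$demographics, alpha = alpha))
  utils::write.csv(gender_a, file.path(out_dir, "gender_table_a.csv"), row.names = FALSE)

  say("stage: timeseries")
  bins <- config$bins %||% c("hour_of_day", "day_of_week", "day_of_month",
                             "month_of_year")
  ts_a <- stage("timeseries", {
    do.call(rbind, lapply(bins, function(bk) group_timeseries(cohort_a, bk)))
  })
  utils::write.csv(ts_a, file.path(out_dir, "timeseries_a.csv"), row.names = FALSE)

  say("stage: clustering")
  cl <- config$clustering %||% list()
  kr <- cl$k_range %||% c(2, 8)
  clusters <- stage("clustering", {
    feats <- build_feature_matrix(metrics_a, mode = cl$mode %||% "gv_metrics",
                                  cohort = cohort_a)
    assess_clusters(feats, k_range = seq(kr[1], kr[length(kr)]),
                    silhouette_threshold = cl$silhouette_threshold %||% 0.25)
  })
  utils::write.csv(
    data.frame(k = clusters$k_range, silhouette = clusters$silhouette),
    file.path(out_dir, "cluster_silhouettes.csv"), row.names = FALSE)
  log$distinct_clusters <- clusters$distinct

  say("stage: comparison")
  cor_a <- stage("comparison", correlation_matrix(cohort_a$demographics, metrics_a))
  utils::write.csv(as.data.frame(unclass(cor_a)),
                   file.path(out_dir, "correlation_a.csv"))
  comparison <- NULL
  cor_b <- NULL
  if (two) {
    cor_b <- stage("comparison", correlation_matrix(cohort_b$demographics, metrics_b))
    utils::write.csv(as.data.frame(unclass(cor_b)),
                     file.path(out_dir, "correlation_b.csv"))
    utils::write.csv(as.data.frame(matrix_abs_diff(cor_a, cor_b)),
                     file.path(out_dir, "correlation_abs_diff.csv"))
    comparison <- stage("comparison",
                        dataset_gv_comparison(metrics_a, metrics_b, alpha = alpha))
    utils::write.csv(comparison, file.path(out_dir, "dataset_comparison.csv"),
                     row.names = FALSE)
  }

  log$n_participants_a <- cohort_size(cohort_a)
  if (two) log$n_participants_b <- cohort_size(cohort_b)
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(cohort_a = cohort_a, cohort_b = cohort_b,
                 matches = matches, truth = truth,
                 metrics_a = metrics_a, metrics_b = metrics_b,
                 summary_a = summary_a, gender_a = gender_a,
                 timeseries_a = ts_a, clusters = clusters,
                 correlation_a = cor_a, correlation_b = cor_b,
                 comparison = comparison, log = log))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
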