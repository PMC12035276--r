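#' Correlation matrix between demographics and glucose metrics
#'
#' Pearson correlations (pairwise-complete) between demographic variables
#' (age, height, weight) and glucose analysis metrics (time out of range
#' below 70, time in range, time out of range above 180, SD of rate of
#' change), or any other set of columns found in the merged table. A
#' Spearman variant is available via `method`. Zero-variance variables get
#' NA rows/columns.
#'
#' @param demographics Demographics data frame.
#' @param metrics Per-participant metric table.
#' @param variables Column names to correlate (default the published
#'   heatmap's variable set).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A symmetric correlation matrix with unit diagonal (class
#'   `matrix`), with attribute `n_pairs` (pairwise-complete counts).
#' @export
correlation_matrix <- function(demographics, metrics,
                               variables = c("age", "height", "weight",
                                             "tor_below_70", "tir",
                                             "tor_above_180", "sd_roc"),
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  df <- merge(demographics, metrics, by = "participant_id")
  missing <- setdiff(variables, names(df))
  if (length(missing) > 0) {
    stop("variable(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(df[, variables, drop = FALSE])
  storage.mode(x) <- "double"
  if (sum(stats::complete.cases(x)) < 3) {
    stop("need at least 3 participants with complete values", call. = FALSE)
  }
  cm <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs",
                                    method = method))
  diag(cm) <- 1
  np <- crossprod(!is.na(x))
  attr(cm, "n_pairs") <- np
  cm
}

#' Entrywise absolute difference of two correlation matrices
#'
#' @param a,b Correlation matrices over identical variables in identical
#'   order (checked; an error lists any mismatch).
#' @return Matrix of `|a - b|`; zero diagonal.
#' @export
matrix_abs_diff <- function(a, b) {
  va <- colnames(a); vb <- colnames(b)
  if (!identical(va, vb)) {
    stop("variable mismatch: a has {", paste(va, collapse = ", "),
         "}, b has {", paste(vb, collapse = ", "), "}", call. = FALSE)
  }
  if (!all(dim(a) == dim(b))) stop("dimension mismatch", call. = FALSE)
  out <- abs(unclass(a) - unclass(b))
  attr(out, "n_pairs") <- NULL
  out
}

#' Cross-data-set comparison of glycemic-variability distributions
#'
#' For every metric present in both tables: the two distribution summaries
#' side by side plus z, KS and MW p-values between the data sets. Metrics
#' present in only one table are skipped with a warning.
#'
#' @param metrics_a,metrics_b Per-participant metric tables from the two
#'   data sets (non-empty).
#' @param alpha Significance level.
#' @param metric_cols Metric columns to compare (default [gv_metric_names()]).
#' @return A data frame, one row per metric, with `mean_a`, `mean_b`,
#'   `sd_a`, `sd_b`, `min`/`max`/`skewness` per data set and the three
#'   p-values with significance flags.
#' @export
dataset_gv_comparison <- function(metrics_a, metrics_b, alpha = 0.05,
                                  metric_cols = gv_metric_names()) {
  if (nrow(metrics_a) == 0 || nrow(metrics_b) == 0) {
    stop("both metric tables must be non-empty", call. = FALSE)
  }
  shared <- metric_cols[metric_cols %in% names(metrics_a) &
                        metric_cols %in% names(metrics_b)]
  skipped <- setdiff(metric_cols, shared)
  if (length(skipped) > 0) {
    warning("metric(s) missing from one table, skipped: ",
            paste(skipped, collapse = ", "))
  }
  rows <- lapply(shared, function(mc) {
    sa <- summarize_distribution(metrics_a[[mc]], mc)
    sb <- summarize_distribution(metrics_b[[mc]], mc)
    tst <- compare_groups(metrics_a[[mc]], metrics_b[[mc]], mc, alpha)
    data.frame(metric_name = mc, n_a = sa$n, n_b = sb$n,
               mean_a = sa$mean, mean_b = sb$mean,
               sd_a = sa$sd, sd_b = sb$sd,
               min_a = sa$min, min_b = sb$min,
               max_a = sa$max, max_b = sb$max,
               skewness_a = sa$skewness, skewness_b = sb$skewness,
               p_z = tst$p_z, p_ks = tst$p_ks, p_mw = tst$p_mw,
               sig_z = tst$sig_z, sig_ks = tst$sig_ks, sig_mw = tst$sig_mw,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
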