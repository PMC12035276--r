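#' Distribution summary of a per-participant metric
#'
#' Sample mean and SD, min/max, linear-interpolation quartiles (type 7),
#' IQR enforced as `q3 - q1`, and Fisher-Pearson skewness
#' `g1 = m3 / m2^(3/2)` (biased moment form). A zero-variance input has
#' undefined skewness; it is reported as 0 with `degenerate = TRUE`.
#'
#' @param values Numeric vector of per-participant metric values (n >= 2,
#'   no NAs).
#' @param metric_name Label for the metric.
#' @return A one-row data frame: `metric_name`, `n`, `mean`, `sd`, `min`,
#'   `max`, `q1`, `q2`, `q3`, `iqr`, `skewness`, `degenerate`.
#' @examples
#' summarize_distribution(1:5, "toy")  # q1 2, q2 3, q3 4, iqr 2, skewness 0
#' @export
summarize_distribution <- function(values, metric_name = "metric") {
  values <- as.numeric(values)
  if (anyNA(values)) stop("values contain NA", call. = FALSE)
  n <- length(values)
  if (n < 2) stop("need at least 2 values to summarize", call. = FALSE)
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  m2 <- mean((values - mean(values))^2)
  degenerate <- m2 == 0
  skew <- if (degenerate) 0 else mean((values - mean(values))^3) / m2^1.5
  data.frame(metric_name = metric_name, n = n,
             mean = mean(values), sd = stats::sd(values),
             min = min(values), max = max(values),
             q1 = q[1], q2 = q[2], q3 = q[3], iqr = q[3] - q[1],
             skewness = skew, degenerate = degenerate,
             stringsAsFactors = FALSE)
}

#' Two-sample z-test on means
#'
#' Unpaired two-sided z-test with a Welch-style (unpooled) standard error
#' from the sample SDs. A warning is issued when either group has fewer
#' than 30 observations (the normal approximation is then doubtful).
#'
#' @param a,b Numeric vectors (n >= 2 each).
#' @return Two-sided p-value.
#' @export
z_test <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("z-test needs at least 2 values per group", call. = FALSE)
  if (min(na, nb) < 30) {
    warning("z-test with a group below n = 30: normal approximation is rough")
  }
  se <- sqrt(stats::var(a) / na + stats::var(b) / nb)
  if (se == 0) return(if (mean(a) == mean(b)) 1 else 0)
  z <- (mean(a) - mean(b)) / se
  2 * stats::pnorm(-abs(z))
}

#' Compare a metric's distribution between two groups
#'
#' Runs the two-sided two-sample z-test ([z_test()]), Kolmogorov-Smirnov
#' test and Mann-Whitney U test (normal approximation with continuity and
#' tie correction), and flags significance at `alpha`.
#'
#' @param values_a,values_b Per-participant metric values in each group.
#' @param metric_name Label.
#' @param alpha Significance level (default 0.05).
#' @return A one-row data frame: `metric_name`, `p_z`, `p_ks`, `p_mw`,
#'   `sig_z`, `sig_ks`, `sig_mw`.
#' @export
compare_groups <- function(values_a, values_b, metric_name = "metric",
                           alpha = 0.05) {
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (length(a) < 2 || length(b) < 2) {
    stop("both groups need at least 2 values", call. = FALSE)
  }
  p_z <- suppressWarnings(z_test(a, b))
  p_ks <- suppressWarnings(stats::ks.test(a, b)$p.value)
  p_mw <- suppressWarnings(
    stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
  data.frame(metric_name = metric_name,
             p_z = p_z, p_ks = p_ks, p_mw = p_mw,
             sig_z = p_z < alpha, sig_ks = p_ks < alpha, sig_mw = p_mw < alpha,
             stringsAsFactors = FALSE)
}

#' Gender-stratified metric table with distribution tests
#'
#' For every glycemic-variability metric: female and male distribution
#' summaries side by side plus z, KS and MW p-values — the layout of a
#' gender sub-analysis table. Participants with unreported gender are
#' excluded.
#'
#' @param metrics Per-participant metric table ([cohort_metrics()]).
#' @param demographics Demographics data frame with `participant_id` and
#'   `gender`.
#' @param metric_cols Metric columns to analyze (default [gv_metric_names()]
#'   minus `mean`, mirroring the published table layout, which reports the
#'   mean through GMI).
#' @param alpha Significance level.
#' @param min_n Minimum participants per gender group (default 2).
#' @return A data frame, one row per metric: `mean_f`, `mean_m`, `sd_f`,
#'   `sd_m`, `min_f`, `min_m`, `max_f`, `max_m`, `skewness_f`, `skewness_m`,
#'   `p_z`, `p_ks`, `p_mw` and significance flags.
#' @export
gender_table <- function(metrics, demographics,
                         metric_cols = setdiff(gv_metric_names(), "mean"),
                         alpha = 0.05, min_n = 2) {
  df <- merge(metrics, demographics[, c("participant_id", "gender")],
              by = "participant_id")
  df <- df[df$gender %in% c("male", "female"), , drop = FALSE]
  nf <- sum(df$gender == "female"); nm <- sum(df$gender == "male")
  if (nf < min_n || nm < min_n) {
    low <- c("female", "male")[c(nf, nm) < min_n]
    stop("gender group(s) below minimum n: ", paste(low, collapse = ", "),
         call. = FALSE)
  }
  missing_cols <- setdiff(metric_cols, names(df))
  if (length(missing_cols) > 0) {
    stop("metric column(s) not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(metric_cols, function(mc) {
    f <- df[[mc]][df$gender == "female"]
    m <- df[[mc]][df$gender == "male"]
    sf <- summarize_distribution(f, mc)
    sm <- summarize_distribution(m, mc)
    tst <- compare_groups(f, m, mc, alpha)
    data.frame(metric_name = mc, n_f = nf, n_m = nm,
               mean_f = sf$mean, mean_m = sm$mean,
               sd_f = sf$sd, sd_m = sm$sd,
               min_f = sf$min, min_m = sm$min,
               max_f = sf$max, max_m = sm$max,
               skewness_f = sf$skewness, skewness_m = sm$skewness,
               p_z = tst$p_z, p_ks = tst$p_ks, p_mw = tst$p_mw,
               sig_z = tst$sig_z, sig_ks = tst$sig_ks, sig_mw = tst$sig_mw,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Table-1-style summary of every metric over a cohort
#'
#' @param metrics Per-participant metric table ([cohort_metrics()]).
#' @param metric_cols Metric columns to summarize.
#' @return A data frame, one [summarize_distribution()] row per metric.
#' @export
metric_summary_table <- function(metrics, metric_cols = gv_metric_names()) {
  rows <- lapply(metric_cols, function(mc) {
    summarize_distribution(metrics[[mc]], mc)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
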