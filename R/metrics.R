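#' Time in range and time out of range
#'
#' Fractions of readings (as percentages) in the consensus target range
#' \[70, 180\] mg/dL (inclusive), below 70, and above 180. The three bands
#' partition the readings, so the percentages sum to 100. Percent-of-readings,
#' not duration-weighted.
#'
#' @param series A cleaned, non-empty [glucose_series].
#' @return Named numeric vector `c(tir, tor_below_70, tor_above_180)`.
#' @examples
#' s <- glucose_series("p", sprintf("2021-01-01T00:%02d", 0:3),
#'                     c(60, 100, 150, 200))
#' time_in_ranges(s)  # 50, 25, 25
#' @export
time_in_ranges <- function(series) {
  stopifnot(inherits(series, "glucose_series"))
  n <- length(series)
  if (n == 0) stop("time in range undefined for an empty series", call. = FALSE)
  v <- series$value
  c(tir = 100 * mean(v >= 70 & v <= 180),
    tor_below_70 = 100 * mean(v < 70),
    tor_above_180 = 100 * mean(v > 180))
}

#' Standard deviation of the glucose rate of change
#'
#' Per-pair rates `(v_i - v_{i-1}) / (t_i - t_{i-1})` in mg/dL per minute
#' are computed for consecutive readings no more than `max_gap` minutes
#' apart (rates across sensor gaps are artefactual); the sample standard
#' deviation of those rates is returned.
#'
#' @param series A cleaned [glucose_series] with at least 3 readings.
#' @param max_gap Maximum pair gap in minutes (default 15).
#' @return SD of rate of change, mg/dL per minute.
#' @export
sd_roc <- function(series, max_gap = 15) {
  stopifnot(inherits(series, "glucose_series"))
  if (length(series) < 3) stop("sd_roc requires at least 3 readings", call. = FALSE)
  dt <- as.numeric(diff(series$time), units = "mins")
  rates <- diff(series$value) / dt
  rates <- rates[dt > 0 & dt <= max_gap]
  if (length(rates) < 2) {
    stop("sd_roc undefined: fewer than 2 consecutive pairs within max_gap",
         call. = FALSE)
  }
  stats::sd(rates)
}

#' Low and high blood glucose indices
#'
#' The glucose scale is symmetrized with
#' `f(g) = 1.509 * ((ln g)^1.084 - 5.381)` (g in mg/dL) and each reading is
#' assigned a risk `r(g) = 10 * f(g)^2`. LBGI is the mean risk over readings
#' with `f(g) < 0` (hypoglycemic branch) and HBGI the mean over `f(g) > 0`;
#' both are non-negative and zero only when no reading falls on that branch.
#'
#' @param series A cleaned, non-empty [glucose_series] in mg/dL.
#' @return Named numeric vector `c(lbgi, hbgi)`.
#' @export
lbgi_hbgi <- function(series) {
  stopifnot(inherits(series, "glucose_series"))
  if (length(series) == 0) stop("LBGI/HBGI undefined for an empty series", call. = FALSE)
  g <- series$value
  if (any(g <= 0)) stop("glucose values must be positive", call. = FALSE)
  f <- 1.509 * (log(g)^1.084 - 5.381)
  r <- 10 * f^2
  c(lbgi = mean(r * (f < 0)), hbgi = mean(r * (f > 0)))
}

#' J-index
#'
#' `0.001 * (mean + sd)^2` in the mg/dL convention: a composite of central
#' tendency and variability.
#'
#' @param mean Mean glucose, mg/dL (positive).
#' @param sd Glucose SD, mg/dL (non-negative).
#' @return Dimensionless J-index.
#' @examples
#' j_index(100, 0)  # 10
#' @export
j_index <- function(mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  0.001 * (mean + sd)^2
}

#' Glucose management indicator
#'
#' The standard mg/dL regression `GMI = 3.31 + 0.02392 * mean`, mapping mean
#' glucose to an HbA1c-like percentage. Affine, so the GMI of a group's mean
#' glucose equals the group's mean GMI.
#'
#' @param mean Mean glucose, mg/dL (positive); vectorized.
#' @return GMI in %-units.
#' @examples
#' round(gmi(132.20), 2)  # 6.47
#' @export
gmi <- function(mean) {
  stopifnot(all(mean > 0))
  3.31 + 0.02392 * mean
}

#' Pooled mean, interday SD and CV
#'
#' Mean and sample SD over all cleaned readings pooled across the full
#' record, and the coefficient of variation `100 * sd / mean`.
#'
#' @param series A cleaned [glucose_series] with at least 2 readings.
#' @return Named numeric vector `c(mean, sd, cv)`.
#' @export
interday_sd_cv <- function(series) {
  stopifnot(inherits(series, "glucose_series"))
  if (length(series) < 2) stop("mean/SD undefined below 2 readings", call. = FALSE)
  m <- mean(series$value)
  s <- stats::sd(series$value)
  c(mean = m, sd = s, cv = 100 * s / m)
}

#' All glycemic-variability metrics for one participant
#'
#' Assembles the full per-participant metric vector: reading and day counts,
#' pooled mean/SD/CV, SD of rate of change, time in/out of range, LBGI,
#' HBGI, J-index and GMI.
#'
#' @param series A cleaned [glucose_series] (at least 3 readings).
#' @param max_gap Maximum pair gap in minutes for the rate of change
#'   (default 15).
#' @return A one-row data frame with columns `participant_id`, `n_readings`,
#'   `n_days`, `mean`, `interday_sd`, `interday_cv`, `sd_roc`, `tir`,
#'   `tor_below_70`, `tor_above_180`, `lbgi`, `hbgi`, `j_index`, `gmi`.
#' @export
compute_all <- function(series, max_gap = 15) {
  msd <- interday_sd_cv(series)
  tr <- time_in_ranges(series)
  bg <- lbgi_hbgi(series)
  data.frame(
    participant_id = series$participant_id,
    n_readings = length(series),
    n_days = length(unique(as.Date(series$time))),
    mean = unname(msd["mean"]),
    interday_sd = unname(msd["sd"]),
    interday_cv = unname(msd["cv"]),
    sd_roc = sd_roc(series, max_gap),
    tir = unname(tr["tir"]),
    tor_below_70 = unname(tr["tor_below_70"]),
    tor_above_180 = unname(tr["tor_above_180"]),
    lbgi = unname(bg["lbgi"]),
    hbgi = unname(bg["hbgi"]),
    j_index = unname(j_index(msd["mean"], msd["sd"])),
    gmi = unname(gmi(msd["mean"])),
    stringsAsFactors = FALSE
  )
}

#' Per-participant metric table for a cohort
#'
#' @param cohort A cleaned [cgm_cohort]; participants should already satisfy
#'   the inclusion threshold (see [filter_participants()]).
#' @param max_gap Maximum pair gap in minutes for the rate of change.
#' @return A data frame, one row per participant (see [compute_all()]).
#' @export
cohort_metrics <- function(cohort, max_gap = 15) {
  stopifnot(inherits(cohort, "cgm_cohort"))
  rows <- lapply(cohort$series, compute_all, max_gap = max_gap)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Names of the glycemic-variability metric columns
#' @return Character vector of metric column names in [compute_all()] output.
#' @export
gv_metric_names <- function() {
  c("mean", "interday_sd", "interday_cv", "sd_roc", "tir",
    "tor_below_70", "tor_above_180", "lbgi", "hbgi", "j_index", "gmi")
}
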