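#' Bin one participant's readings by calendar unit
#'
#' Groups readings by hour of day (0-23), day of week (Monday = 0), day of
#' month (1-31) or month of year (1-12), derived from the local timestamp,
#' and returns the participant's mean and sample SD per bin. Bins with fewer
#' than 2 readings are skipped.
#'
#' @param series A cleaned, non-empty [glucose_series].
#' @param bin_kind One of `"hour_of_day"`, `"day_of_week"`, `"day_of_month"`,
#'   `"month_of_year"`.
#' @return A data frame: `bin_kind`, `bin`, `mean`, `sd`, `n`.
#' @export
bin_series <- function(series, bin_kind = c("hour_of_day", "day_of_week",
                                            "day_of_month", "month_of_year")) {
  stopifnot(inherits(series, "glucose_series"))
  bin_kind <- match.arg(bin_kind)
  if (length(series) == 0) stop("cannot bin an empty series", call. = FALSE)
  lt <- as.POSIXlt(series$time, tz = "UTC")
  bin <- switch(bin_kind,
    hour_of_day = lt$hour,
    day_of_week = (lt$wday + 6L) %% 7L,  # Monday = 0
    day_of_month = lt$mday,
    month_of_year = lt$mon + 1L)
  n <- tapply(series$value, bin, length)
  keep <- n >= 2
  if (!any(keep)) stop("no bin holds 2 or more readings", call. = FALSE)
  means <- tapply(series$value, bin, mean)[keep]
  sds <- tapply(series$value, bin, stats::sd)[keep]
  data.frame(bin_kind = bin_kind,
             bin = as.integer(names(means)),
             mean = unname(means), sd = unname(sds), n = unname(n[keep]),
             stringsAsFactors = FALSE)
}

#' Gender-stratified calendar-binned glucose curves
#'
#' For each gender group and calendar bin, the group curve is the unweighted
#' mean over participants of the per-participant bin means (`avg_mean`) and
#' bin SDs (`avg_sd`): each participant counts equally regardless of record
#' length. Pooled weighting (all readings pooled per group and bin) is
#' available via `weighting = "pooled"`. Groups with zero participants are
#' omitted with a warning.
#'
#' @param cohort A cleaned [cgm_cohort] with gender in its demographics.
#' @param bin_kind See [bin_series()].
#' @param weighting `"participant"` (default) or `"pooled"`.
#' @param groups Gender labels to include (default male and female).
#' @return A data frame: `bin_kind`, `bin`, `group`, `avg_mean`, `avg_sd`,
#'   `n_participants`.
#' @export
group_timeseries <- function(cohort,
                             bin_kind = c("hour_of_day", "day_of_week",
                                          "day_of_month", "month_of_year"),
                             weighting = c("participant", "pooled"),
                             groups = c("female", "male")) {
  stopifnot(inherits(cohort, "cgm_cohort"))
  bin_kind <- match.arg(bin_kind)
  weighting <- match.arg(weighting)
  demo <- cohort$demographics
  out <- list()
  for (g in groups) {
    ids <- demo$participant_id[demo$gender == g]
    ids <- intersect(ids, names(cohort$series))
    if (length(ids) == 0) {
      warning("group '", g, "' has zero participants; omitted")
      next
    }
    if (weighting == "participant") {
      per <- do.call(rbind, lapply(ids, function(id) {
        b <- bin_series(cohort$series[[id]], bin_kind)
        b$participant_id <- id
        b
      }))
      agg_mean <- tapply(per$mean, per$bin, mean)
      agg_sd <- tapply(per$sd, per$bin, mean)
      npart <- tapply(per$participant_id, per$bin, function(x) length(unique(x)))
      out[[g]] <- data.frame(bin_kind = bin_kind,
                             bin = as.integer(names(agg_mean)),
                             group = g,
                             avg_mean = unname(agg_mean),
                             avg_sd = unname(agg_sd),
                             n_participants = as.integer(unname(npart)),
                             stringsAsFactors = FALSE)
    } else {
      # pool readings across participants (duplicate timestamps allowed here)
      time <- do.call(c, lapply(ids, function(id) cohort$series[[id]]$time))
      value <- unlist(lapply(ids, function(id) cohort$series[[id]]$value))
      lt <- as.POSIXlt(time, tz = "UTC")
      bin <- switch(bin_kind,
        hour_of_day = lt$hour,
        day_of_week = (lt$wday + 6L) %% 7L,
        day_of_month = lt$mday,
        month_of_year = lt$mon + 1L)
      n <- tapply(value, bin, length)
      keep <- n >= 2
      means <- tapply(value, bin, mean)[keep]
      sds <- tapply(value, bin, stats::sd)[keep]
      out[[g]] <- data.frame(bin_kind = bin_kind,
                             bin = as.integer(names(means)), group = g,
                             avg_mean = unname(means), avg_sd = unname(sds),
                             n_participants = length(ids),
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
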