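#' Construct a glucose series
#'
#' A `glucose_series` holds one participant's timestamped CGM readings in
#' mg/dL. Timestamps are naive local time (stored as POSIXct in a fixed
#' zone with no timezone arithmetic) at 1-second resolution. Readings are
#' sorted ascending by time; readings sharing an identical timestamp are
#' collapsed to the first occurrence.
#'
#' @param participant_id Opaque participant identifier (coerced to character).
#' @param time Timestamps: POSIXct, or character parseable as ISO-8601 local
#'   time with or without seconds (`"2021-03-01T08:05"` or
#'   `"2021-03-01 08:05:00"`).
#' @param value Glucose readings in mg/dL (positive numbers).
#' @param quiet Suppress the message emitted when duplicate timestamps are
#'   collapsed.
#' @return An object of class `glucose_series`: a list with elements
#'   `participant_id`, `time` (POSIXct) and `value` (numeric).
#' @examples
#' s <- glucose_series("p1", c("2021-03-01T08:05", "2021-03-01T08:00"),
#'                     c(132, 128))
#' s$value  # sorted by time: 128, 132
#' @export
glucose_series <- function(participant_id, time, value, quiet = FALSE) {
  if (length(time) != length(value)) {
    stop("`time` and `value` must have the same length", call. = FALSE)
  }
  time <- parse_local_time(time)
  if (anyNA(time)) stop("unparseable timestamp in `time`", call. = FALSE)
  value <- as.numeric(value)
  if (anyNA(value)) stop("missing glucose value", call. = FALSE)
  ord <- order(time)
  time <- time[ord]
  value <- value[ord]
  dup <- duplicated(time)
  if (any(dup)) {
    if (!quiet) {
      message(sprintf("participant %s: dropped %d reading(s) at duplicate timestamps (kept first)",
                      participant_id, sum(dup)))
    }
    time <- time[!dup]
    value <- value[!dup]
  }
  structure(
    list(participant_id = as.character(participant_id)[1],
         time = time, value = value),
    class = "glucose_series"
  )
}

# ISO-8601 local time, "T" or space separator, seconds optional; no tz math.
# Stored in UTC purely as a fixed frame so arithmetic never crosses DST.
parse_local_time <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(format(x, "%Y-%m-%d %H:%M:%S"), tz = "UTC"))
  x <- gsub("T", " ", as.character(x), fixed = TRUE)
  out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  miss <- is.na(out)
  if (any(miss)) {
    out[miss] <- as.POSIXct(x[miss], tz = "UTC", format = "%Y-%m-%d %H:%M")
  }
  out
}

#' @export
print.glucose_series <- function(x, ...) {
  n <- length(x$value)
  cat(sprintf("<glucose_series> participant %s: %d readings", x$participant_id, n))
  if (n > 0) {
    cat(sprintf(", %s to %s, mean %.1f mg/dL",
                format(min(x$time)), format(max(x$time)), mean(x$value)))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.glucose_series <- function(x) length(x$value)

#' Construct a CGM cohort
#'
#' A `cgm_cohort` bundles a set of per-participant glucose series with a
#' demographics table keyed by `participant_id`.
#'
#' @param series Named list of [glucose_series] objects (names are
#'   participant IDs; taken from each series if unnamed).
#' @param demographics Data frame with at least a `participant_id` column.
#' @return An object of class `cgm_cohort`.
#' @export
cgm_cohort <- function(series, demographics) {
  stopifnot(is.list(series), is.data.frame(demographics))
  if (is.null(names(series)) && length(series) > 0) {
    names(series) <- vapply(series, function(s) s$participant_id, character(1))
  }
  if (!"participant_id" %in% names(demographics)) {
    stop("demographics must have a `participant_id` column", call. = FALSE)
  }
  demographics$participant_id <- as.character(demographics$participant_id)
  structure(list(series = series, demographics = demographics),
            class = "cgm_cohort")
}

#' @export
print.cgm_cohort <- function(x, ...) {
  nr <- sum(vapply(x$series, length, integer(1)))
  cat(sprintf("<cgm_cohort> %d participants, %d readings\n",
              length(x$series), nr))
  if (nrow(x$demographics) > 0 && "gender" %in% names(x$demographics)) {
    tb <- table(x$demographics$gender)
    cat("  gender:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

cohort_size <- function(cohort) length(cohort$series)
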