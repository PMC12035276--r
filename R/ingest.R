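#' Write a glucose series as entries JSON
#'
#' Serializes one participant's readings as a JSON array of
#' `{"glucose": <integer mg/dL>, "timestamp": "<ISO-8601 local time>"}`
#' objects, the convention used by open-source diabetes tooling exports.
#' Round-trips losslessly through [read_entries_json()].
#'
#' @param series A non-empty [glucose_series].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_entries_json <- function(series, path) {
  stopifnot(inherits(series, "glucose_series"))
  if (length(series) == 0) stop("refusing to write an empty series", call. = FALSE)
  df <- data.frame(glucose = as.integer(round(series$value)),
                   timestamp = format(series$time, "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}

#' Write a cohort as a directory of entries JSON files plus demographics CSV
#'
#' One `<participant_id>.json` per participant (empty series are skipped)
#' and a `demographics.csv` with a header row.
#'
#' @param cohort A [cgm_cohort].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cgm_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$series)) {
    if (length(cohort$series[[id]]) == 0) next
    write_entries_json(cohort$series[[id]], file.path(dir, paste0(id, ".json")))
  }
  utils::write.csv(cohort$demographics, file.path(dir, "demographics.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a glucose entries JSON file
#'
#' Accepts a JSON array whose elements carry a glucose value in mg/dL
#' (field `glucose` or the Nightscout field `sgv`) and a local-time
#' ISO-8601 timestamp (field `timestamp` or `dateString`). Readings are
#' returned sorted by timestamp; raw values are preserved (cleaning is a
#' separate step, see [clean_series()]).
#'
#' @param path Path to the JSON file.
#' @param participant_id Participant identifier; defaults to the file name
#'   without extension.
#' @return A [glucose_series].
#' @export
read_entries_json <- function(path, participant_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(participant_id)) {
    participant_id <- sub("\\.[^.]*$", "", basename(path))
  }
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
                  error = function(e) {
                    stop(sprintf("malformed JSON in %s: %s", path,
                                 conditionMessage(e)), call. = FALSE)
                  })
  if (length(raw) == 0) {
    return(glucose_series(participant_id,
                          as.POSIXct(character(0), tz = "UTC"), numeric(0)))
  }
  if (!is.data.frame(raw)) {
    stop("entries JSON must be an array of objects: ", path, call. = FALSE)
  }
  gcol <- intersect(c("glucose", "sgv"), names(raw))[1]
  tcol <- intersect(c("timestamp", "dateString"), names(raw))[1]
  if (is.na(gcol)) stop("schema error: no glucose/sgv field in ", path, call. = FALSE)
  if (is.na(tcol)) stop("schema error: no timestamp/dateString field in ", path, call. = FALSE)
  bad <- which(is.na(raw[[gcol]]) | is.na(raw[[tcol]]) | raw[[tcol]] == "")
  if (length(bad) > 0) {
    stop(sprintf("schema error in %s: missing glucose or timestamp at element(s) %s",
                 path, paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  glucose_series(participant_id, raw[[tcol]], raw[[gcol]])
}

#' Read a cohort from a directory of entries JSON files
#'
#' @param entries_dir Directory of `*.json` entries files (file name =
#'   participant ID).
#' @param demographics Path to the demographics CSV, or a demographics data
#'   frame; defaults to `demographics.csv` inside `entries_dir`.
#' @return A [cgm_cohort].
#' @export
read_cohort <- function(entries_dir,
                        demographics = file.path(entries_dir, "demographics.csv")) {
  files <- sort(list.files(entries_dir, pattern = "\\.json$", full.names = TRUE))
  series <- lapply(files, read_entries_json)
  names(series) <- vapply(series, function(s) s$participant_id, character(1))
  demo <- if (is.data.frame(demographics)) demographics
          else read_demographics_csv(demographics)
  cgm_cohort(series, demo)
}

#' Apply the glucose cleaning rule
#'
#' Values in \[400, 1000\] mg/dL are capped at 400; values above 1000 are
#' omitted; everything else is unchanged. Non-positive values are treated as
#' corrupt input and raise an error. The operation is idempotent.
#'
#' @param series A [glucose_series] with positive values.
#' @return A list with `series` (the cleaned [glucose_series]) and `report`,
#'   a named integer vector with counts `capped`, `omitted` and `kept`.
#' @examples
#' s <- glucose_series("p", sprintf("2021-01-01T00:%02d", 0:4),
#'                     c(350, 400, 450, 1000, 1001))
#' clean_series(s)$report  # capped 3, omitted 1, kept 4
#' @export
clean_series <- function(series) {
  stopifnot(inherits(series, "glucose_series"))
  v <- series$value
  if (any(v <= 0)) {
    stop(sprintf("participant %s: non-positive glucose value (corrupt input)",
                 series$participant_id), call. = FALSE)
  }
  omit <- v > 1000
  cap <- v >= 400 & v <= 1000
  v[cap] <- 400
  out <- series
  out$value <- v[!omit]
  out$time <- series$time[!omit]
  list(series = out,
       report = c(capped = sum(cap), omitted = sum(omit), kept = sum(!omit)))
}

#' Clean every series in a cohort
#'
#' @param cohort A [cgm_cohort].
#' @return A list with `cohort` (cleaned) and `report` (aggregate counts).
#' @export
clean_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cgm_cohort"))
  total <- c(capped = 0L, omitted = 0L, kept = 0L)
  for (id in names(cohort$series)) {
    res <- clean_series(cohort$series[[id]])
    cohort$series[[id]] <- res$series
    total <- total + res$report
  }
  list(cohort = cohort, report = total)
}

#' Read a demographics CSV
#'
#' Expects a header row and a `participant_id` column. Gender strings are
#' normalized to `male` / `female`; anything else (including empty cells)
#' maps to `unreported`. Missing numeric cells become `NA`.
#'
#' @param path Path to the CSV (RFC-4180, UTF-8, header row).
#' @return A data frame of demographic records.
#' @export
read_demographics_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if (!"participant_id" %in% names(df)) {
    stop("schema error: demographics CSV has no participant_id column",
         call. = FALSE)
  }
  df$participant_id <- as.character(df$participant_id)
  dup <- df$participant_id[duplicated(df$participant_id)]
  if (length(dup) > 0) {
    stop("duplicate participant_id in demographics: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if ("gender" %in% names(df)) {
    g <- tolower(trimws(ifelse(is.na(df$gender), "", df$gender)))
    df$gender <- ifelse(g %in% c("male", "m"), "male",
                 ifelse(g %in% c("female", "f"), "female", "unreported"))
  } else {
    df$gender <- "unreported"
  }
  df
}

#' Filter a cohort by declarative criteria
#'
#' Criteria are a named list. Reserved names: `min_readings` (minimum number
#' of readings) and `min_days` (minimum record span in days, computed as the
#' elapsed time between first and last reading). Any other name must be a
#' demographics column and its value either a vector of allowed values or a
#' predicate function of the column value. One message is logged per
#' excluded participant, naming the failing criterion.
#'
#' @param cohort A [cgm_cohort].
#' @param criteria Named list of criteria; empty list keeps everything.
#' @param quiet Suppress per-exclusion messages.
#' @return The filtered [cgm_cohort].
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(sim_config(n_participants = 6, days_per_participant = 2))
#' filter_participants(cohort, list(gender = "male", min_readings = 100))
#' }
#' @export
filter_participants <- function(cohort, criteria = list(), quiet = FALSE) {
  stopifnot(inherits(cohort, "cgm_cohort"))
  if (length(criteria) == 0) return(cohort)
  demo <- cohort$demographics
  reserved <- c("min_readings", "min_days")
  unknown <- setdiff(setdiff(names(criteria), reserved), names(demo))
  if (length(unknown) > 0) {
    stop("criteria reference unknown field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  keep_id <- character(0)
  for (id in names(cohort$series)) {
    s <- cohort$series[[id]]
    drow <- demo[demo$participant_id == id, , drop = FALSE]
    fail <- NULL
    for (nm in names(criteria)) {
      crit <- criteria[[nm]]
      ok <- if (nm == "min_readings") {
        length(s) >= crit
      } else if (nm == "min_days") {
        length(s) >= 2 &&
          as.numeric(difftime(max(s$time), min(s$time), units = "days")) >= crit
      } else if (is.function(crit)) {
        nrow(drow) == 1 && isTRUE(crit(drow[[nm]]))
      } else {
        nrow(drow) == 1 && !is.na(drow[[nm]]) && drow[[nm]] %in% crit
      }
      if (!ok) { fail <- nm; break }
    }
    if (is.null(fail)) {
      keep_id <- c(keep_id, id)
    } else if (!quiet) {
      message(sprintf("excluding participant %s: failed criterion '%s'", id, fail))
    }
  }
  out <- cgm_cohort(cohort$series[keep_id],
                    demo[demo$participant_id %in% keep_id, , drop = FALSE])
  attr(out, "config") <- attr(cohort, "config")
  out
}
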