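#' Fingerprint a glucose series for deduplication
#'
#' Participants are identified across data sets purely by their glucose
#' values and timestamps: the fingerprint is the set of unique
#' (timestamp rounded to the nearest minute, glucose value) pairs, plus the
#' set of calendar dates covered. Minute rounding absorbs sub-minute
#' serialization jitter between export pipelines.
#'
#' @param series A non-empty, cleaned [glucose_series].
#' @return An object of class `pair_fingerprint` with elements
#'   `participant_id`, `pairs` (character set of `"minute|value"` keys) and
#'   `dates` (Date vector).
#' @export
fingerprint_series <- function(series) {
  stopifnot(inherits(series, "glucose_series"))
  if (length(series) == 0) {
    stop(sprintf("participant %s: cannot fingerprint an empty series",
                 series$participant_id), call. = FALSE)
  }
  minute <- round(series$time, "mins")
  keys <- unique(paste(format(minute, "%Y-%m-%d %H:%M"), series$value, sep = "|"))
  structure(list(participant_id = series$participant_id,
                 pairs = keys,
                 dates = sort(unique(as.Date(substr(keys, 1, 10))))),
            class = "pair_fingerprint")
}

#' Normalized symmetric-difference distance between two fingerprints
#'
#' `distance = |A Δ B| / |A ∪ B|` over the (timestamp, glucose)
#' pair sets — equivalently one minus the Jaccard similarity. Zero iff the
#' sets are identical, one iff they are disjoint.
#'
#' @param a,b Non-empty [fingerprint_series()] results.
#' @return A one-row data frame with `id_a`, `id_b`, `n_common` and
#'   `distance`.
#' @export
pair_distance <- function(a, b) {
  stopifnot(inherits(a, "pair_fingerprint"), inherits(b, "pair_fingerprint"))
  if (length(a$pairs) == 0 || length(b$pairs) == 0) {
    stop("fingerprints must be non-empty", call. = FALSE)
  }
  n_common <- sum(a$pairs %in% b$pairs)
  n_union <- length(a$pairs) + length(b$pairs) - n_common
  data.frame(id_a = a$participant_id, id_b = b$participant_id,
             n_common = n_common, distance = 1 - n_common / n_union,
             stringsAsFactors = FALSE)
}

#' Find duplicate participants across two cohorts
#'
#' Scores every cross-data-set pair with [pair_distance()], flags pairs with
#' `distance <= threshold` and `n_common >= min_common`, and resolves flags
#' to a one-to-one matching by greedy assignment in ascending distance
#' (ties broken by lexicographic ID order), so each participant appears in
#' at most one duplicate pair.
#'
#' @param cohort_a,cohort_b [cgm_cohort] objects (cleaned).
#' @param threshold Maximum normalized symmetric-difference distance for a
#'   duplicate (default 0.5).
#' @param min_common Minimum shared (timestamp, glucose) pairs (default 288,
#'   about one day of shared 5-minute readings).
#' @return A data frame of class `dedup_matches`, one row per cross pair,
#'   sorted by distance, with columns `id_a`, `id_b`, `n_common`, `distance`
#'   and `is_duplicate`.
#' @export
find_duplicates <- function(cohort_a, cohort_b, threshold = 0.5,
                            min_common = 288) {
  stopifnot(inherits(cohort_a, "cgm_cohort"), inherits(cohort_b, "cgm_cohort"))
  empty <- data.frame(id_a = character(0), id_b = character(0),
                      n_common = integer(0), distance = numeric(0),
                      is_duplicate = logical(0), stringsAsFactors = FALSE)
  if (cohort_size(cohort_a) == 0 || cohort_size(cohort_b) == 0) {
    warning("empty cohort: no duplicate search performed")
    return(structure(empty, class = c("dedup_matches", "data.frame")))
  }
  fa <- lapply(cohort_a$series, fingerprint_series)
  fb <- lapply(cohort_b$series, fingerprint_series)
  rows <- vector("list", length(fa) * length(fb))
  k <- 0
  for (i in seq_along(fa)) {
    for (j in seq_along(fb)) {
      k <- k + 1
      rows[[k]] <- pair_distance(fa[[i]], fb[[j]])
    }
  }
  m <- do.call(rbind, rows)
  m <- m[order(m$distance, m$id_a, m$id_b), , drop = FALSE]
  rownames(m) <- NULL
  eligible <- m$distance <= threshold & m$n_common >= min_common
  m$is_duplicate <- FALSE
  used_a <- used_b <- character(0)
  for (r in which(eligible)) {
    if (m$id_a[r] %in% used_a || m$id_b[r] %in% used_b) next
    m$is_duplicate[r] <- TRUE
    used_a <- c(used_a, m$id_a[r])
    used_b <- c(used_b, m$id_b[r])
  }
  structure(m, class = c("dedup_matches", "data.frame"))
}

#' @export
print.dedup_matches <- function(x, ...) {
  cat(sprintf("<dedup_matches> %d cross pairs scored, %d duplicate(s) flagged\n",
              nrow(x), sum(x$is_duplicate)))
  if (any(x$is_duplicate)) print.data.frame(x[x$is_duplicate, ], row.names = FALSE)
  invisible(x)
}

#' Write the duplicate ID mapping and date-coverage files
#'
#' File 1 maps both project member IDs of every matched person, one row per
#' match. File 2 repeats the mapping and adds each ID's covered calendar
#' dates (semicolon-separated ISO dates).
#'
#' @param matches A [find_duplicates()] result.
#' @param cohort_a,cohort_b The cohorts the matches were computed from.
#' @param path_mapping,path_dates Output CSV paths.
#' @return Invisibly, the mapping data frame.
#' @export
write_mapping <- function(matches, cohort_a, cohort_b, path_mapping, path_dates) {
  dup <- matches[matches$is_duplicate, c("id_a", "id_b", "n_common", "distance"),
                 drop = FALSE]
  utils::write.csv(dup, path_mapping, row.names = FALSE)
  date_str <- function(cohort, id) {
    s <- cohort$series[[id]]
    paste(format(sort(unique(as.Date(round(s$time, "mins"))))), collapse = ";")
  }
  dates <- dup
  dates$dates_a <- vapply(dup$id_a, function(id) date_str(cohort_a, id), character(1))
  dates$dates_b <- vapply(dup$id_b, function(id) date_str(cohort_b, id), character(1))
  utils::write.csv(dates, path_dates, row.names = FALSE)
  invisible(dup)
}

#' Remove matched duplicates from the second cohort
#'
#' @param cohort_b The [cgm_cohort] to deduplicate.
#' @param matches A [find_duplicates()] result against a reference cohort.
#' @return `cohort_b` without the participants flagged as duplicates.
#' @export
drop_duplicates <- function(cohort_b, matches) {
  dup_ids <- matches$id_b[matches$is_duplicate]
  keep <- setdiff(names(cohort_b$series), dup_ids)
  out <- cgm_cohort(cohort_b$series[keep],
                    cohort_b$demographics[
                      cohort_b$demographics$participant_id %in% keep, ,
                      drop = FALSE])
  attr(out, "config") <- attr(cohort_b, "config")
  out
}
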