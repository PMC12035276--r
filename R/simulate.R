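#' Configuration for the synthetic CGM cohort generator
#'
#' Defines the statistical structure of a simulated cohort of CGM traces
#' from automated insulin delivery (AID) users. Defaults reproduce the
#' magnitudes reported for open-source AID cohorts: per-participant mean
#' glucose around 132 mg/dL with pooled SD around 43 mg/dL, a 24 h circadian
#' cycle with an early-morning trough, females running slightly higher and
#' more variable than males, 5-minute sampling, occasional sensor gaps, and
#' rare out-of-range artifacts above 400 mg/dL.
#'
#' @param n_participants Number of participants.
#' @param days_per_participant Days of data per participant (scalar, or a
#'   vector of length `n_participants`).
#' @param sample_interval Sampling interval in minutes (default 5).
#' @param base_mean Baseline mean glucose, mg/dL.
#' @param base_sd Stationary SD of the AR(1) noise component, mg/dL.
#' @param circadian_amplitude Amplitude of the 24 h sinusoid, mg/dL.
#' @param circadian_trough_hour Local hour of day (0-23) at which the
#'   sinusoid reaches its minimum.
#' @param gender_mean_shift Additive mean shift, mg/dL, applied to female
#'   participants.
#' @param gender_sd_scale Multiplicative scale on the noise SD for female
#'   participants.
#' @param ar_coefficient AR(1) autocorrelation of consecutive readings,
#'   in \[0, 1).
#' @param gap_rate Probability that any reading is missing (sensor gap).
#' @param artifact_rate Probability that a reading is replaced by an
#'   out-of-range artifact drawn uniformly from the integers 401..1200 mg/dL.
#' @param proportion_male Fraction of male participants; gender counts are
#'   exact (`round(n * proportion_male)` males).
#' @param start_date First calendar day of every trace (local time).
#' @param seed Master integer seed; identical config + seed gives
#'   bit-identical cohorts.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 75,
                       days_per_participant = 28,
                       sample_interval = 5,
                       base_mean = 132,
                       base_sd = 43,
                       circadian_amplitude = 15,
                       circadian_trough_hour = 5,
                       gender_mean_shift = 3.7,
                       gender_sd_scale = 1.15,
                       ar_coefficient = 0.98,
                       gap_rate = 0.05,
                       artifact_rate = 0.001,
                       proportion_male = 47 / 74,
                       start_date = "2021-01-01",
                       seed = 20231L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    days_per_participant = days_per_participant,
    sample_interval = sample_interval,
    base_mean = base_mean, base_sd = base_sd,
    circadian_amplitude = circadian_amplitude,
    circadian_trough_hour = circadian_trough_hour,
    gender_mean_shift = gender_mean_shift,
    gender_sd_scale = gender_sd_scale,
    ar_coefficient = ar_coefficient,
    gap_rate = gap_rate, artifact_rate = artifact_rate,
    proportion_male = proportion_male,
    start_date = as.character(start_date),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  ok <- function(test, msg) if (!isTRUE(test)) stop("invalid config: ", msg, call. = FALSE)
  ok(cfg$n_participants >= 0, "n_participants must be >= 0")
  ok(all(cfg$days_per_participant >= 0), "days_per_participant must be non-negative")
  ok(cfg$sample_interval > 0, "sample_interval must be positive")
  ok(cfg$base_mean > 0, "base_mean must be positive")
  ok(cfg$base_sd >= 0, "base_sd must be non-negative")
  ok(cfg$circadian_amplitude >= 0, "circadian_amplitude must be non-negative")
  ok(cfg$ar_coefficient >= 0 && cfg$ar_coefficient < 1, "ar_coefficient must be in [0, 1)")
  ok(cfg$gap_rate >= 0 && cfg$gap_rate < 1, "gap_rate must be in [0, 1)")
  ok(cfg$artifact_rate >= 0 && cfg$artifact_rate < 1, "artifact_rate must be in [0, 1)")
  ok(cfg$proportion_male >= 0 && cfg$proportion_male <= 1, "proportion_male must be in [0, 1]")
  invisible(cfg)
}

#' Simulate one participant's CGM trace
#'
#' Readings sit on a regular local-time grid of `sample_interval` minutes.
#' The value model is baseline + gender shift + a 24 h sinusoid with its
#' trough at `circadian_trough_hour` + stationary AR(1) Gaussian noise.
#' Values are floored at 40 mg/dL (a physiological sensor floor) before
#' artifact injection, artifacts are drawn from 401..1200 mg/dL at
#' `artifact_rate`, readings are rounded to integer mg/dL, and grid points
#' are then dropped independently at `gap_rate`.
#'
#' @param config A [sim_config].
#' @param participant_seed Integer seed for this participant's randomness.
#' @param gender `"male"` or `"female"`; females receive the configured mean
#'   shift and SD scale.
#' @param participant_id Identifier for the resulting series.
#' @param days Days of data; defaults to `config$days_per_participant`.
#' @return A [glucose_series].
#' @export
simulate_participant <- function(config, participant_seed,
                                 gender = c("male", "female"),
                                 participant_id = "sim",
                                 days = NULL) {
  validate_sim_config(config)
  gender <- match.arg(gender)
  if (is.null(days)) days <- config$days_per_participant[1]
  if (days < 0) stop("invalid config: negative days", call. = FALSE)
  per_day <- as.integer(round(1440 / config$sample_interval))
  n <- as.integer(days * per_day)
  t0 <- parse_local_time(paste(config$start_date, "00:00:00"))
  if (n == 0) return(glucose_series(participant_id, t0[0], numeric(0)))
  time <- t0 + (seq_len(n) - 1) * config$sample_interval * 60

  set.seed(as.integer(participant_seed))
  hour <- (as.numeric(time - t0, units = "hours")) %% 24
  circ <- -config$circadian_amplitude *
    cos(2 * pi * (hour - config$circadian_trough_hour) / 24)
  sdn <- config$base_sd * if (gender == "female") config$gender_sd_scale else 1
  phi <- config$ar_coefficient
  if (sdn > 0) {
    innov <- stats::rnorm(n, 0, sdn * sqrt(1 - phi^2))
    noise <- as.numeric(stats::filter(innov, phi, method = "recursive",
                                      init = stats::rnorm(1, 0, sdn)))
  } else {
    noise <- numeric(n)
  }
  shift <- if (gender == "female") config$gender_mean_shift else 0
  value <- config$base_mean + shift + circ + noise
  value <- pmax(value, 40)
  if (config$artifact_rate > 0) {
    art <- stats::runif(n) < config$artifact_rate
    value[art] <- sample(401:1200, sum(art), replace = TRUE)
  }
  value <- round(value)
  if (config$gap_rate > 0) {
    keep <- stats::runif(n) >= config$gap_rate
    time <- time[keep]
    value <- value[keep]
  }
  glucose_series(participant_id, time, value, quiet = TRUE)
}

#' Simulate a CGM cohort with demographics
#'
#' Draws `n_participants` independent traces with per-participant seeds
#' derived deterministically from `config$seed`, exact gender counts per
#' `proportion_male`, and a demographics table (age, gender, height, weight,
#' country, diabetes type, device experience, AID system) with marginals
#' modelled on published open-source AID cohorts.
#'
#' @param config A [sim_config].
#' @param id_prefix Prefix for generated participant IDs; IDs are random
#'   8-digit project-member-style numbers, unique within the cohort.
#' @return A [cgm_cohort] with the config attached as attribute `"config"`.
#' @export
simulate_cohort <- function(config, id_prefix = "") {
  validate_sim_config(config)
  n <- config$n_participants
  if (n < 0) stop("invalid config: n_participants must be >= 0", call. = FALSE)
  set.seed(config$seed)
  if (n == 0) {
    return(cgm_cohort(stats::setNames(list(), character(0)), empty_demographics()))
  }
  ids <- paste0(id_prefix, sample.int(90000000L, n) + 9999999L)
  pseeds <- sample.int(.Machine$integer.max - 1L, n)
  n_male <- round(n * config$proportion_male)
  gender <- sample(rep(c("male", "female"), c(n_male, n - n_male)))
  days <- rep(config$days_per_participant, length.out = n)
  demo <- data.frame(
    participant_id = ids,
    age = pmin(pmax(round(stats::rnorm(n, 41, 15)), 5), 78),
    gender = gender,
    height = round(stats::rnorm(n, 172, 10)),
    weight = round(stats::rnorm(n, 75, 15)),
    country = sample(c("Germany", "United States", "United Kingdom", "other"),
                     n, replace = TRUE, prob = c(33, 11, 6, 25)),
    diabetes_type = sample(c("type1", "type2"), n, replace = TRUE, prob = c(73, 1)),
    years_pump = round(stats::runif(n, 0, 38), 1),
    years_cgm = round(stats::runif(n, 0, 12), 1),
    years_loop = round(stats::runif(n, 0, 4), 1),
    aid_system = sample(c("AndroidAPS", "Loop", "OpenAPS"),
                        n, replace = TRUE, prob = c(55, 22, 4)),
    stringsAsFactors = FALSE
  )
  series <- vector("list", n)
  for (i in seq_len(n)) {
    series[[i]] <- simulate_participant(config, pseeds[i], gender[i],
                                        participant_id = ids[i], days = days[i])
  }
  names(series) <- ids
  out <- cgm_cohort(series, demo)
  attr(out, "config") <- config
  out
}

empty_demographics <- function() {
  data.frame(participant_id = character(0), age = numeric(0),
             gender = character(0), height = numeric(0), weight = numeric(0),
             country = character(0), diabetes_type = character(0),
             years_pump = numeric(0), years_cgm = numeric(0),
             years_loop = numeric(0), aid_system = character(0),
             stringsAsFactors = FALSE)
}

#' Plant cross-data-set duplicate participants
#'
#' Builds a second cohort in which `n_dup` participants are copies of
#' randomly chosen members of `cohort_a` under new random project member
#' IDs, optionally truncated (the first `date_shift` days dropped) and
#' thinned (each reading kept independently with probability
#' `subsample_rate`), plus `n_new` freshly simulated non-duplicates. The
#' returned truth mapping supports deduplication evaluation.
#'
#' @param cohort_a Donor [cgm_cohort].
#' @param n_dup Number of duplicates to plant (must not exceed the cohort
#'   size).
#' @param date_shift Days to truncate from the start of each copied record.
#' @param subsample_rate Probability each copied reading is retained, in
#'   (0, 1\].
#' @param seed Integer seed for donor choice, thinning and the fresh
#'   participants.
#' @param n_new Number of fresh non-duplicate participants (default: cohort
#'   size minus `n_dup`).
#' @param config [sim_config] for the fresh participants (default: the donor
#'   cohort's config).
#' @return A list with `cohort` (the new [cgm_cohort]) and `truth` (a data
#'   frame mapping `id_a` to `id_b` for every planted pair).
#' @export
plant_duplicates <- function(cohort_a, n_dup, date_shift = 0,
                             subsample_rate = 1, seed = 1L,
                             n_new = NULL, config = NULL) {
  stopifnot(inherits(cohort_a, "cgm_cohort"))
  if (n_dup > cohort_size(cohort_a)) {
    stop("n_dup exceeds the size of cohort_a", call. = FALSE)
  }
  if (subsample_rate <= 0 || subsample_rate > 1) {
    stop("subsample_rate must be in (0, 1]", call. = FALSE)
  }
  if (is.null(config)) config <- attr(cohort_a, "config")
  if (is.null(n_new)) n_new <- cohort_size(cohort_a) - n_dup
  set.seed(as.integer(seed))
  donors <- if (n_dup > 0) sample(names(cohort_a$series), n_dup) else character(0)
  new_ids <- as.character(sample.int(90000000L, n_dup + n_new) + 9999999L)
  series <- list()
  demo_rows <- list()
  truth <- data.frame(id_a = character(0), id_b = character(0),
                      stringsAsFactors = FALSE)
  for (i in seq_len(n_dup)) {
    don <- cohort_a$series[[donors[i]]]
    time <- don$time
    value <- don$value
    if (date_shift > 0) {
      cutoff <- min(as.Date(time)) + date_shift
      keep <- as.Date(time) >= cutoff
      time <- time[keep]; value <- value[keep]
    }
    if (subsample_rate < 1) {
      keep <- stats::runif(length(value)) < subsample_rate
      time <- time[keep]; value <- value[keep]
    }
    series[[new_ids[i]]] <- glucose_series(new_ids[i], time, value, quiet = TRUE)
    drow <- cohort_a$demographics[
      cohort_a$demographics$participant_id == donors[i], , drop = FALSE]
    drow$participant_id <- new_ids[i]
    demo_rows[[i]] <- drow
    truth <- rbind(truth, data.frame(id_a = donors[i], id_b = new_ids[i],
                                     stringsAsFactors = FALSE))
  }
  if (n_new > 0) {
    if (is.null(config)) {
      stop("config required to simulate fresh non-duplicates", call. = FALSE)
    }
    fresh_cfg <- config
    fresh_cfg$n_participants <- as.integer(n_new)
    fresh_cfg$seed <- (config$seed + as.integer(seed) * 7919L) %% .Machine$integer.max
    fresh <- simulate_cohort(fresh_cfg)
    # re-key fresh participants onto the pre-drawn IDs for this cohort
    fresh_ids <- new_ids[n_dup + seq_len(n_new)]
    for (j in seq_len(n_new)) {
      s <- fresh$series[[j]]
      s$participant_id <- fresh_ids[j]
      series[[fresh_ids[j]]] <- s
    }
    fd <- fresh$demographics
    fd$participant_id <- fresh_ids
    demo_rows[[length(demo_rows) + 1]] <- fd
  }
  demo <- if (length(demo_rows) > 0) do.call(rbind, demo_rows) else empty_demographics()
  rownames(demo) <- NULL
  out <- cgm_cohort(series, demo)
  attr(out, "config") <- config
  list(cohort = out, truth = truth)
}
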