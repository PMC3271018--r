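#' Generate a jittered event-related design
#'
#' Builds a single-condition event-related design in which each trial lasts
#' `stim_duration` seconds and consecutive trials are separated by a fixed
#' inter-trial interval plus a uniform jitter draw, mimicking rapid
#' event-related fMRI task designs.
#'
#' @param n_trials number of trials (>= 1)
#' @param stim_duration stimulus duration in seconds (> 0)
#' @param iti_fixed fixed part of the inter-trial gap, seconds (>= 0)
#' @param jitter_bounds length-2 numeric `(low, high)` in seconds; jitter is
#'   drawn uniformly on this interval (both 0 gives a fixed design)
#' @param TR sampling interval of the accompanying scan, seconds
#' @param seed integer seed; the design is a pure function of its arguments
#' @param start_time time of the first onset (baseline before the task),
#'   seconds
#' @param condition condition label applied to all trials
#' @return an `event_design`: list with `onsets`, `durations`, `conditions`,
#'   `run_length`, `TR`, `n_trials`
#' @export
#' @examples
#' d <- generate_event_design(52, 5, 1, c(0, 3.5), TR = 2, seed = 1)
#' d$n_trials
generate_event_design <- function(n_trials, stim_duration, iti_fixed = 1,
                                  jitter_bounds = c(0, 3.5), TR = 2,
                                  seed = 1, start_time = 10,
                                  condition = "task") {
  if (!is.numeric(n_trials) || length(n_trials) != 1 || n_trials < 1) {
    stopf("`n_trials` must be a single integer >= 1")
  }
  if (!is.numeric(stim_duration) || stim_duration <= 0) {
    stopf("`stim_duration` must be positive")
  }
  if (iti_fixed < 0) stopf("`iti_fixed` must be non-negative")
  if (length(jitter_bounds) != 2 || any(jitter_bounds < 0) ||
      jitter_bounds[1] > jitter_bounds[2]) {
    stopf("`jitter_bounds` must be (low, high) with 0 <= low <= high")
  }
  if (TR <= 0) stopf("`TR` must be positive")
  n_trials <- as.integer(n_trials)
  jit <- with_seed(seed, {
    if (diff(jitter_bounds) == 0) {
      rep(jitter_bounds[1], n_trials - 1L)
    } else if (n_trials > 1) {
      runif(n_trials - 1L, jitter_bounds[1], jitter_bounds[2])
    } else {
      numeric(0)
    }
  })
  gaps <- stim_duration + iti_fixed + jit
  onsets <- start_time + c(0, cumsum(gaps))
  run_length <- onsets[n_trials] + stim_duration + iti_fixed +
    mean(jitter_bounds) + start_time
  run_length <- ceiling(run_length / TR) * TR
  structure(list(onsets = onsets,
                 durations = rep(stim_duration, n_trials),
                 conditions = rep(condition, n_trials),
                 run_length = run_length, TR = TR,
                 n_trials = n_trials),
            class = "event_design")
}

#' @export
print.event_design <- function(x, ...) {
  cat(sprintf(
    "<event_design> %d trials, duration %g s, run length %g s (TR %g s)\n",
    x$n_trials, x$durations[1], x$run_length, x$TR))
  invisible(x)
}

#' Boxcar stimulus regressor on the TR grid
#'
#' Binary vector (one element per scan) that is 1 while any trial's stimulus
#' is on: the external-input / modulatory regressor for the state-space
#' model.
#'
#' @param design an `event_design`
#' @param n_timepoints number of samples; defaults to `run_length / TR`
#' @return numeric 0/1 vector of length `n_timepoints`
#' @export
design_boxcar <- function(design, n_timepoints = NULL) {
  stopifnot(inherits(design, "event_design"))
  if (is.null(n_timepoints)) {
    n_timepoints <- floor(design$run_length / design$TR)
  }
  tgrid <- (seq_len(n_timepoints) - 1) * design$TR
  on <- rep(0, n_timepoints)
  for (i in seq_len(design$n_trials)) {
    on[tgrid >= design$onsets[i] &
         tgrid < design$onsets[i] + design$durations[i]] <- 1
  }
  on
}

#' Impulse (onset) regressor on the TR grid
#'
#' One unit impulse at the scan nearest each trial onset; used for
#' event-related response fitting.
#'
#' @inheritParams design_boxcar
#' @return numeric vector of event counts per scan
#' @export
design_impulses <- function(design, n_timepoints = NULL) {
  stopifnot(inherits(design, "event_design"))
  if (is.null(n_timepoints)) {
    n_timepoints <- floor(design$run_length / design$TR)
  }
  imp <- rep(0, n_timepoints)
  idx <- pmin(pmax(round(design$onsets / design$TR) + 1, 1), n_timepoints)
  for (i in idx) imp[i] <- imp[i] + 1
  imp
}

#' Read / write BIDS-style event tables
#'
#' Tab-delimited with columns `onset`, `duration`, `trial_type` (seconds).
#'
#' @param design an `event_design`
#' @param path file path
#' @param TR,run_length used when reading (not stored in the table)
#' @return `read_events` returns an `event_design`
#' @export
write_events <- function(design, path) {
  stopifnot(inherits(design, "event_design"))
  df <- data.frame(onset = design$onsets, duration = design$durations,
                   trial_type = design$conditions)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path, TR = 2, run_length = NULL) {
  df <- read.delim(path)
  if (!all(c("onset", "duration", "trial_type") %in% names(df))) {
    stopf("events table must have columns onset, duration, trial_type")
  }
  if (is.null(run_length)) {
    run_length <- ceiling((max(df$onset + df$duration) + 12) / TR) * TR
  }
  structure(list(onsets = df$onset, durations = df$duration,
                 conditions = as.character(df$trial_type),
                 run_length = run_length, TR = TR,
                 n_trials = nrow(df)),
            class = "event_design")
}
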