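#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the forward model that simulates epoched sensor
#' recordings with planted, dimension-specific temporal response profiles.
#' The default is a desk-scale setup (2 participants, 4 sessions, 200
#' concepts, 32 sensors, 8 dimensions at 100 Hz) small enough to run the
#' whole analysis pipeline in minutes; [full_scale_config()] carries the
#' study-scale bookkeeping counts (4 participants, 12 sessions, 1,854
#' concepts, 66 dimensions) for structural checks that need no data.
#'
#' @param n_participants number of simulated participants.
#' @param n_sessions recording sessions per participant; each concept is
#'   shown once per session, so trials per session equals `n_concepts`.
#' @param n_concepts number of object concepts (trials per session).
#' @param n_sensors number of recording channels.
#' @param n_dims number of embedding dimensions.
#' @param sfreq sampling frequency of the epoch grid, in Hz.
#' @param epoch_window numeric length-2, epoch start and end in ms relative
#'   to stimulus onset; start must be negative (a baseline window is
#'   required) and end positive.
#' @param stim_duration_ms stimulus duration in ms (drives the latency of
#'   offset responses).
#' @param noise_sd standard deviation of additive Gaussian sensor noise, in
#'   signal units before baseline z-scoring.
#' @param shared_fraction_per_dim numeric vector (recycled to `n_dims`) in
#'   \[0, 1\]: the fraction of each dimension's sensor projection that is
#'   common to all participants. Defaults are high (0.9) for dimensions
#'   assigned an early profile and low (0.3) for late ones, emulating the
#'   empirical pattern that early stimulus-driven responses generalize
#'   across people while later responses are more idiosyncratic.
#' @param profile_assignments list of [temporal_profile()] specs, one per
#'   dimension (recycled). Default: first half early (peak 125 ms with an
#'   offset bump), second half late (peak 300 ms).
#' @param amplitude peak kernel amplitude used by the default profile
#'   assignments.
#' @param seed integer seed; all generator randomness derives from it.
#'
#' @return an object of class `generator_config` (a validated list).
#' @seealso [simulate_epochs()], [temporal_profile()], [trial_counts()]
#' @export
generator_config <- function(n_participants = 2L,
                             n_sessions = 4L,
                             n_concepts = 200L,
                             n_sensors = 32L,
                             n_dims = 8L,
                             sfreq = 100,
                             epoch_window = c(-100, 1300),
                             stim_duration_ms = 500,
                             noise_sd = 1,
                             shared_fraction_per_dim = NULL,
                             profile_assignments = NULL,
                             amplitude = 1,
                             seed = 1L) {
  counts <- c(n_participants = n_participants, n_sessions = n_sessions,
              n_concepts = n_concepts, n_sensors = n_sensors, n_dims = n_dims)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("all counts must be integers >= 1")
  if (length(epoch_window) != 2 || !(epoch_window[1] < 0 && 0 < epoch_window[2]))
    stop("epoch_window must satisfy start < 0 < end")
  if (sfreq <= 0) stop("sfreq must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")

  if (is.null(profile_assignments)) {
    n_early <- ceiling(n_dims / 2)
    profile_assignments <- c(
      replicate(n_early, temporal_profile("early", peak_ms = 125,
                                          width_ms = 30, amplitude = amplitude,
                                          offset_amplitude = amplitude / 2),
                simplify = FALSE),
      replicate(n_dims - n_early, temporal_profile("late", peak_ms = 300,
                                                   width_ms = 150,
                                                   amplitude = amplitude),
                simplify = FALSE)
    )
  }
  profile_assignments <- rep_len(profile_assignments, n_dims)
  stopifnot(all(vapply(profile_assignments, inherits, logical(1),
                       "temporal_profile")))

  if (is.null(shared_fraction_per_dim)) {
    kinds <- vapply(profile_assignments, `[[`, character(1), "kind")
    shared_fraction_per_dim <- ifelse(kinds == "early", 0.9, 0.3)
  }
  shared_fraction_per_dim <- rep_len(shared_fraction_per_dim, n_dims)
  if (any(shared_fraction_per_dim < 0 | shared_fraction_per_dim > 1))
    stop("shared_fraction_per_dim must lie in [0, 1]")

  structure(list(
    n_participants = as.integer(n_participants),
    n_sessions = as.integer(n_sessions),
    n_concepts = as.integer(n_concepts),
    n_sensors = as.integer(n_sensors),
    n_dims = as.integer(n_dims),
    sfreq = sfreq,
    epoch_window = as.numeric(epoch_window),
    stim_duration_ms = stim_duration_ms,
    noise_sd = noise_sd,
    shared_fraction_per_dim = shared_fraction_per_dim,
    profile_assignments = profile_assignments,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' Study-scale configuration for bookkeeping
#'
#' The full-scale counts of the emulated study: 4 participants, 12 sessions
#' of 1,854 unique-concept trials each, 66 embedding dimensions, 272
#' sensors. Intended for structural checks (fold sizes, trial totals) --
#' simulating data at this scale is not the package's use case.
#'
#' @param ... overrides passed to [generator_config()].
#' @return a `generator_config`.
#' @export
full_scale_config <- function(...) {
  generator_config(n_participants = 4L, n_sessions = 12L, n_concepts = 1854L,
                   n_sensors = 272L, n_dims = 66L, ...)
}

#' Trial bookkeeping implied by a configuration
#'
#' @param config a [generator_config()].
#' @return list with trials per session, experimental trials per participant,
#'   and session-wise cross-validation train/test sizes.
#' @export
trial_counts <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  per_session <- config$n_concepts
  total <- config$n_sessions * per_session
  list(trials_per_session = per_session,
       trials_per_participant = total,
       cv_train_trials = (config$n_sessions - 1L) * per_session,
       cv_test_trials = per_session)
}

#' Epoch time axis of a configuration
#'
#' @param config a [generator_config()].
#' @return numeric vector of timepoint positions in ms, strictly increasing,
#'   spanning the epoch window at the configured sampling rate.
#' @export
config_times <- function(config) {
  step <- 1000 / config$sfreq
  seq(config$epoch_window[1], config$epoch_window[2], by = step)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic-data generator configuration\n")
  cat(sprintf("  %d participant(s), %d sessions x %d concepts (%d trials each)\n",
              x$n_participants, x$n_sessions, x$n_concepts,
              x$n_sessions * x$n_concepts))
  cat(sprintf("  %d sensors, %d dimensions, %g Hz, epoch %g..%g ms\n",
              x$n_sensors, x$n_dims, x$sfreq, x$epoch_window[1],
              x$epoch_window[2]))
  kinds <- vapply(x$profile_assignments, `[[`, character(1), "kind")
  cat(sprintf("  profiles: %s\n",
              paste(sprintf("%s x%d", names(table(kinds)), table(kinds)),
                    collapse = ", ")))
  cat(sprintf("  noise_sd %g, seed %d\n", x$noise_sd, x$seed))
  invisible(x)
}
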