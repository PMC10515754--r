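#' Temporal response profile specification
#'
#' Describes the deterministic temporal kernel with which one embedding
#' dimension modulates the simulated sensor signal. Three canonical shapes
#' are supported, mirroring the response types seen in time-resolved
#' recordings of object vision: a transient early bump (~125 ms), a slow
#' rise to a late sustained peak (~300 ms), and a stimulus-offset response
#' (~100 ms after stimulus disappearance). `mixture` combines an early bump
#' with a late component.
#'
#' @param kind one of `"early"`, `"late"`, `"offset"`, `"mixture"`.
#' @param peak_ms kernel peak latency in ms after stimulus onset (for
#'   `"offset"` the peak is tied to stimulus duration instead).
#' @param width_ms shape parameter in ms: the Gaussian SD of transient
#'   bumps, or the rise span of the late ramp.
#' @param amplitude peak kernel value (unitless signal gain).
#' @param offset_amplitude amplitude of an additional offset bump appended
#'   to any kind; 0 disables it.
#'
#' @return object of class `temporal_profile`.
#' @export
temporal_profile <- function(kind = c("early", "late", "offset", "mixture"),
                             peak_ms = 125, width_ms = 30, amplitude = 1,
                             offset_amplitude = 0) {
  kind <- match.arg(kind)
  stopifnot(width_ms > 0, is.finite(amplitude), offset_amplitude >= 0)
  structure(list(kind = kind, peak_ms = peak_ms, width_ms = width_ms,
                 amplitude = amplitude, offset_amplitude = offset_amplitude),
            class = "temporal_profile")
}

#' @export
print.temporal_profile <- function(x, ...) {
  cat(sprintf("temporal_profile: %s, peak %g ms, width %g ms, amplitude %g",
              x$kind, x$peak_ms, x$width_ms, x$amplitude))
  if (x$offset_amplitude > 0)
    cat(sprintf(" (+offset bump, amplitude %g)", x$offset_amplitude))
  cat("\n")
  invisible(x)
}

# Gaussian bump, hard-zeroed before stimulus onset.
.bump <- function(times_ms, peak_ms, width_ms, amplitude) {
  k <- amplitude * exp(-(times_ms - peak_ms)^2 / (2 * width_ms^2))
  k[times_ms < 0] <- 0
  k
}

# Smoothstep rise from `from_ms` to `peak_ms`, then slow exponential decay:
# a sustained response whose argmax sits exactly at the grid point nearest
# peak_ms (a perfectly flat plateau would leave the planted latency
# unidentifiable downstream).
.late_ramp <- function(times_ms, peak_ms, width_ms, amplitude,
                       decay_tau_ms = 150) {
  from_ms <- max(0, peak_ms - width_ms)
  u <- pmin(1, pmax(0, (times_ms - from_ms) / (peak_ms - from_ms)))
  k <- amplitude * u^2 * (3 - 2 * u)
  after <- times_ms > peak_ms
  k[after] <- amplitude * exp(-(times_ms[after] - peak_ms) / decay_tau_ms)
  k[times_ms < 0] <- 0
  k
}

#' Evaluate a temporal profile on the epoch grid
#'
#' Turns a [temporal_profile()] spec into a kernel vector over the epoch
#' timepoints. Kernels are causal: exactly zero at every timepoint before
#' stimulus onset.
#'
#' @param profile a [temporal_profile()].
#' @param times_ms epoch time axis in ms (strictly increasing, spanning 0).
#' @param stim_duration_ms stimulus duration in ms; offset bumps peak at
#'   `stim_duration_ms + 100`.
#' @return numeric kernel vector, one value per timepoint.
#' @examples
#' t_ms <- seq(-100, 1300, by = 10)
#' k <- make_profile(temporal_profile("early", peak_ms = 125), t_ms)
#' t_ms[which.max(k)]  # 120 or 130: the grid point nearest 125 ms
#' @export
make_profile <- function(profile, times_ms, stim_duration_ms = 500) {
  stopifnot(inherits(profile, "temporal_profile"),
            is.numeric(times_ms), !is.unsorted(times_ms, strictly = TRUE))
  if (profile$kind != "offset" &&
      (profile$peak_ms <= 0 || profile$peak_ms >= max(times_ms)))
    stop("profile peak_ms lies outside the epoch window",
         " (must fall between stimulus onset and the epoch end)")
  offset_peak <- stim_duration_ms + 100
  k <- switch(profile$kind,
    early = .bump(times_ms, profile$peak_ms, profile$width_ms,
                  profile$amplitude),
    late = .late_ramp(times_ms, profile$peak_ms, profile$width_ms,
                      profile$amplitude),
    offset = .bump(times_ms, offset_peak, profile$width_ms,
                   profile$amplitude),
    mixture = .bump(times_ms, profile$peak_ms, profile$width_ms,
                    profile$amplitude) +
      .late_ramp(times_ms, max(300, profile$peak_ms + 150), 150,
                 0.8 * profile$amplitude)
  )
  if (profile$offset_amplitude > 0 && profile$kind != "offset")
    k <- k + .bump(times_ms, offset_peak, 30, profile$offset_amplitude)
  stopifnot(all(is.finite(k)))
  k
}
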