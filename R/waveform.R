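#' Ideal mIPSC waveform on a uniform time grid
#'
#' Evaluates the canonical synthetic event shape: a saturating-exponential
#' rise `1 - exp(-t/tau_rise)` normalized to reach the full amplitude at the
#' peak, joined at the peak to an exact biexponential decay
#' `p_fast * exp(-t'/tau_fast) + (1 - p_fast) * exp(-t'/tau_slow)` (with `t'`
#' measured from the peak). The peak time (`5 * tau_rise`, snapped to the
#' sample grid) therefore carries exactly the requested amplitude, and every
#' post-peak sample lies exactly on the biexponential.
#'
#' @param kinetics an [event_kinetics()] object; `amplitude_mean` is used as
#'   the peak amplitude.
#' @param dt sample interval in ms; must be positive.
#' @param duration waveform length in ms; must be at least `10 * tau_slow` so
#'   the decay is essentially complete within the window.
#' @return Numeric vector of current samples (pA) at times
#'   `seq(0, duration, by = dt)`; starts at 0, reaches a single negative
#'   extremum equal to the requested amplitude, then decays.
#' @examples
#' k <- event_kinetics(amplitude_mean = -50, tau_fast = 20, tau_slow = 20,
#'                     p_fast = 1)
#' w <- event_waveform(k, dt = 0.1, duration = 200)
#' min(w)  # -50
#' @export
event_waveform <- function(kinetics, dt, duration) {
  stopifnot(inherits(kinetics, "event_kinetics"))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a positive time step (ms)")
  if (!is.numeric(duration) || length(duration) != 1L || !is.finite(duration) ||
      duration < 10 * kinetics$tau_slow)
    stop("duration must be at least 10 * tau_slow (ms)")
  t <- seq(0, duration, by = dt)
  # snap the peak onto the grid so the sampled extremum equals the amplitude
  t_peak <- dt * ceiling(5 * kinetics$tau_rise / dt)
  waveform_at(kinetics, t, t_peak = t_peak)
}

# evaluate the canonical waveform at arbitrary times (ms from onset);
# t_peak defaults to the unsnapped 5 * tau_rise (used for event injection,
# where sub-sample peak placement is realistic)
waveform_at <- function(kinetics, t, t_peak = 5 * kinetics$tau_rise,
                        amplitude = kinetics$amplitude_mean) {
  y <- numeric(length(t))
  pos <- t >= 0
  tr <- kinetics$tau_rise
  rise <- pos & t <= t_peak
  y[rise] <- (1 - exp(-t[rise] / tr)) / (1 - exp(-t_peak / tr))
  dec <- pos & t > t_peak
  td <- t[dec] - t_peak
  y[dec] <- kinetics$p_fast * exp(-td / kinetics$tau_fast) +
    (1 - kinetics$p_fast) * exp(-td / kinetics$tau_slow)
  amplitude * y
}
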