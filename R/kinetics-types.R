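#' Kinetic parameters of a synthetic mIPSC
#'
#' Bundles the waveform parameters of a miniature inhibitory postsynaptic
#' current: a saturating-exponential rise characterised by `tau_rise` and a
#' biexponential decay `A_fast * exp(-t/tau_fast) + A_slow * exp(-t/tau_slow)`,
#' where `p_fast = A_fast / (A_fast + A_slow)` is the amplitude fraction of the
#' fast component. The implied weighted decay time constant is
#' `tau_w = p_fast * tau_fast + (1 - p_fast) * tau_slow`.
#'
#' @param amplitude_mean mean peak amplitude in pA; negative for inward
#'   currents.
#' @param amplitude_cv coefficient of variation of the (log-normal) peak
#'   amplitude distribution; dimensionless.
#' @param tau_rise rise time constant in ms. The 10-90% rise time of the
#'   resulting waveform is about `2.2 * tau_rise`.
#' @param tau_fast fast decay time constant in ms; must be `< tau_slow` unless
#'   the two coincide.
#' @param tau_slow slow decay time constant in ms.
#' @param p_fast amplitude fraction of the fast component, in `[0, 1]`.
#' @return An object of class `event_kinetics`.
#' @examples
#' k <- event_kinetics(amplitude_mean = -40, tau_fast = 10, tau_slow = 30,
#'                     p_fast = 0.5)
#' tau_w_of(k)  # 20 ms
#' @export
event_kinetics <- function(amplitude_mean = -40, amplitude_cv = 0.4,
                           tau_rise = 0.3, tau_fast = 8, tau_slow = 35,
                           p_fast = 0.55) {
  stopifnot(is.numeric(amplitude_mean), length(amplitude_mean) == 1L)
  if (!is.finite(amplitude_mean) || amplitude_mean >= 0)
    stop("amplitude_mean must be negative (inward current, pA)")
  if (!is.finite(amplitude_cv) || amplitude_cv < 0)
    stop("amplitude_cv must be non-negative")
  if (!is.finite(tau_rise) || tau_rise <= 0)
    stop("tau_rise must be positive (ms)")
  if (!is.finite(tau_fast) || tau_fast <= 0 || !is.finite(tau_slow) || tau_slow <= 0)
    stop("decay time constants must be positive (ms)")
  if (tau_fast > tau_slow)
    stop("tau_fast must not exceed tau_slow")
  if (!is.finite(p_fast) || p_fast < 0 || p_fast > 1)
    stop("p_fast must lie in [0, 1]")
  structure(
    list(amplitude_mean = amplitude_mean, amplitude_cv = amplitude_cv,
         tau_rise = tau_rise, tau_fast = tau_fast, tau_slow = tau_slow,
         p_fast = p_fast),
    class = "event_kinetics"
  )
}

#' Weighted decay time constant implied by a kinetics object
#'
#' @param kinetics an [event_kinetics()] object.
#' @return `tau_w = p_fast * tau_fast + (1 - p_fast) * tau_slow`, in ms.
#' @export
tau_w_of <- function(kinetics) {
  stopifnot(inherits(kinetics, "event_kinetics"))
  kinetics$p_fast * kinetics$tau_fast + (1 - kinetics$p_fast) * kinetics$tau_slow
}

#' @export
print.event_kinetics <- function(x, ...) {
  cat(sprintf(
    "mIPSC kinetics: amp %.1f pA (CV %.2f), tau_rise %.2f ms, decay %.1f/%.1f ms (p_fast %.2f), tau_w %.2f ms\n",
    x$amplitude_mean, x$amplitude_cv, x$tau_rise, x$tau_fast, x$tau_slow,
    x$p_fast, tau_w_of(x)))
  invisible(x)
}

# Build a kinetics object from a target tau_w using the canonical
# decomposition p_fast = 0.55, tau_fast = 0.4 * tau_w (so tau_slow follows
# from tau_w = p_fast*tau_fast + (1-p_fast)*tau_slow, exactly).
kinetics_from_tau_w <- function(tau_w, amplitude_mean = -40, amplitude_cv = 0.4,
                                tau_rise = 0.3, p_fast = 0.55,
                                tau_fast_frac = 0.4) {
  tau_fast <- tau_fast_frac * tau_w
  tau_slow <- (tau_w - p_fast * tau_fast) / (1 - p_fast)
  event_kinetics(amplitude_mean = amplitude_mean, amplitude_cv = amplitude_cv,
                 tau_rise = tau_rise, tau_fast = tau_fast, tau_slow = tau_slow,
                 p_fast = p_fast)
}
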