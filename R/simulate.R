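#' Configuration for a synthetic voltage-clamp sweep
#'
#' @param kinetics [event_kinetics()] for the injected events.
#' @param event_rate mean event frequency, events per second (Poisson
#'   arrivals).
#' @param sweep_duration sweep length in seconds.
#' @param sampling_rate sampling frequency in Hz; must be at least four times
#'   `filter_cutoff`.
#' @param noise_sd SD of the additive white Gaussian baseline noise in pA,
#'   before low-pass filtering.
#' @param filter_cutoff low-pass corner frequency in Hz applied to the whole
#'   trace (signal plus noise); 2 kHz matches standard acquisition filtering.
#' @param holding_potential holding potential in mV (metadata only).
#' @param temperature bath temperature in degrees C (metadata only).
#' @param rs_start,rs_end series-resistance readings (MOhm) recorded at the
#'   start and end of the sweep, carried as QC metadata.
#' @param seed integer seed making the sweep reproducible.
#' @return A `sim_config` object (validated list).
#' @export
sim_config <- function(kinetics = event_kinetics(), event_rate = 1.2,
                       sweep_duration = 30, sampling_rate = 10000,
                       noise_sd = 1.5, filter_cutoff = 2000,
                       holding_potential = -60, temperature = 35,
                       rs_start = 8, rs_end = 8.6, seed = 1) {
  stopifnot(inherits(kinetics, "event_kinetics"))
  if (!is.finite(event_rate) || event_rate < 0) stop("event_rate must be >= 0")
  if (!is.finite(sweep_duration) || sweep_duration <= 0)
    stop("sweep_duration must be positive (s)")
  if (!is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be positive (Hz)")
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.finite(filter_cutoff) || filter_cutoff <= 0)
    stop("filter_cutoff must be positive (Hz)")
  if (sampling_rate < 4 * filter_cutoff)
    stop("sampling_rate must be at least 4 x filter_cutoff")
  if (rs_start <= 0 || rs_end <= 0) stop("series-resistance readings must be positive")
  structure(
    list(kinetics = kinetics, event_rate = event_rate,
         sweep_duration = sweep_duration, sampling_rate = sampling_rate,
         noise_sd = noise_sd, filter_cutoff = filter_cutoff,
         holding_potential = holding_potential, temperature = temperature,
         rs_start = rs_start, rs_end = rs_end, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# 4-pole Butterworth low-pass, applied forward-backward (zero phase) so event
# onsets and rise times are not delayed by the filter
lowpass_trace <- function(x, sampling_rate, cutoff) {
  if (cutoff >= sampling_rate / 2) return(x)
  bf <- signal::butter(4, 2 * cutoff / sampling_rate, type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

#' Simulate one voltage-clamp sweep with known ground truth
#'
#' Event onsets follow a homogeneous Poisson process at `event_rate`; peak
#' amplitudes are drawn log-normally with the configured mean and CV
#' (sign-flipped to negative); each event contributes the canonical waveform
#' ([event_waveform()] shape) at its (sub-sample) onset. White Gaussian noise
#' is added and the whole trace is low-pass filtered at `filter_cutoff`.
#'
#' @param config a [sim_config()] object.
#' @param min_events if positive, the sweep is extended in whole-duration
#'   chunks until at least this many events have been injected (the Poisson
#'   law is preserved within each chunk); 0 disables.
#' @return A list of class `sweep_sim` with elements `trace` (a
#'   [sweep_trace()]) and `truth` (tibble: `onset_s`, `amplitude_pa`,
#'   `tau_rise_ms`, `tau_fast_ms`, `tau_slow_ms`, `p_fast`, `overlapped` --
#'   `TRUE` where the onset falls within 10 ms of the previous onset).
#' @export
simulate_sweep <- function(config, min_events = 0) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    fs <- config$sampling_rate
    kin <- config$kinetics
    dur <- config$sweep_duration
    onsets <- .draw_onsets(config$event_rate, dur)
    chunk <- max(5, 0.1 * config$sweep_duration)
    while (length(onsets) < min_events) {
      extra <- .draw_onsets(config$event_rate, chunk)
      onsets <- c(onsets, dur + extra)
      dur <- dur + chunk
    }
    n <- round(dur * fs)
    amps <- .draw_amplitudes(length(onsets), kin$amplitude_mean, kin$amplitude_cv)
    x <- numeric(n)
    support_ms <- max(10 * kin$tau_slow, 50)
    len <- ceiling(support_ms / 1000 * fs)
    for (i in seq_along(onsets)) {
      k0 <- floor(onsets[i] * fs) + 1L
      if (k0 > n) next
      kk <- k0:min(n, k0 + len)
      t_ms <- ((kk - 1) / fs - onsets[i]) * 1000
      x[kk] <- x[kk] + waveform_at(kin, t_ms, amplitude = amps[i])
    }
    if (config$noise_sd > 0) x <- x + stats::rnorm(n, 0, config$noise_sd)
    x <- lowpass_trace(x, fs, config$filter_cutoff)
    truth <- tibble::tibble(
      onset_s = onsets,
      amplitude_pa = amps,
      tau_rise_ms = kin$tau_rise,
      tau_fast_ms = kin$tau_fast,
      tau_slow_ms = kin$tau_slow,
      p_fast = kin$p_fast,
      overlapped = c(FALSE, diff(onsets) < 0.010)
    )
    trace <- sweep_trace(samples = x, sampling_rate = fs,
                         holding_potential = config$holding_potential,
                         temperature = config$temperature,
                         rs_start = config$rs_start, rs_end = config$rs_end,
                         label = sprintf("sim_seed%d", config$seed))
    structure(list(trace = trace, truth = truth, config = config),
              class = "sweep_sim")
  })
}

.draw_onsets <- function(rate, duration) {
  n_ev <- stats::rpois(1L, rate * duration)
  sort(stats::runif(n_ev, 0, duration))
}

# log-normal magnitudes with the requested mean and CV, sign-flipped inward
.draw_amplitudes <- function(n, amplitude_mean, cv) {
  if (n == 0L) return(numeric(0))
  m <- abs(amplitude_mean)
  if (cv <= 0) return(rep(-m, n))
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(m) - sdlog^2 / 2
  -stats::rlnorm(n, meanlog, sdlog)
}

#' Simulate a full cohort from a named preset
#'
#' Generates `n_cells` independent cells. Per-cell ground-truth `tau_w` is
#' jittered around the preset mean with the preset's across-cell SD; the
#' jitter is carried by `tau_slow` alone (with `tau_fast` and `p_fast` fixed)
#' so that the across-cell SD of true `tau_w` matches the printed group SD by
#' construction. Each cell contains at least `events_per_cell` injected
#' events.
#'
#' @param preset a [preset()] object or preset name.
#' @param seed integer seed; per-cell seeds are derived deterministically.
#' @param n_cells optionally override the preset's cell count.
#' @param ... passed to [sim_config()] (e.g. `noise_sd`, `event_rate`).
#' @return A list of class `cohort_sim`: `cells` (list of `sweep_sim`),
#'   `true_tau_w` (numeric per cell), `preset`.
#' @export
simulate_cohort <- function(preset, seed = 1, n_cells = NULL, ...) {
  if (is.character(preset)) preset <- preset(preset)
  stopifnot(inherits(preset, "cohort_preset"))
  if (is.null(n_cells)) n_cells <- preset$n_cells
  cells <- vector("list", n_cells)
  true_tau_w <- numeric(n_cells)
  for (i in seq_len(n_cells)) {
    sim <- simulate_cell(preset, cell_index = i, seed = seed, ...)
    cells[[i]] <- sim
    true_tau_w[i] <- tau_w_of(sim$config$kinetics)
  }
  structure(list(cells = cells, true_tau_w = true_tau_w, preset = preset),
            class = "cohort_sim")
}

#' Simulate a single cell of a preset cohort
#'
#' @inheritParams simulate_cohort
#' @param cell_index 1-based cell index within the cohort; determines the
#'   per-cell seed and tau_w jitter.
#' @return A `sweep_sim` (see [simulate_sweep()]).
#' @export
simulate_cell <- function(preset, cell_index, seed = 1, ...) {
  if (is.character(preset)) preset <- preset(preset)
  stopifnot(inherits(preset, "cohort_preset"))
  # fold the preset name into the per-cell seed so that different cohorts
  # simulated from one master seed draw independent jitter
  name_hash <- sum(utf8ToInt(preset$name) * seq_along(utf8ToInt(preset$name)))
  cell_seed <- derive_seed(seed + name_hash, cell_index)
  kin <- with_seed(cell_seed, .jitter_kinetics(preset$kinetics, preset$tau_w_sd))
  args <- list(...)
  args$kinetics <- kin
  args$seed <- derive_seed(cell_seed, 1)
  if (is.null(args$event_rate)) args$event_rate <- 1.2
  if (is.null(args$sweep_duration))
    args$sweep_duration <- ceiling(preset$events_per_cell / args$event_rate)
  cfg <- do.call(sim_config, args)
  simulate_sweep(cfg, min_events = preset$events_per_cell)
}

# shift tau_slow so that tau_w moves by a N(0, sd) draw; resample while the
# ordering tau_rise-free invariants would break (tau_slow must stay above
# tau_fast)
.jitter_kinetics <- function(kin, sd) {
  if (sd <= 0) return(kin)
  for (trial in 1:100) {
    delta <- stats::rnorm(1, 0, sd)
    tau_slow <- kin$tau_slow + delta / (1 - kin$p_fast)
    if (tau_slow > kin$tau_fast) {
      kin$tau_slow <- tau_slow
      return(event_kinetics(kin$amplitude_mean, kin$amplitude_cv, kin$tau_rise,
                            kin$tau_fast, tau_slow, kin$p_fast))
    }
  }
  stop("could not jitter kinetics while keeping tau_slow > tau_fast")
}
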