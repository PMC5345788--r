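#' Construct a sweep trace
#'
#' A uniformly sampled membrane-current recording with its acquisition
#' metadata and the series-resistance readings used for recording-level QC.
#'
#' @param samples numeric vector of current samples in pA.
#' @param sampling_rate sampling frequency in Hz.
#' @param holding_potential holding potential in mV.
#' @param temperature bath temperature in degrees C.
#' @param rs_start,rs_end series-resistance readings in MOhm.
#' @param label free-text identifier.
#' @return An object of class `sweep_trace`.
#' @export
sweep_trace <- function(samples, sampling_rate, holding_potential = -60,
                        temperature = 35, rs_start = 8, rs_end = 8,
                        label = "") {
  if (!is.numeric(samples) || !all(is.finite(samples)))
    stop("samples must be finite numeric")
  if (!is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be positive (Hz)")
  structure(
    list(samples = as.numeric(samples), sampling_rate = sampling_rate,
         holding_potential = holding_potential, temperature = temperature,
         rs_start = rs_start, rs_end = rs_end, label = as.character(label)),
    class = "sweep_trace"
  )
}

#' @export
print.sweep_trace <- function(x, ...) {
  cat(sprintf("sweep trace '%s': %.1f s at %g kHz, Vh %g mV, %g C, Rs %.1f->%.1f MOhm\n",
              x$label, length(x$samples) / x$sampling_rate,
              x$sampling_rate / 1000, x$holding_potential, x$temperature,
              x$rs_start, x$rs_end))
  invisible(x)
}

#' Recording-level series-resistance QC
#'
#' A recording is invalid when the series resistance changed by more than 20%
#' between the start and end readings, or when either reading exceeded
#' 15 MOhm. Both bounds are strict: a change of exactly 20% or a reading of
#' exactly 15 MOhm still passes.
#'
#' @param rs_start,rs_end series-resistance readings in MOhm; must be
#'   positive.
#' @return A list with `rs_start`, `rs_end`, `change` (fractional, relative to
#'   the start reading) and `valid`.
#' @examples
#' qc_recording(10, 16)$valid    # FALSE: exceeds 15 MOhm
#' qc_recording(10, 12.5)$valid  # FALSE: 25% change
#' qc_recording(10, 12)$valid    # TRUE: exactly 20% is not "more than 20%"
#' @export
qc_recording <- function(rs_start, rs_end) {
  if (!is.finite(rs_start) || !is.finite(rs_end) || rs_start <= 0 || rs_end <= 0)
    stop("series-resistance readings must be positive (MOhm)")
  change <- abs(rs_end - rs_start) / rs_start
  valid <- !(change > 0.20 || max(rs_start, rs_end) > 15)
  list(rs_start = rs_start, rs_end = rs_end, change = change, valid = valid)
}

#' Slowly varying baseline of a sweep
#'
#' Running-median baseline: robust to the (one-signed) synaptic events riding
#' on it, so on event-containing traces the estimate tracks drift while lying
#' above the event troughs.
#'
#' @param trace a [sweep_trace()].
#' @param window_s median window length in seconds (default 0.4; several times
#'   the longest event extent).
#' @return Numeric baseline, same length as the trace.
#' @export
estimate_baseline <- function(trace, window_s = 0.4) {
  stopifnot(inherits(trace, "sweep_trace"))
  n <- length(trace$samples)
  if (n / trace$sampling_rate < 1) stop("trace must be at least 1 s long")
  k <- odd_window(min(window_s * trace$sampling_rate, n - 1))
  as.numeric(stats::runmed(trace$samples, k, endrule = "median"))
}

#' Detect candidate mIPSCs in a sweep
#'
#' Baseline-subtracted threshold-crossing detector. A candidate starts where
#' the baseline-subtracted current crosses `threshold`; its onset is located
#' by walking back to the last point inside the baseline noise band, the peak
#' is the minimum of the below-threshold excursion, and a post-peak lockout of
#' `min_duration` merges re-crossings. Each candidate is then measured
#' ([event_metrics()]) and classified:
#' \itemize{
#'   \item rejected `amplitude` unless the peak is at least as negative as
#'     `threshold`;
#'   \item rejected `duration` unless the excursion outlasts `min_duration`
#'     (onset to return within one noise SD of baseline);
#'   \item rejected `rise_time` when the 10-90% rise exceeds `max_rise`
#'     (distally generated events);
#'   \item rejected `artifact` when the waveform correlation with the
#'     canonical event template falls below `template_r` (stands in for
#'     manual visual inspection);
#'   \item flagged `overlap` (but still measured) when a neighbouring onset
#'     falls within the measurement window, so contaminated decays are kept
#'     out of mean-event construction.
#' }
#'
#' @param trace a [sweep_trace()].
#' @param threshold amplitude threshold in pA (negative; default -5).
#' @param min_duration minimum event duration in ms (default 2).
#' @param max_rise maximum 10-90% rise time in ms (default 1).
#' @param window_ms measurement window per event, ms from onset (default 150).
#' @param pre_ms pre-onset context used for rise measurement, ms (default 10).
#' @param pre_exclude_ms events whose onset falls within this long after a
#'   preceding onset are flagged `overlap` (default 300 ms): the preceding
#'   decay must have died away before an event may enter the mean event.
#' @param template_r minimum correlation with the canonical waveform template
#'   (default 0.5); `NA` disables the artifact screen.
#' @param template_kinetics [event_kinetics()] used to build the artifact
#'   template (defaults to the canonical shape).
#' @param baseline optional precomputed baseline (from
#'   [estimate_baseline()]).
#' @return A tibble with one row per candidate: `onset_index`, `peak_index`,
#'   `onset_ms`, `peak_amplitude` (pA, baseline-subtracted), `rise_10_90`
#'   (ms), `duration` (ms), `charge` (pA ms), `t70` (ms; `NA` when the decay
#'   is truncated), `t70_truncated`, `template_corr`, `overlap`, `accepted`,
#'   `reject_reason`. Indices are 1-based sample indices; times are ms from
#'   sweep start.
#' @export
detect_events <- function(trace, threshold = -5, min_duration = 2,
                          max_rise = 1, window_ms = 150, pre_ms = 10,
                          pre_exclude_ms = 300, template_r = 0.5,
                          template_kinetics = NULL, baseline = NULL) {
  stopifnot(inherits(trace, "sweep_trace"))
  if (threshold >= 0) stop("threshold must be negative (pA)")
  fs <- trace$sampling_rate
  dt_ms <- 1000 / fs
  n <- length(trace$samples)
  if (n * dt_ms < window_ms + pre_ms) {
    warning("trace shorter than one event window; no detection attempted")
    return(.empty_events())
  }
  if (is.null(baseline)) baseline <- estimate_baseline(trace)
  d <- trace$samples - baseline
  noise_sd <- stats::mad(d)
  band <- -noise_sd  # return-to-baseline level (1 noise SD)

  # candidate trigger: below threshold AND arrived there on a steep
  # downstroke (a drop of at least 60% of |threshold| over the preceding
  # 0.5 ms). The downstroke condition both suppresses noise re-crossings on
  # slowly decaying tails and exposes events riding on the decay of an
  # earlier event, which never re-cross the absolute threshold on their own.
  below <- d < threshold
  k_slope <- max(1L, round(0.5 / dt_ms))
  # downstroke measured on a lightly smoothed copy (0.3 ms boxcar) so that
  # sample-to-sample noise cannot fake a steep drop inside a deep event
  k_sm <- max(1L, round(0.3 / dt_ms))
  ds <- if (k_sm > 1L) as.numeric(stats::filter(d, rep(1 / k_sm, k_sm),
                                                sides = 2L)) else d
  ds[is.na(ds)] <- d[is.na(ds)]
  dd <- c(rep(0, k_slope), ds[(k_slope + 1L):n] - ds[seq_len(n - k_slope)])
  drop_req <- -max(0.6 * abs(threshold), 4 * stats::mad(dd))
  trig <- below & (dd < drop_req)
  starts <- which(trig & !c(FALSE, trig[-n]))
  if (length(starts) == 0L) return(.empty_events())

  # merge triggers closer than the post-peak lockout
  lockout <- max(1L, round(min_duration / dt_ms))
  if (length(starts) > 1L) {
    keep <- rep(TRUE, length(starts))
    last <- starts[1L]
    for (i in 2L:length(starts)) {
      if (starts[i] <= last + lockout) keep[i] <- FALSE else last <- starts[i]
    }
    starts <- starts[keep]
  }

  m <- length(starts)
  onset <- integer(m); peak <- integer(m)
  max_back <- round(pre_ms / dt_ms)
  nxt <- c(starts[-1L] - 1L, n)
  for (i in seq_len(m)) {
    # peak: minimum between this trigger and the earlier of the return above
    # threshold or the next trigger
    run_end <- nxt[i]
    above <- which(!below[starts[i]:run_end])
    if (length(above)) run_end <- starts[i] + above[1L] - 2L
    seg <- d[starts[i]:max(run_end, starts[i])]
    peak[i] <- starts[i] + which.min(seg) - 1L
    # onset: walk back to the last sample inside the baseline noise band, or
    # to the local maximum when the event rides on a decaying tail; never
    # walk back past the previous trigger, or a rider would collapse onto
    # its host's onset and be lost to deduplication
    lo <- max(1L, starts[i] - max_back,
              if (i > 1L) starts[i - 1L] + 1L else 1L)
    pre <- d[lo:starts[i]]
    in_band <- which(pre >= band)
    onset[i] <- if (length(in_band)) lo + in_band[length(in_band)] - 1L
                else lo + which.max(pre) - 1L
  }
  # drop duplicate onsets from merged re-crossings
  dup <- duplicated(onset)
  onset <- onset[!dup]; peak <- peak[!dup]; m <- length(onset)

  win_len <- round(window_ms / dt_ms)
  next_onset <- c(onset[-1L], n + 1L)
  prev_onset <- c(-Inf, onset[-m])
  template <- .event_template(template_kinetics, dt_ms, window_ms)

  amp <- rise <- dur_ms <- charge <- t70 <- tcorr <- rep(NA_real_, m)
  t70_trunc <- overlap <- logical(m)
  reason <- rep(NA_character_, m)
  k_ref <- max(1L, round(2 / dt_ms))
  for (i in seq_len(m)) {
    if (onset[i] >= peak[i]) onset[i] <- peak[i] - 1L  # degenerate back-walk
    win_end <- min(onset[i] + win_len, next_onset[i] - 1L, n)
    win_end <- min(max(win_end, peak[i] + 2L), n)  # keep a decay foothold
    met <- event_metrics(d, onset[i], peak[i], win_end, fs, band = band)
    amp[i] <- met$peak_amplitude; rise[i] <- met$rise_10_90
    dur_ms[i] <- met$duration; charge[i] <- met$charge
    t70[i] <- met$t70; t70_trunc[i] <- met$t70_truncated
    overlap[i] <- (onset[i] - prev_onset[i]) * dt_ms < pre_exclude_ms ||
      (next_onset[i] - onset[i]) * dt_ms < window_ms
    if (!is.na(template_r)) {
      L <- min(win_end - onset[i] + 1L, length(template))
      tcorr[i] <- if (L >= 3L) suppressWarnings(
        stats::cor(d[onset[i]:(onset[i] + L - 1L)], template[seq_len(L)])
      ) else NA_real_
    }
    # excursion relative to the immediately pre-onset level: a noise dip
    # riding on the decaying tail of an earlier event crosses the absolute
    # threshold without a genuine local downstroke -- the kind of candidate
    # manual inspection would discard
    local_ref <- stats::median(d[max(1L, onset[i] - k_ref):onset[i]])
    if (amp[i] > threshold) reason[i] <- "amplitude"
    else if (!is.na(dur_ms[i]) && dur_ms[i] <= min_duration) reason[i] <- "duration"
    else if (!is.na(rise[i]) && rise[i] > max_rise) reason[i] <- "rise_time"
    else if (amp[i] - local_ref > threshold) reason[i] <- "artifact"
    else if (!is.na(tcorr[i]) && tcorr[i] < template_r) reason[i] <- "artifact"
  }
  tibble::tibble(
    onset_index = onset, peak_index = peak,
    onset_ms = (onset - 1L) * dt_ms,
    peak_amplitude = amp, rise_10_90 = rise, duration = dur_ms,
    charge = charge, t70 = t70, t70_truncated = t70_trunc,
    template_corr = tcorr, overlap = overlap, accepted = is.na(reason),
    reject_reason = reason
  )
}

.empty_events <- function() {
  tibble::tibble(onset_index = integer(), peak_index = integer(),
                 onset_ms = numeric(), peak_amplitude = numeric(),
                 rise_10_90 = numeric(), duration = numeric(),
                 charge = numeric(), t70 = numeric(),
                 t70_truncated = logical(), template_corr = numeric(),
                 overlap = logical(), accepted = logical(),
                 reject_reason = character())
}

.event_template <- function(kinetics, dt_ms, window_ms) {
  if (is.null(kinetics)) kinetics <- event_kinetics()
  dur <- max(10 * kinetics$tau_slow, window_ms)
  w <- event_waveform(kinetics, dt_ms, dur)
  w[seq_len(min(length(w), round(window_ms / dt_ms)))]
}

#' Per-event kinetic metrics
#'
#' Measures one event window of a baseline-subtracted trace. The 10-90% rise
#' time interpolates the crossing times of 10% and 90% of the baseline-to-peak
#' excursion; `t70` is the interpolated time from the peak until the excursion
#' has decayed by 70% (to 30% remaining); charge is the trapezoidal area of
#' the excursion over the window (pA ms, same sign as the peak).
#'
#' @param d baseline-subtracted current (pA), full sweep.
#' @param onset_index,peak_index,win_end 1-based sample indices delimiting the
#'   event (onset, peak, end of measurement window).
#' @param sampling_rate Hz.
#' @param band return-to-baseline level in pA (negative) used for the duration
#'   measurement; defaults to one robust noise SD below baseline.
#' @return List with `peak_amplitude`, `rise_10_90`, `duration`, `charge`,
#'   `t70`, `t70_truncated`.
#' @export
event_metrics <- function(d, onset_index, peak_index, win_end, sampling_rate,
                          band = -stats::mad(d)) {
  dt_ms <- 1000 / sampling_rate
  stopifnot(onset_index < peak_index, peak_index <= win_end)
  amp <- d[peak_index]

  idx_rise <- onset_index:peak_index
  t_rise <- (idx_rise - onset_index) * dt_ms
  y_rise <- d[idx_rise]
  t10 <- crossing_time(t_rise, y_rise, 0.1 * amp, "down")
  t90 <- crossing_time(t_rise, y_rise, 0.9 * amp, "down")
  rise <- if (is.na(t10) || is.na(t90)) NA_real_ else t90 - t10

  idx_dec <- peak_index:win_end
  t_dec <- (idx_dec - peak_index) * dt_ms
  y_dec <- d[idx_dec]
  t70 <- crossing_time(t_dec, y_dec, 0.30 * amp, "up")
  t70_truncated <- is.na(t70)

  t_end <- crossing_time(t_dec, y_dec, band, "up")
  duration <- if (is.na(t_end)) (win_end - onset_index) * dt_ms
              else (peak_index - onset_index) * dt_ms + t_end

  charge <- trapz_uniform(d[onset_index:win_end], dt_ms)
  list(peak_amplitude = amp, rise_10_90 = rise, duration = duration,
       charge = charge, t70 = t70, t70_truncated = t70_truncated)
}

#' Event-masked baseline refinement
#'
#' Second-pass baseline: the sample stretches occupied by detected events
#' (from 2 ms before each onset to several decay times after it) are masked
#' out, the remaining quiet samples are averaged in short blocks, and the
#' block levels are linearly interpolated across the masked gaps. Unlike a
#' plain running median, the refined baseline cannot be dragged down by the
#' decaying tails of the events themselves, which would otherwise clip the
#' slow component of the mean event.
#'
#' @param trace a [sweep_trace()].
#' @param events detection table from [detect_events()].
#' @param block_s block length for the quiet-level estimate, seconds.
#' @param tail_ms mask extent after each onset; defaults to
#'   `max(200, 12 * median(t70))` so tails are masked down to well below the
#'   noise floor.
#' @return Numeric baseline, same length as the trace.
#' @export
refine_baseline <- function(trace, events, block_s = 0.1, tail_ms = NULL) {
  stopifnot(inherits(trace, "sweep_trace"))
  x <- trace$samples
  n <- length(x)
  fs <- trace$sampling_rate
  if (!nrow(events)) return(rep(stats::median(x), n))
  if (is.null(tail_ms)) {
    t70m <- stats::median(events$t70, na.rm = TRUE)
    tail_ms <- if (is.finite(t70m)) max(200, 12 * t70m) else 200
  }
  masked <- rep(FALSE, n)
  pre <- round(2e-3 * fs)
  post <- round(tail_ms / 1000 * fs)
  for (o in events$onset_index)
    masked[max(1L, o - pre):min(n, o + post)] <- TRUE
  bl <- max(10L, round(block_s * fs))
  nb <- ceiling(n / bl)
  centers <- levels_ <- numeric(nb)
  ok <- logical(nb)
  for (b in seq_len(nb)) {
    i0 <- (b - 1L) * bl + 1L; i1 <- min(n, b * bl)
    idx <- i0:i1
    quiet <- idx[!masked[idx]]
    centers[b] <- (i0 + i1) / 2
    if (length(quiet) >= bl / 5) {
      levels_[b] <- mean(x[quiet]); ok[b] <- TRUE
    }
  }
  if (!any(ok)) return(rep(stats::median(x[!masked]), n))
  stats::approx(centers[ok], levels_[ok], xout = seq_len(n), rule = 2)$y
}
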