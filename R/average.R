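#' Rise-midpoint-aligned mean event
#'
#' Builds the mean mIPSC of a cell: each accepted, non-overlapped event is
#' shifted so that the midpoint of its rising phase (the interpolated 50%
#' point of the baseline-to-peak excursion) sits at a common time origin, and
#' the aligned segments are averaged point-wise. Sub-sample alignment uses
#' linear interpolation of the trace onto the common grid.
#'
#' @param trace a [sweep_trace()].
#' @param events detection table from [detect_events()].
#' @param window_ms post-midpoint extent of the averaged segment, ms.
#' @param pre_ms pre-midpoint extent, ms.
#' @param baseline optional precomputed baseline.
#' @param use_overlapped include overlap-flagged events (default `FALSE`).
#' @return An object of class `mean_event`: `waveform` (pA,
#'   baseline-subtracted), `t_ms` (time from the rise midpoint), `dt_ms`,
#'   `n_events`, `alignment = "rise-midpoint"`.
#' @export
average_events <- function(trace, events, window_ms = 150, pre_ms = 10,
                           baseline = NULL, use_overlapped = FALSE) {
  stopifnot(inherits(trace, "sweep_trace"))
  sel <- events$accepted & (use_overlapped | !events$overlap)
  ev <- events[sel, , drop = FALSE]
  if (nrow(ev) < 2L)
    stop("at least 2 accepted, non-overlapped events are required for averaging")
  fs <- trace$sampling_rate
  dt_ms <- 1000 / fs
  if (is.null(baseline)) baseline <- estimate_baseline(trace)
  d <- trace$samples - baseline
  n <- length(d)
  t_all_ms <- (seq_len(n) - 1L) * dt_ms

  grid <- seq(-pre_ms, window_ms, by = dt_ms)
  acc <- numeric(length(grid))
  used <- 0L
  for (i in seq_len(nrow(ev))) {
    mid <- .rise_midpoint_ms(d, ev$onset_index[i], ev$peak_index[i], dt_ms)
    if (is.na(mid)) next
    at <- mid + grid
    if (at[1L] < 0 || at[length(at)] > t_all_ms[n]) next  # truncated by sweep edge
    # interpolate on a local slice only; the trace is long
    i0 <- max(1L, floor(at[1L] / dt_ms))
    i1 <- min(n, ceiling(at[length(at)] / dt_ms) + 2L)
    seg <- stats::approx(t_all_ms[i0:i1], d[i0:i1], xout = at)$y
    acc <- acc + seg
    used <- used + 1L
  }
  if (used < 2L) stop("fewer than 2 events had a full averaging window")
  structure(
    list(waveform = acc / used, t_ms = grid, dt_ms = dt_ms, n_events = used,
         alignment = "rise-midpoint"),
    class = "mean_event"
  )
}

# interpolated time (ms from sweep start) at which the excursion first reaches
# 50% of the baseline-to-peak amplitude
.rise_midpoint_ms <- function(d, onset_index, peak_index, dt_ms) {
  idx <- onset_index:peak_index
  t <- (idx - 1L) * dt_ms
  crossing_time(t, d[idx], 0.5 * d[peak_index], "down")
}

#' @export
print.mean_event <- function(x, ...) {
  cat(sprintf("mean event: %d events, %.1f ms window at %.2f ms, peak %.1f pA (%s aligned)\n",
              x$n_events, max(x$t_ms) - min(x$t_ms), x$dt_ms,
              min(x$waveform), x$alignment))
  invisible(x)
}
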