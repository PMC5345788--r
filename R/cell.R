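#' Per-cell summary of event metrics and mean-event kinetics
#'
#' Aggregates the accepted events of one cell (mean peak amplitude, 10-90%
#' rise, charge transfer and T70) and attaches the weighted decay constant of
#' the mean-event fit. Cells with fewer than `min_events` accepted events are
#' returned with `included = FALSE` (they are excluded from cohort statistics)
#' and the reason recorded.
#'
#' @param events detection table from [detect_events()].
#' @param fit a [decay_fit()] of the cell's mean event (may be `NULL` when the
#'   cell is excluded).
#' @param cell_id identifier carried into the summary row.
#' @param min_events minimum accepted events for inclusion (default 50).
#' @return One-row tibble: `cell_id`, `n_events` (accepted), `n_averaged`,
#'   `amp_pa`, `rise_ms`, `charge_pams`, `t70_ms`, `model`, `tau_fast`,
#'   `tau_slow`, `p1`, `tau_w`, `f_p`, `included`, `exclude_reason`.
#' @export
cell_summary <- function(events, fit = NULL, cell_id = "cell",
                         min_events = 50) {
  acc <- events[events$accepted, , drop = FALSE]
  n_acc <- nrow(acc)
  reason <- NA_character_
  if (n_acc < min_events) reason <- "min_events"
  else if (is.null(fit) || !isTRUE(fit$converged)) reason <- "fit_failure"
  ok <- is.na(reason)
  tibble::tibble(
    cell_id = as.character(cell_id),
    n_events = n_acc,
    n_averaged = if (ok) fit$bi$n_points_events %||% NA_integer_ else NA_integer_,
    amp_pa = mean(acc$peak_amplitude),
    rise_ms = mean(acc$rise_10_90, na.rm = TRUE),
    charge_pams = mean(acc$charge),
    t70_ms = mean(acc$t70, na.rm = TRUE),
    model = if (ok) fit$model else NA_character_,
    tau_fast = if (ok) fit$tau_fast else NA_real_,
    tau_slow = if (ok) fit$tau_slow else NA_real_,
    p1 = if (ok) fit$p1 else NA_real_,
    tau_w = if (ok) fit$tau_w else NA_real_,
    f_p = if (ok) fit$f_pvalue else NA_real_,
    included = ok,
    exclude_reason = reason
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run detection, averaging and decay fitting on one sweep
#'
#' @param trace a [sweep_trace()].
#' @param cell_id identifier for the summary row.
#' @param min_events inclusion rule for cohort statistics (default 50).
#' @param alpha F-test level.
#' @param window_ms,pre_ms detection/averaging windows (ms).
#' @param template_kinetics optional template for the artifact screen.
#' @param ... further arguments to [detect_events()].
#' @return List of class `cell_analysis`: `qc`, `events`, `mean_event`, `fit`,
#'   `summary` (one-row tibble). Traces failing series-resistance QC are
#'   summarised as excluded with reason `"qc"`.
#' @export
analyze_cell <- function(trace, cell_id = trace$label, min_events = 50,
                         alpha = 0.05, window_ms = 150, pre_ms = 10,
                         template_kinetics = NULL, ...) {
  qc <- qc_recording(trace$rs_start, trace$rs_end)
  if (!qc$valid) {
    smry <- tibble::tibble(
      cell_id = as.character(cell_id), n_events = 0L, n_averaged = NA_integer_,
      amp_pa = NA_real_, rise_ms = NA_real_, charge_pams = NA_real_,
      t70_ms = NA_real_, model = NA_character_, tau_fast = NA_real_,
      tau_slow = NA_real_, p1 = NA_real_, tau_w = NA_real_, f_p = NA_real_,
      included = FALSE, exclude_reason = "qc")
    return(structure(list(qc = qc, events = .empty_events(), mean_event = NULL,
                          fit = NULL, summary = smry),
                     class = "cell_analysis"))
  }
  # two-pass baseline: a coarse running median locates the events, then the
  # event-masked refinement removes the tail-induced droop before the final
  # detection and averaging pass
  b0 <- estimate_baseline(trace)
  ev0 <- detect_events(trace, window_ms = window_ms, pre_ms = pre_ms,
                       template_kinetics = template_kinetics,
                       baseline = b0, ...)
  baseline <- refine_baseline(trace, ev0)
  events <- detect_events(trace, window_ms = window_ms, pre_ms = pre_ms,
                          template_kinetics = template_kinetics,
                          baseline = baseline, ...)
  mean_event <- NULL; fit <- NULL
  n_usable <- sum(events$accepted & !events$overlap)
  if (n_usable >= 2L) {
    mean_event <- average_events(trace, events, window_ms = window_ms,
                                 pre_ms = pre_ms, baseline = baseline)
    fit <- decay_fit(mean_event, alpha = alpha)
  }
  smry <- cell_summary(events, fit, cell_id = cell_id, min_events = min_events)
  if (!is.null(mean_event)) smry$n_averaged <- mean_event$n_events
  structure(list(qc = qc, events = events, mean_event = mean_event, fit = fit,
                 summary = smry),
            class = "cell_analysis")
}

#' Simulate and analyse a whole cohort
#'
#' Streams through the cells of a preset cohort: each cell is simulated
#' ([simulate_cell()]), analysed ([analyze_cell()]) and discarded, keeping the
#' per-cell summaries and the ground truth.
#'
#' @inheritParams simulate_cohort
#' @param min_events,alpha,window_ms analysis options (see [analyze_cell()]).
#' @param verbose print one line per cell.
#' @return Tibble of per-cell summaries with extra columns `preset`,
#'   `true_tau_w`.
#' @export
analyze_cohort <- function(preset, seed = 1, n_cells = NULL, min_events = 50,
                           alpha = 0.05, window_ms = 150, verbose = FALSE,
                           ...) {
  if (is.character(preset)) preset <- preset(preset)
  if (is.null(n_cells)) n_cells <- preset$n_cells
  out <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    sim <- simulate_cell(preset, cell_index = i, seed = seed, ...)
    res <- analyze_cell(sim$trace, cell_id = sprintf("%s_c%02d", preset$name, i),
                        min_events = min_events, alpha = alpha,
                        window_ms = window_ms,
                        template_kinetics = sim$config$kinetics)
    s <- res$summary
    s$preset <- preset$name
    s$true_tau_w <- tau_w_of(sim$config$kinetics)
    out[[i]] <- s
    if (verbose)
      message(sprintf("%s: %d accepted events, tau_w %.2f (true %.2f)",
                      s$cell_id, s$n_events, s$tau_w, s$true_tau_w))
  }
  do.call(rbind, out)
}
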