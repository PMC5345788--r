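# Cohort preset registry.
#
# Each preset fixes the ground-truth weighted decay constant tau_w (ms), the
# across-cell SD of tau_w, and the number of cells for one recorded group.
# Developmental presets (spinal lamina II, nucleus reticularis) use published
# group means; the adult cortex control values are not available as printed
# numbers and are synthetic defaults chosen to be physiologically plausible
# (flagged by `synthetic_tau = TRUE`). Neurosteroid-incubation presets are
# defined as multiplicative tau_w shifts of their control preset, applied
# proportionally to both decay components.

.preset_table <- function() {
  list(
    # spinal cord lamina II, development
    spinal_P8_11  = list(tau_w = 24.8, sd = 2.0, n_cells = 26, synthetic_tau = FALSE),
    spinal_P17_25 = list(tau_w = 19.4, sd = 1.8, n_cells = 31, synthetic_tau = FALSE),
    spinal_P60_75 = list(tau_w = 17.5, sd = 1.8, n_cells = 13, synthetic_tau = FALSE),
    # nucleus reticularis of the thalamus, development
    nRT_P6_7   = list(tau_w = 33.2, sd = 1.0, n_cells = 24, synthetic_tau = FALSE),
    nRT_P9_10  = list(tau_w = 22.5, sd = 0.7, n_cells = 14, synthetic_tau = FALSE),
    nRT_P17_25 = list(tau_w = 18.2, sd = 0.6, n_cells = 32, synthetic_tau = FALSE),
    # adult cortex layer 2/3 (control tau_w values synthetic: group means for
    # these panels are not printed; they anchor the percent-of-control arms)
    cortex_WT_P60_75 = list(tau_w = 11.0, sd = 1.5, n_cells = 15, synthetic_tau = TRUE),
    cortex_obob_ctrl = list(tau_w = 9.0, sd = 1.2, n_cells = 9, synthetic_tau = TRUE),
    # allopregnanolone 2-h incubation arms: published percent-of-control
    # shifts (362% and 534%) applied to the ob/ob control preset; the printed
    # +-27/28 dispersions are percentage points on the percent-of-control
    # scale, so the across-cell SD is that fraction of the CONTROL mean
    cortex_obob_allo_100nM = list(tau_w = 9.0 * 3.62, sd = 0.27 * 9.0,
                                  n_cells = 9, synthetic_tau = TRUE,
                                  control = "cortex_obob_ctrl", shift = 3.62),
    cortex_obob_allo_300nM = list(tau_w = 9.0 * 5.34, sd = 0.28 * 9.0,
                                  n_cells = 9, synthetic_tau = TRUE,
                                  control = "cortex_obob_ctrl", shift = 5.34)
  )
}

#' Look up a named cohort preset
#'
#' A preset bundles the ground-truth kinetics of one recorded group (its
#' weighted decay constant `tau_w`, the across-cell SD of `tau_w`, and the
#' group size) together with the simulation defaults needed to generate a
#' full synthetic cohort. The returned kinetics satisfy
#' `p_fast * tau_fast + (1 - p_fast) * tau_slow == tau_w` exactly.
#'
#' Registered presets: spinal lamina II development (`spinal_P8_11`,
#' `spinal_P17_25`, `spinal_P60_75`), nucleus reticularis development
#' (`nRT_P6_7`, `nRT_P9_10`, `nRT_P17_25`), adult cortex layer 2/3
#' (`cortex_WT_P60_75`, `cortex_obob_ctrl`) and allopregnanolone incubation
#' arms defined as multiplicative shifts of the ob/ob control
#' (`cortex_obob_allo_100nM`, `cortex_obob_allo_300nM`).
#'
#' @param name preset label.
#' @param events_per_cell injected events per simulated cell (default 120,
#'   comfortably above the 50-accepted-event analysis rule after detection
#'   losses and overlap exclusion).
#' @return An object of class `cohort_preset` with fields `name`, `kinetics`
#'   (an [event_kinetics()]), `tau_w` (ground truth, ms), `tau_w_sd`
#'   (across-cell SD, ms), `n_cells` and `events_per_cell`.
#' @examples
#' preset("spinal_P8_11")$tau_w  # 24.8
#' @export
preset <- function(name, events_per_cell = 120) {
  tab <- .preset_table()
  if (!is.character(name) || length(name) != 1L || !name %in% names(tab))
    stop("unknown preset '", paste(name, collapse = ","), "'; registered presets: ",
         paste(names(tab), collapse = ", "))
  p <- tab[[name]]
  structure(
    list(name = name,
         kinetics = kinetics_from_tau_w(p$tau_w),
         tau_w = p$tau_w,
         tau_w_sd = p$sd,
         n_cells = p$n_cells,
         events_per_cell = events_per_cell,
         synthetic_tau = p$synthetic_tau,
         control = p$control,
         shift = p$shift),
    class = "cohort_preset"
  )
}

#' Names of all registered cohort presets
#' @return Character vector of preset labels.
#' @export
preset_names <- function() names(.preset_table())

#' @export
print.cohort_preset <- function(x, ...) {
  cat(sprintf("cohort preset '%s': tau_w %.2f +- %.2f ms, %d cells x >=%d events%s\n",
              x$name, x$tau_w, x$tau_w_sd, x$n_cells, x$events_per_cell,
              if (isTRUE(x$synthetic_tau)) " (synthetic tau_w)" else ""))
  invisible(x)
}
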