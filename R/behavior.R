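#' Maximum possible effect (MPE) of a tail-flick latency
#'
#' Antinociception expressed relative to the assay cutoff. In the default
#' `"normalized"` mode `MPE = 100 * (latency - baseline) / (cutoff -
#' baseline)`, clipped to `[0, 100]`; the `"simple"` mode expresses the
#' latency directly as a percentage of the cutoff (`100 * latency / cutoff`),
#' without baseline subtraction.
#'
#' @param latency withdrawal latency in seconds, in `(0, cutoff]`.
#' @param baseline pre-treatment latency in seconds (normalized mode only).
#' @param cutoff assay cutoff in seconds (default 15).
#' @param mode `"normalized"` (default) or `"simple"`.
#' @return MPE in percent; vectorised over `latency`.
#' @examples
#' mpe(15, baseline = 3)          # 100: ceiling case
#' mpe(9, baseline = 3)           # 50
#' mpe(9, mode = "simple")        # 60
#' @export
mpe <- function(latency, baseline = NULL, cutoff = 15,
                mode = c("normalized", "simple")) {
  mode <- match.arg(mode)
  if (any(!is.finite(latency) | latency <= 0 | latency > cutoff))
    stop("latency must lie in (0, cutoff]")
  if (mode == "simple") return(pmin(pmax(100 * latency / cutoff, 0), 100))
  if (is.null(baseline)) stop("normalized MPE requires a baseline latency")
  if (any(!is.finite(baseline) | baseline <= 0 | baseline > cutoff))
    stop("baseline must lie in (0, cutoff]")
  if (any(baseline == cutoff))
    stop("baseline equal to cutoff: normalized MPE undefined")
  pmin(pmax(100 * (latency - baseline) / (cutoff - baseline), 0), 100)
}

#' von Frey response frequency of a group
#'
#' Pooled response frequency for one filament: total withdrawal responses over
#' total presses, with 10 presses per subject (5 per hindpaw).
#'
#' @param responses integer vector of per-subject response counts, each in
#'   0-10.
#' @param presses_per_subject presses per subject (default 10).
#' @return Frequency in percent.
#' @examples
#' vf_frequency(c(5))         # 50
#' vf_frequency(rep(10, 4))   # 100
#' @export
vf_frequency <- function(responses, presses_per_subject = 10) {
  if (!length(responses)) stop("at least one assessment is required")
  if (any(responses < 0 | responses > presses_per_subject))
    stop("response counts must lie in [0, presses_per_subject]")
  100 * sum(responses) / (presses_per_subject * length(responses))
}

#' Rotarod speed schedule
#'
#' Accelerating protocol: the rod starts at 6 rpm and steps up in 4 rpm
#' increments to a maximum of 50 rpm. The increment interval is configurable
#' (default 27 s, spreading the 11 speed steps over the 300 s trial).
#'
#' @param t time into the trial in seconds, in `[0, 300]`.
#' @param step_s seconds per increment (default 27).
#' @param cutoff trial cutoff in seconds (default 300).
#' @return Rod speed in rpm; vectorised.
#' @examples
#' rotarod_speed_at(0)    # 6
#' rotarod_speed_at(299)  # 50
#' @export
rotarod_speed_at <- function(t, step_s = 27, cutoff = 300) {
  if (any(!is.finite(t) | t < 0 | t > cutoff))
    stop("t must lie within the trial, [0, cutoff] seconds")
  pmin(6 + 4 * floor(t / step_s), 50)
}

#' Non-parametric comparison of behavioural outcomes
#'
#' Rank-based tests for behavioural trial data: Mann-Whitney rank-sum for two
#' independent groups, Wilcoxon signed-rank for paired before/after designs,
#' and Kruskal-Wallis for three or more groups (pass a list of vectors as
#' `a`). Exact small-sample p values are used where there are no ties;
#' otherwise the normal approximation with tie correction. Censored latencies
#' should be entered at their cutoff value; ceiling ties are handled by
#' mid-ranks.
#'
#' @param a numeric vector (or, for `"kruskal"`, a list of numeric vectors).
#' @param b numeric vector (second group, or paired "after" values).
#' @param test `"mannwhitney"`, `"wilcoxon_signed"` or `"kruskal"`.
#' @return List: `test`, `statistic`, `p_value`.
#' @export
compare_behavior <- function(a, b = NULL,
                             test = c("mannwhitney", "wilcoxon_signed",
                                      "kruskal")) {
  test <- match.arg(test)
  if (test == "kruskal") {
    stopifnot(is.list(a), length(a) >= 2L)
    ht <- stats::kruskal.test(a)
    return(list(test = test, statistic = unname(ht$statistic),
                p_value = ht$p.value))
  }
  stopifnot(is.numeric(a), is.numeric(b))
  if (test == "wilcoxon_signed") {
    if (length(a) != length(b)) stop("paired test requires matched lengths")
    if (all(a == b)) {
      warning("all paired differences are zero; degenerate signed-rank test")
      return(list(test = test, statistic = 0, p_value = 1))
    }
    ht <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b))
  }
  list(test = test, statistic = unname(ht$statistic), p_value = ht$p.value)
}

# Behavioural generator presets. Latency assays draw truncated-normal
# latencies censored at the assay cutoff; von Frey assays draw
# Binomial(10, p) response counts per subject. Rotarod group parameters are
# published group values; tail-flick means and the elevated ob/ob von Frey
# probabilities for sub-threshold filaments are plausible synthetic defaults
# (the printed sources give significance, not group means, for those panels).
.behavior_presets <- function() {
  list(
    rotarod_WT   = list(assay = "rotarod", mean = 216, sd = 14, cutoff = 300),
    rotarod_obob = list(assay = "rotarod", mean = 21, sd = 5, cutoff = 300),
    tailflick_WT_50C   = list(assay = "tailflick", mean = 3.0, sd = 0.8,
                              cutoff = 15, temp_c = 50),
    tailflick_obob_50C = list(assay = "tailflick", mean = 6.0, sd = 1.5,
                              cutoff = 15, temp_c = 50),
    vonfrey_WT   = list(assay = "vonfrey",
                        p = c(`0.16` = 0.20, `0.4` = 0.40, `0.6` = 0.60,
                              `1` = 0.90)),
    vonfrey_obob = list(assay = "vonfrey",
                        p = c(`0.16` = 0.55, `0.4` = 0.70, `0.6` = 0.85,
                              `1` = 0.93))
  )
}

#' Names of the registered behavioural presets
#' @return Character vector.
#' @export
behavior_preset_names <- function() names(.behavior_presets())

#' Simulate behavioural trial tables
#'
#' Draws one trial table from a named behavioural preset. Latency assays
#' (rotarod, tail flick) use a normal distribution truncated below at 0.1 s
#' and censored at the assay cutoff (`censored = TRUE` where the cutoff was
#' reached); von Frey assays draw Binomial(10, p) response counts per subject
#' for each of the four filaments.
#'
#' @param preset preset name (see [behavior_preset_names()]).
#' @param n_subjects number of subjects.
#' @param seed integer seed.
#' @return Tibble: `subject_id`, `group`, `assay`, `filament_g` / `temp_c`
#'   (where applicable), `value` (latency in s, or response count), `cutoff`,
#'   `censored`.
#' @export
simulate_behavior <- function(preset, n_subjects = 15, seed = 1) {
  tab <- .behavior_presets()
  if (!is.character(preset) || length(preset) != 1L || !preset %in% names(tab))
    stop("unknown behavioural preset '", preset, "'; registered: ",
         paste(names(tab), collapse = ", "))
  p <- tab[[preset]]
  with_seed(seed, {
    if (p$assay == "vonfrey") {
      rows <- lapply(names(p$p), function(f) {
        tibble::tibble(
          subject_id = sprintf("s%02d", seq_len(n_subjects)),
          group = preset, assay = "vonfrey",
          filament_g = as.numeric(f),
          value = stats::rbinom(n_subjects, 10, p$p[[f]]),
          cutoff = NA_real_, censored = FALSE)
      })
      return(do.call(rbind, rows))
    }
    lat <- stats::rnorm(n_subjects, p$mean, p$sd)
    lat <- pmax(lat, 0.1)
    censored <- lat >= p$cutoff
    lat <- pmin(lat, p$cutoff)
    out <- tibble::tibble(
      subject_id = sprintf("s%02d", seq_len(n_subjects)),
      group = preset, assay = p$assay,
      value = lat, cutoff = p$cutoff, censored = censored)
    if (!is.null(p$temp_c)) out$temp_c <- p$temp_c
    out
  })
}
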