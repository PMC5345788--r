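#' Group summaries of a per-cell metric
#'
#' Arithmetic mean and sample SD of one metric per group, over cells that
#' passed the inclusion rules.
#'
#' @param values numeric vector of per-cell values.
#' @param groups group labels, same length.
#' @return Tibble: `group`, `n`, `mean`, `sd`.
#' @export
cohort_summarize <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  labs <- unique(groups)
  empty <- labs[!labs %in% groups[!is.na(values)]]
  if (length(empty)) stop("empty group after filtering: ", paste(empty, collapse = ", "))
  out <- lapply(labs, function(g) {
    v <- values[groups == g & !is.na(values)]
    tibble::tibble(group = g, n = length(v), mean = mean(v), sd = stats::sd(v))
  })
  do.call(rbind, out)
}

#' Group comparison for per-cell electrophysiology metrics
#'
#' Classical parametric tests matching standard practice for per-neuron
#' summaries: Student's unpaired or paired t test, one-way ANOVA (with a
#' Newman-Keuls post hoc stepdown when the omnibus test is significant), or a
#' one-way repeated-measures ANOVA (subject as the error stratum).
#'
#' @param values numeric per-cell values.
#' @param groups group labels.
#' @param design one of `"t_unpaired"`, `"t_paired"`, `"anova_1way"`,
#'   `"anova_rm"`.
#' @param subject subject identifiers, required for paired/repeated designs.
#' @param alpha level used to gate the post hoc procedure.
#' @return List of class `cohort_test`: `design`, `statistic`, `p_value`,
#'   `summary` (per-group tibble), and `posthoc` (Newman-Keuls pairwise table,
#'   only for a significant one-way ANOVA).
#' @export
cohort_compare <- function(values, groups,
                           design = c("t_unpaired", "t_paired", "anova_1way",
                                      "anova_rm"),
                           subject = NULL, alpha = 0.05) {
  design <- match.arg(design)
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  posthoc <- NULL
  if (design %in% c("t_unpaired", "t_paired")) {
    if (nlevels(groups) != 2L) stop("t tests require exactly 2 groups")
    a <- values[groups == levels(groups)[1L]]
    b <- values[groups == levels(groups)[2L]]
    if (design == "t_paired") {
      if (length(a) != length(b)) stop("paired design requires matched lengths")
      if (stats::sd(a - b) == 0) {
        # zero-variance differences: define t = 0, p = 1 (no effect)
        return(structure(list(design = design, statistic = 0, p_value = 1,
                              summary = cohort_summarize(values, groups),
                              posthoc = NULL),
                         class = "cohort_test"))
      }
      ht <- stats::t.test(a, b, paired = TRUE)
    } else {
      ht <- stats::t.test(a, b, var.equal = TRUE)
    }
    statistic <- unname(ht$statistic); p <- ht$p.value
  } else if (design == "anova_1way") {
    fit <- stats::aov(values ~ groups)
    tab <- summary(fit)[[1L]]
    statistic <- tab[["F value"]][1L]; p <- tab[["Pr(>F)"]][1L]
    if (is.finite(p) && p < alpha)
      posthoc <- newman_keuls(values, groups, alpha = alpha)
  } else {
    if (is.null(subject)) stop("anova_rm requires subject identifiers")
    subject <- factor(subject)
    fit <- stats::aov(values ~ groups + Error(subject))
    tab <- summary(fit)[["Error: Within"]][[1L]]
    statistic <- tab[["F value"]][1L]; p <- tab[["Pr(>F)"]][1L]
  }
  structure(list(design = design, statistic = statistic, p_value = p,
                 summary = cohort_summarize(values, groups), posthoc = posthoc),
            class = "cohort_test")
}

#' @export
print.cohort_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$design, x$statistic, x$p_value))
  print(x$summary)
  if (!is.null(x$posthoc)) { cat("Newman-Keuls:\n"); print(x$posthoc) }
  invisible(x)
}

#' Newman-Keuls stepdown post hoc comparisons
#'
#' Studentized-range stepdown on the ranked group means after a one-way
#' ANOVA. Pairs spanning `r` ordered means are compared against
#' `qtukey(1 - alpha, r, df_error)`; a pair is only tested (and can only be
#' declared significant) when every wider pair containing it was significant.
#' Unequal group sizes use the harmonic mean n.
#'
#' @param values numeric observations.
#' @param groups group labels.
#' @param alpha level of each stepdown stage (default 0.05).
#' @return Tibble: `group_a`, `group_b` (ordered by mean), `diff`, `span`,
#'   `q`, `q_crit`, `significant`.
#' @export
newman_keuls <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  k <- nlevels(groups)
  stopifnot(k >= 2L)
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1L]]
  mse <- tab[["Mean Sq"]][2L]
  df_err <- tab[["Df"]][2L]
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  ord <- order(means)
  means <- means[ord]; ns <- ns[ord]
  labs <- names(means)

  sig <- matrix(NA, k, k)  # upper triangle in ordered indices
  rows <- list()
  for (span in k:2) {
    for (i in 1:(k - span + 1L)) {
      j <- i + span - 1L
      # containment rule: testable only if every wider pair containing (i, j)
      # was significant
      testable <- TRUE
      if (span < k) {
        if (i > 1L && !isTRUE(sig[i - 1L, j])) testable <- FALSE
        if (j < k && !isTRUE(sig[i, j + 1L])) testable <- FALSE
      }
      nh <- 2 / (1 / ns[i] + 1 / ns[j])  # harmonic mean n for the pair
      se <- sqrt(mse / nh)
      q <- (means[j] - means[i]) / se
      qc <- stats::qtukey(1 - alpha, span, df_err)
      s <- testable && q > qc
      sig[i, j] <- s
      rows[[length(rows) + 1L]] <- tibble::tibble(
        group_a = labs[i], group_b = labs[j],
        diff = unname(means[j] - means[i]), span = span, q = unname(q),
        q_crit = qc, significant = s)
    }
  }
  do.call(rbind, rows)
}

#' Percent-of-control normalization of a treated group
#'
#' Expresses the mean of the treated group's metric as a percentage of the
#' control group's mean, with the standard error propagated by the delta
#' method.
#'
#' @param treated,control numeric per-cell values (e.g. `tau_w`).
#' @param treatment_label,control_label labels carried into the result.
#' @return List of class `normalized_effect`: `percent_of_control`,
#'   `dispersion` (delta-method SE, in percent), group means and ns.
#' @export
normalize_to_control <- function(treated, control,
                                 treatment_label = "treated",
                                 control_label = "control") {
  treated <- treated[!is.na(treated)]; control <- control[!is.na(control)]
  if (!length(treated) || !length(control)) stop("both groups must be non-empty")
  mc <- mean(control); mt <- mean(treated)
  if (mc <= 0) stop("control mean must be positive")
  se_t <- stats::sd(treated) / sqrt(length(treated))
  se_c <- stats::sd(control) / sqrt(length(control))
  pct <- 100 * mt / mc
  disp <- 100 * sqrt(se_t^2 / mc^2 + mt^2 * se_c^2 / mc^4)
  structure(list(treatment_label = treatment_label,
                 control_label = control_label,
                 percent_of_control = pct, dispersion = disp,
                 mean_treated = mt, mean_control = mc,
                 n_treated = length(treated), n_control = length(control)),
            class = "normalized_effect")
}

#' @export
print.normalized_effect <- function(x, ...) {
  cat(sprintf("%s = %.1f +- %.1f %% of %s (n = %d vs %d)\n",
              x$treatment_label, x$percent_of_control, x$dispersion,
              x$control_label, x$n_treated, x$n_control))
  invisible(x)
}
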