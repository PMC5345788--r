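# shared fixtures and independent oracles

# canonical kinetics used across tests
fix_kinetics <- function(tau_fast = 5, tau_slow = 40, p_fast = 0.6,
                         amplitude = -40, tau_rise = 0.3, cv = 0.4) {
  event_kinetics(amplitude_mean = amplitude, amplitude_cv = cv,
                 tau_rise = tau_rise, tau_fast = tau_fast,
                 tau_slow = tau_slow, p_fast = p_fast)
}

# small sweep config for fast tests
fix_config <- function(...) {
  args <- list(kinetics = fix_kinetics(), event_rate = 1.5,
               sweep_duration = 20, noise_sd = 1.5, seed = 42)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# a trace containing a single clean injected event, returned with its truth
fix_single_event_trace <- function(kinetics = fix_kinetics(),
                                   amplitude = -30, onset_s = 1.0,
                                   noise_sd = 0, fs = 10000,
                                   duration_s = 3, seed = 7,
                                   filter_cutoff = 2000) {
  n <- duration_s * fs
  x <- if (noise_sd > 0) withr::with_seed(seed, rnorm(n, 0, noise_sd))
       else numeric(n)
  k0 <- round(onset_s * fs) + 1L
  len <- min(n - k0, ceiling(10 * kinetics$tau_slow / 1000 * fs))
  t_ms <- (0:len) / fs * 1000
  x[k0:(k0 + len)] <- x[k0:(k0 + len)] +
    minis:::waveform_at(kinetics, t_ms, amplitude = amplitude)
  x <- minis:::lowpass_trace(x, fs, filter_cutoff)
  sweep_trace(x, fs, label = "single_event")
}

# independent brute-force biexponential fit: coarse grid search over
# (tau_fast, tau_slow, p1) with amplitude solved in closed form
grid_biexp_fit <- function(t, y, tau_grid = exp(seq(log(1), log(120), length.out = 60)),
                           p_grid = seq(0.05, 0.95, by = 0.05)) {
  best <- list(sse = Inf)
  for (tf in tau_grid) for (ts in tau_grid) {
    if (tf >= ts) next
    for (p1 in p_grid) {
      shape <- p1 * exp(-t / tf) + (1 - p1) * exp(-t / ts)
      A <- sum(shape * y) / sum(shape^2)
      sse <- sum((y - A * shape)^2)
      if (sse < best$sse)
        best <- list(sse = sse, A = A, tau_fast = tf, tau_slow = ts, p1 = p1,
                     tau_w = p1 * tf + (1 - p1) * ts)
    }
  }
  best
}

# independent Newman-Keuls stepdown, written with an explicit list of
# retained (non-significant) ranges: a pair contained in any retained range
# is never tested; otherwise its studentized range statistic is compared at
# its own span
brute_newman_keuls <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1L]]
  mse <- tab[["Mean Sq"]][2L]; dfe <- tab[["Df"]][2L]
  means <- sort(tapply(values, groups, mean))
  ns <- tapply(values, groups, length)[names(means)]
  k <- length(means)
  sig <- matrix(FALSE, k, k, dimnames = list(names(means), names(means)))
  retained <- list()
  for (span in k:2) {
    for (i in seq_len(k - span + 1L)) {
      j <- i + span - 1L
      blocked <- any(vapply(retained, function(r) r[1] <= i && j <= r[2],
                            logical(1)))
      if (blocked) { retained <- c(retained, list(c(i, j))); next }
      nh <- 2 / (1 / ns[i] + 1 / ns[j])
      q <- (means[j] - means[i]) / sqrt(mse / nh)
      if (q > stats::qtukey(1 - alpha, span, dfe)) sig[i, j] <- TRUE
      else retained <- c(retained, list(c(i, j)))
    }
  }
  sig
}
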