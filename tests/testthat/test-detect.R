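test_that("series-resistance QC applies the strict 20% / 15 MOhm rules", {
  expect_false(qc_recording(10, 16)$valid)    # exceeds 15 MOhm
  expect_false(qc_recording(10, 12.5)$valid)  # 25% change
  expect_true(qc_recording(10, 12)$valid)     # exactly 20% passes
  expect_true(qc_recording(15, 15)$valid)     # exactly 15 MOhm passes
  expect_false(qc_recording(16, 16)$valid)
  expect_false(qc_recording(10, 7.5)$valid)   # 25% drop also invalid
  expect_error(qc_recording(0, 10), "positive")
})

test_that("baseline estimation tracks constant level, drift and event-laden traces", {
  fs <- 5000
  flat <- sweep_trace(rep(-10, 2 * fs), fs)
  expect_equal(estimate_baseline(flat), rep(-10, 2 * fs))

  # linear drift, event-free noise: baseline follows the drift and the
  # residual keeps the noise SD
  drift <- seq(0, 5, length.out = 3 * fs)
  x <- withr::with_seed(1, drift + rnorm(3 * fs, 0, 1))
  tr <- sweep_trace(x, fs)
  b <- estimate_baseline(tr)
  res <- x - b
  mid <- (fs):(2 * fs)  # away from edges
  expect_lt(abs(mean(res[mid])), 0.05)
  expect_lt(abs(sd(res[mid]) - 1), 0.15)

  # dense events: baseline stays above the troughs
  sim <- simulate_sweep(fix_config(event_rate = 4, seed = 5))
  b2 <- estimate_baseline(sim$trace)
  expect_gt(min(b2), min(sim$trace$samples))
  expect_lt(abs(median(b2)), 1)
})

test_that("detection enforces the printed acceptance criteria", {
  # -4 pA event: rejected for amplitude
  small <- fix_single_event_trace(amplitude = -4)
  ev_small <- detect_events(small, template_r = NA)
  expect_false(any(ev_small$accepted))
  if (nrow(ev_small)) expect_true(all(ev_small$reject_reason == "amplitude"))

  # slow-rise event (10-90% rise 1.5 ms): rejected as rise_time
  slow <- fix_single_event_trace(kinetics = fix_kinetics(tau_rise = 0.7),
                                 amplitude = -30)
  ev_slow <- detect_events(slow, template_r = NA)
  expect_equal(nrow(ev_slow), 1)
  expect_gt(ev_slow$rise_10_90, 1)
  expect_false(ev_slow$accepted)
  expect_equal(ev_slow$reject_reason, "rise_time")

  # a clean event passes all three criteria
  ok <- fix_single_event_trace(amplitude = -30)
  ev_ok <- detect_events(ok)
  expect_true(any(ev_ok$accepted))
  acc <- ev_ok[ev_ok$accepted, ]
  expect_true(all(acc$peak_amplitude <= -5))
  expect_true(all(acc$duration > 2))
  expect_true(all(acc$rise_10_90 <= 1))
})

test_that("no accepted event ever violates the acceptance taxonomy", {
  sim <- simulate_sweep(fix_config(seed = 31))
  ev <- detect_events(sim$trace)
  acc <- ev[ev$accepted, ]
  expect_gt(nrow(acc), 5)
  expect_true(all(acc$peak_amplitude <= -5))
  expect_true(all(acc$duration > 2))
  expect_true(all(acc$rise_10_90 <= 1))
})

test_that("lowering the threshold magnitude never decreases the candidate count", {
  sim <- simulate_sweep(fix_config(seed = 13))
  n_at <- function(thr) nrow(detect_events(sim$trace, threshold = thr,
                                           template_r = NA))
  counts <- vapply(c(-20, -10, -5, -3), n_at, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("detection achieves high recall and precision on isolated events", {
  # default-noise sweeps; scored against the generator's truth table on
  # events without a close neighbour
  hits <- 0; n_iso <- 0; false_acc <- 0; n_acc <- 0
  for (s in 1:3) {
    sim <- simulate_sweep(fix_config(seed = 400 + s, sweep_duration = 30))
    ev <- detect_events(sim$trace, template_kinetics = sim$config$kinetics)
    truth_ms <- sim$truth$onset_s * 1000
    iso <- vapply(seq_along(truth_ms), function(j) {
      g <- abs(truth_ms[-j] - truth_ms[j]); all(g > 50)
    }, logical(1)) & sim$truth$amplitude_pa < -6
    det <- ev$onset_ms[ev$accepted]
    n_iso <- n_iso + sum(iso)
    hits <- hits + sum(vapply(truth_ms[iso],
                              function(o) any(abs(det - o) < 3), logical(1)))
    n_acc <- n_acc + length(det)
    false_acc <- false_acc + sum(vapply(det, function(o)
      all(abs(truth_ms - o) > 5), logical(1)))
  }
  expect_gte(hits / n_iso, 0.9)                 # recall
  expect_gte(1 - false_acc / n_acc, 0.9)        # precision
})

test_that("a too-short trace yields an empty result with a warning", {
  tr <- sweep_trace(rnorm(100), 10000)
  expect_warning(ev <- detect_events(tr), "shorter")
  expect_equal(nrow(ev), 0)
})
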