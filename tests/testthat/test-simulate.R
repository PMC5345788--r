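test_that("identical config and seed give bit-identical sweeps and truth", {
  cfg <- fix_config()
  a <- simulate_sweep(cfg)
  b <- simulate_sweep(cfg)
  expect_identical(a$trace$samples, b$trace$samples)
  expect_identical(a$truth, b$truth)
})

test_that("injected event counts follow the Poisson law", {
  # 200 replicate 20 s sweeps at 1.5 events/s: mean count 30
  counts <- vapply(1:200, function(i) {
    nrow(simulate_sweep(fix_config(seed = 1000 + i, noise_sd = 0))$truth)
  }, numeric(1))
  expected <- 1.5 * 20
  se <- sqrt(expected / 200)
  expect_lt(abs(mean(counts) - expected), 3 * se)
  expect_lt(abs(var(counts) / expected - 1), 0.35)  # Poisson variance
})

test_that("truth table is conserved and onsets stay inside the sweep", {
  sim <- simulate_sweep(fix_config(seed = 11))
  expect_true(all(sim$truth$onset_s >= 0))
  expect_true(all(sim$truth$onset_s < length(sim$trace$samples) /
                    sim$trace$sampling_rate))
  expect_false(is.unsorted(sim$truth$onset_s))
  # overlap flag marks onsets within 10 ms of the previous one
  expect_equal(sim$truth$overlapped,
               c(FALSE, diff(sim$truth$onset_s) < 0.010))
})

test_that("low-pass filtering strictly reduces the noise SD", {
  cfg <- fix_config(event_rate = 0, seed = 3)
  sim <- simulate_sweep(cfg)
  expect_lt(sd(sim$trace$samples), cfg$noise_sd)
})

test_that("noiseless single event is recovered by detection", {
  tr <- fix_single_event_trace(amplitude = -30)
  ev <- detect_events(tr)
  acc <- ev[ev$accepted, ]
  expect_equal(nrow(acc), 1)
  expect_equal(acc$peak_amplitude, -30, tolerance = 0.01)
  expect_lt(abs(acc$onset_ms - 1000), 0.2)
})

test_that("the minimum event count contract extends the sweep when needed", {
  cfg <- fix_config(sweep_duration = 5, event_rate = 2, seed = 21, noise_sd = 0)
  sim <- simulate_sweep(cfg, min_events = 30)
  expect_gte(nrow(sim$truth), 30)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(sampling_rate = 5000, filter_cutoff = 2000),
               "4 x filter_cutoff")
  expect_error(sim_config(event_rate = -1), "event_rate")
  expect_error(sim_config(noise_sd = -2), "noise_sd")
})

test_that("cohort simulation is reproducible and jitter targets the printed spread", {
  p <- preset("spinal_P8_11", events_per_cell = 10)
  # per-cell true tau_w draws: across many cells the SD approaches the
  # preset's across-cell SD and the mean its tau_w (law of large numbers on
  # the generator's own jitter distribution)
  tws <- vapply(1:150, function(i) {
    k <- withr::with_seed(minis:::derive_seed(55, i),
                          minis:::.jitter_kinetics(p$kinetics, p$tau_w_sd))
    tau_w_of(k)
  }, numeric(1))
  expect_lt(abs(mean(tws) - 24.8), 2 * 2.0 / sqrt(150))
  expect_lt(abs(sd(tws) - 2.0), 0.35)
  # determinism of a (tiny) simulated cohort
  small <- preset("spinal_P8_11", events_per_cell = 5)
  a <- simulate_cohort(small, seed = 9, n_cells = 2, sweep_duration = 4)
  b <- simulate_cohort(small, seed = 9, n_cells = 2, sweep_duration = 4)
  expect_identical(a$cells[[1]]$trace$samples, b$cells[[1]]$trace$samples)
  expect_identical(a$true_tau_w, b$true_tau_w)
})

test_that("preset registry exposes the printed group values", {
  expect_equal(preset("spinal_P8_11")$tau_w, 24.8)
  expect_equal(preset("spinal_P8_11")$n_cells, 26)
  expect_equal(preset("nRT_P6_7")$tau_w, 33.2)
  expect_equal(preset("nRT_P6_7")$n_cells, 24)
  # treatment presets are multiplicative shifts of their control
  expect_equal(preset("cortex_obob_allo_300nM")$tau_w /
                 preset("cortex_obob_ctrl")$tau_w, 5.34)
  expect_equal(preset("cortex_obob_allo_100nM")$tau_w /
                 preset("cortex_obob_ctrl")$tau_w, 3.62)
  # preset kinetics satisfy the tau_w identity exactly
  for (nm in preset_names())
    expect_equal(tau_w_of(preset(nm)$kinetics), preset(nm)$tau_w)
  expect_error(preset("no_such_cohort"), "registered presets")
})
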