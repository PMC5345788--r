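test_that("MPE boundary cases and arithmetic", {
  expect_equal(mpe(15, baseline = 3), 100)            # ceiling
  expect_equal(mpe(15, mode = "simple"), 100)
  expect_equal(mpe(3, baseline = 3), 0)               # latency at baseline
  expect_equal(mpe(9, baseline = 3), 50)              # (9-3)/(15-3)
  expect_equal(mpe(9, mode = "simple"), 60)
  # clipping below baseline
  expect_equal(mpe(2, baseline = 3), 0)
  # monotone nondecreasing in latency, bounded in [0, 100]
  lat <- seq(0.5, 15, by = 0.5)
  m <- mpe(lat, baseline = 3)
  expect_true(all(diff(m) >= 0))
  expect_true(all(m >= 0 & m <= 100))
  expect_error(mpe(16, baseline = 3), "latency")
  expect_error(mpe(10, baseline = 15), "undefined")
  expect_error(mpe(10), "baseline")
})

test_that("von Frey response frequency pools presses across subjects", {
  expect_equal(vf_frequency(rep(10, 4)), 100)
  expect_equal(vf_frequency(5), 50)
  expect_equal(vf_frequency(c(2, 4, 6, 8)), 50)
  # invariant to subject ordering; equals the pooled binomial MLE
  r <- withr::with_seed(2, rbinom(20, 10, 0.6))
  expect_equal(vf_frequency(r), vf_frequency(rev(r)))
  expect_equal(vf_frequency(r), 100 * sum(r) / 200)
  expect_error(vf_frequency(integer(0)), "at least one")
  expect_error(vf_frequency(11), "response counts")
})

test_that("rotarod schedule starts at 6 rpm, steps by 4, caps at 50", {
  expect_equal(rotarod_speed_at(0), 6)
  expect_equal(rotarod_speed_at(26.9), 6)
  expect_equal(rotarod_speed_at(27), 10)
  expect_equal(rotarod_speed_at(299), 50)
  sp <- rotarod_speed_at(seq(0, 300, by = 1))
  expect_true(all(sp %in% seq(6, 50, by = 4)))
  expect_true(all(diff(sp) >= 0))
  expect_error(rotarod_speed_at(301), "trial")
})

test_that("rank tests behave on identical, paired and multi-group data", {
  a <- c(1, 2, 3, 4, 5)
  r <- compare_behavior(a, a, test = "mannwhitney")
  expect_equal(r$p_value, 1)
  expect_warning(rw <- compare_behavior(a, a, test = "wilcoxon_signed"),
                 "degenerate")
  expect_equal(rw$p_value, 1)
  expect_error(compare_behavior(a, c(1, 2), test = "wilcoxon_signed"),
               "matched")
  kr <- compare_behavior(list(a, a + 10, a + 20), test = "kruskal")
  expect_lt(kr$p_value, 0.05)
  # rank tests are invariant to strictly monotone transforms
  b <- c(4, 5, 6, 7, 9)
  r1 <- compare_behavior(a, b, test = "mannwhitney")
  r2 <- compare_behavior(exp(a), exp(b), test = "mannwhitney")
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$statistic, r2$statistic)
})

test_that("Mann-Whitney type-I error is near nominal under the null", {
  rej <- vapply(1:500, function(i) {
    withr::with_seed(6000 + i, {
      a <- rnorm(12); b <- rnorm(12)
    })
    compare_behavior(a, b, test = "mannwhitney")$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.025)
})

test_that("behavioural simulation respects cutoffs and is reproducible", {
  t1 <- simulate_behavior("rotarod_WT", n_subjects = 15, seed = 8)
  t2 <- simulate_behavior("rotarod_WT", n_subjects = 15, seed = 8)
  expect_identical(t1, t2)
  expect_true(all(t1$value <= 300))
  expect_true(all(t1$value > 0))
  tf <- simulate_behavior("tailflick_obob_50C", n_subjects = 40, seed = 9)
  expect_true(all(tf$value <= 15))
  expect_identical(tf$censored, tf$value >= 15)
  vf <- simulate_behavior("vonfrey_WT", n_subjects = 12, seed = 10)
  expect_true(all(vf$value >= 0 & vf$value <= 10))
  expect_setequal(unique(vf$filament_g), c(0.16, 0.4, 0.6, 1))
  expect_error(simulate_behavior("no_such"), "registered")
})

test_that("impaired and control rotarod cohorts separate decisively", {
  wt <- simulate_behavior("rotarod_WT", 15, seed = 12)
  ob <- simulate_behavior("rotarod_obob", 15, seed = 13)
  r <- compare_behavior(wt$value, ob$value, test = "mannwhitney")
  expect_lt(r$p_value, 0.001)
})
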