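test_that("group summaries report arithmetic mean and sample SD", {
  s <- cohort_summarize(c(10, 20, 30), rep("g", 3))
  expect_equal(s$mean, 20)
  expect_equal(s$sd, 10)
  expect_equal(s$n, 3L)
  # duplicated group yields identical summaries
  s2 <- cohort_summarize(c(10, 20, 30, 10, 20, 30),
                         rep(c("a", "b"), each = 3))
  expect_equal(s2$mean[1], s2$mean[2])
  expect_equal(s2$sd[1], s2$sd[2])
  expect_error(cohort_summarize(c(NA_real_, 1), c("x", "y")), "empty group")
})

test_that("two identical groups give t = 0 and p = 1", {
  v <- c(1, 2, 3, 4)
  r <- cohort_compare(c(v, v), rep(c("a", "b"), each = 4),
                      design = "t_unpaired")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  rp <- cohort_compare(c(v, v), rep(c("a", "b"), each = 4),
                       design = "t_paired", subject = rep(1:4, 2))
  expect_equal(rp$p_value, 1)
})

test_that("t and F statistics are invariant to common rescaling", {
  withr::with_seed(10, {
    v <- rnorm(30, 10, 2)
    g <- rep(c("a", "b", "c"), each = 10)
  })
  r1 <- cohort_compare(v, g, design = "anova_1way")
  r2 <- cohort_compare(v * 7.3, g, design = "anova_1way")
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p_value, r2$p_value)
  t1 <- cohort_compare(v[1:20], g[1:20], design = "t_unpaired")
  t2 <- cohort_compare(7.3 * v[1:20], g[1:20], design = "t_unpaired")
  expect_equal(t1$statistic, t2$statistic)
})

test_that("one-way ANOVA type-I error is near nominal under the null", {
  rej <- vapply(1:600, function(i) {
    withr::with_seed(3000 + i, {
      v <- rnorm(24)
      g <- rep(c("a", "b", "c"), each = 8)
    })
    cohort_compare(v, g, design = "anova_1way")$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.025)
})

test_that("Newman-Keuls agrees with an independent stepdown implementation", {
  cases <- list(
    list(seed = 1, k = 3, delta = c(0, 1.2, 2.4), n = 10),
    list(seed = 2, k = 4, delta = c(0, 0.2, 2.5, 2.7), n = 8),
    list(seed = 3, k = 5, delta = c(0, 0, 0, 0, 0), n = 6),
    list(seed = 4, k = 3, delta = c(0, 3, 6), n = 12),
    list(seed = 5, k = 4, delta = c(0, 0.1, 0.2, 4), n = 9)
  )
  for (cs in cases) {
    vals <- withr::with_seed(cs$seed,
      unlist(lapply(cs$delta, function(d) rnorm(cs$n, d, 1))))
    grp <- rep(letters[seq_len(cs$k)], each = cs$n)
    nk <- newman_keuls(vals, grp)
    ref <- brute_newman_keuls(vals, grp)
    for (r in seq_len(nrow(nk))) {
      expect_identical(nk$significant[r],
                       unname(ref[nk$group_a[r], nk$group_b[r]]),
                       label = sprintf("case seed %d pair %s-%s", cs$seed,
                                       nk$group_a[r], nk$group_b[r]))
    }
  }
})

test_that("Newman-Keuls handles unequal group sizes via harmonic mean n", {
  vals <- withr::with_seed(9, c(rnorm(6, 0), rnorm(14, 2), rnorm(9, 5)))
  grp <- rep(c("a", "b", "c"), times = c(6, 14, 9))
  nk <- newman_keuls(vals, grp)
  ref <- brute_newman_keuls(vals, grp)
  for (r in seq_len(nrow(nk)))
    expect_identical(nk$significant[r],
                     unname(ref[nk$group_a[r], nk$group_b[r]]))
})

test_that("percent-of-control normalization and its invariances", {
  ctrl <- c(9, 10, 11)
  expect_equal(normalize_to_control(ctrl, ctrl)$percent_of_control, 100)
  expect_equal(normalize_to_control(2 * ctrl, ctrl)$percent_of_control, 200)
  # invariance to common rescaling
  tr <- c(30, 34, 38)
  a <- normalize_to_control(tr, ctrl)
  b <- normalize_to_control(5 * tr, 5 * ctrl)
  expect_equal(a$percent_of_control, b$percent_of_control)
  expect_equal(a$dispersion, b$dispersion)
  expect_error(normalize_to_control(tr, c(-3, 1)), "positive")
  expect_error(normalize_to_control(numeric(0), ctrl), "non-empty")
})

test_that("repeated-measures design uses the within-subject error stratum", {
  withr::with_seed(11, {
    subj <- rep(1:8, times = 3)
    cond <- rep(c("ctrl", "lo", "hi"), each = 8)
    base <- rnorm(8, 10, 3)[subj]
    v <- base + c(ctrl = 0, lo = 1, hi = 2)[cond] + rnorm(24, 0, 0.5)
  })
  rm_fit <- cohort_compare(v, cond, design = "anova_rm", subject = subj)
  ow <- cohort_compare(v, cond, design = "anova_1way")
  # removing the large between-subject variance must sharpen the test
  expect_lt(rm_fit$p_value, ow$p_value)
  expect_error(cohort_compare(v, cond, design = "anova_rm"), "subject")
})
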