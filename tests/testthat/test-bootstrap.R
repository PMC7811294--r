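test_that("error variances are unbiased sample variances per group", {
  # a two-point dataset with hand-set residuals +1 and -1
  scn <- scenario("caf_mono", A0 = 4, X0 = 8e4, id = "s1")
  tr <- simulate_scenario(scn, caf_pars)
  rec <- data.frame(scenario_id = "s1", time_h = c(24, 48),
                    stream = "NH4_mM",
                    value = tr$states[2:3, "W"] + c(1, -1))
  d <- gln_data(rec, scn, "CAF")
  f <- glnfit(d, init = caf_pars, free = character())
  expect_equal(unname(estimate_sigmas(f)), 2, tolerance = 1e-9)
  expect_equal(unname(estimate_sigmas(f, grouping = "stream")), 2,
               tolerance = 1e-9)

  # exact model output -> all variances 0
  f0 <- glnfit(caf_noiseless, init = caf_pars, free = character())
  expect_equal(unname(estimate_sigmas(f0)), 0, tolerance = 1e-15)

  # a group with < 2 residuals errors
  d1 <- gln_data(rec[1, ], scn, "CAF")
  f1 <- glnfit(d1, init = caf_pars, free = character())
  expect_error(estimate_sigmas(f1), "fewer than 2")
})

test_that("noise-variance estimation is calibrated on synthetic data", {
  # single replicates (no averaging), sigma = 0.5 on the weighted scale.
  # Calibration is checked on the cell-count stream, whose values sit far
  # from 0 so the additive-Gaussian model holds exactly; concentrations near
  # 0 are truncated by the generator, which biases their variance downward
  # by construction.
  hits <- 0L
  n_rep <- 200L
  des <- design_spec("CAF", noise = 0.5, n_replicates_averaged = 1,
                     obs_times = seq(0, 72, by = 12))
  for (i in seq_len(n_rep)) {
    d <- generate_data(des, caf_pars, seed = 10000 + i)
    f <- glnfit(d, init = caf_pars, free = character())
    s <- sqrt(estimate_sigmas(f, grouping = "stream")[["cells_CAF"]])
    if (s >= 0.4 && s <= 0.6) hits <- hits + 1L
  }
  expect_gte(hits, 0.9 * n_rep)
})

test_that("zero-noise bootstrap gives zero-width, reproducible intervals", {
  f <- cached("fit_caf_at_truth",
              glnfit(caf_noiseless, init = caf_pars,
                     control = glnfit_control(restarts = 1)))
  b <- bootstrap_ci(f, n_replicates = 12, seed = 3,
                    control = glnfit_control(maxit = 200, restarts = 0))
  width <- b$ci_high[b$free] - b$ci_low[b$free]
  expect_lt(max(abs(width) / coef(f)[b$free]), 1e-6)
  expect_equal(b$n_failed, 0L)
})

test_that("bootstrap intervals are seed-reproducible and shrink with noise", {
  d <- generate_data(design_spec("CAF", noise = 0.4), caf_pars, seed = 21)
  f <- glnfit(d, init = caf_pars, free = c("r1", "d1"),
              control = glnfit_control(maxit = 500, restarts = 0))
  ctl <- glnfit_control(maxit = 300, restarts = 0)
  b1 <- bootstrap_ci(f, n_replicates = 25, seed = 9, control = ctl)
  b2 <- bootstrap_ci(f, n_replicates = 25, seed = 9, control = ctl)
  expect_identical(b1$ci_low, b2$ci_low)
  expect_identical(b1$ci_high, b2$ci_high)
  expect_identical(b1$replicates, b2$replicates)

  # quartering the injected noise SD narrows the intervals
  d_lo <- generate_data(design_spec("CAF", noise = 0.1), caf_pars, seed = 21)
  f_lo <- glnfit(d_lo, init = caf_pars, free = c("r1", "d1"), control = ctl)
  b_lo <- bootstrap_ci(f_lo, n_replicates = 25, seed = 9, control = ctl)
  w_hi <- (b1$ci_high - b1$ci_low)[f$free] / coef(f)[f$free]
  w_lo <- (b_lo$ci_high - b_lo$ci_low)[f$free] / coef(f_lo)[f$free]
  expect_true(all(w_lo < w_hi))
})

test_that("sensitivity ranking normalizes intervals and tolerates zeros", {
  tab <- data.frame(parameter = c("a", "b", "c"),
                    estimate = c(2, 5, 0),
                    ci_low = c(1.9, 4, -1),
                    ci_high = c(2.1, 6, 1))
  s <- sensitivity_table(tab)
  expect_equal(s$parameter, c("a", "b", "c"))
  expect_equal(s$rel_width, c(0.1, 0.4, NA))
  expect_true(s$flagged[3])
  # degenerate interval ranks first
  tab2 <- rbind(tab, data.frame(parameter = "d", estimate = 3,
                                ci_low = 3, ci_high = 3))
  expect_equal(sensitivity_table(tab2)$parameter[1], "d")
  # ranking is invariant to input row order
  s2 <- sensitivity_table(tab2[c(3, 1, 4, 2), ])
  expect_equal(sensitivity_table(tab2), s2)
})
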