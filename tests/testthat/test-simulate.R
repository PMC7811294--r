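test_that("zero rates leave the state constant", {
  p0 <- mono_params(k1 = 0, c1 = 0, k2 = 0, c2 = 0, h = 0, k3 = 0,
                    r1 = 0, K1 = 1, r2 = 0, K2 = 1, d1 = 0, d2 = 0)
  tr <- simulate_scenario(scenario("caf_mono", A0 = 2, W0 = 5, X0 = 8e4), p0)
  expect_equal(tr$states,
               matrix(rep(c(2, 5, 20, 8e4), each = 4), 4,
                      dimnames = list(NULL, c("A", "W", "R", "X"))))
})

test_that("adaptive solver matches the fixed-step Euler oracle", {
  scn <- scenario("caf_mono", A0 = 4, W0 = 0, X0 = 8e4)
  tr <- simulate_scenario(scn, caf_pars)
  oracle <- euler_mono(caf_pars, c(4, 0, 20, 8e4), tr$times)
  expect_rel_close(tr$states[-1, ], oracle[-1, ])
})

test_that("solver-tolerance refinement changes observations by < 0.1%", {
  scn <- scenario("cc_mono", W0 = 10, X0 = 8e4)
  a <- simulate_scenario(scn, cc_pars, rtol = 1e-8, atol = 1e-10)
  b <- simulate_scenario(scn, cc_pars, rtol = 1e-9, atol = 1e-11)
  expect_rel_close(a$states[-1, ], b$states[-1, ], rel = 1e-3)

  co <- scenario("coculture_stress", W0 = 10, X0 = 4e4, Y0 = 4e4)
  a <- simulate_scenario(co, co_stress, rtol = 1e-8, atol = 1e-10)
  b <- simulate_scenario(co, co_stress, rtol = 1e-9, atol = 1e-11)
  expect_rel_close(a$states[-1, ], b$states[-1, ], rel = 1e-3)
})

test_that("the lsoda fallback agrees with the default integrator", {
  scn <- scenario("coculture_merged", W0 = 5, X0 = 4e4, Y0 = 4e4)
  a <- simulate_scenario(scn, co_merged)
  b <- simulate_scenario(scn, co_merged, solver = "lsoda")
  expect_rel_close(a$states[-1, ], b$states[-1, ], rel = 1e-4)
})

test_that("R is nonincreasing and L nondecreasing along trajectories", {
  grid <- seq(0, 72, by = 2)
  tr <- simulate_scenario(scenario("caf_mono", A0 = 4, X0 = 8e4), caf_pars,
                          times = grid)
  expect_true(all(diff(tr$states[, "R"]) <= 1e-10))
  tr <- simulate_scenario(scenario("coculture_stress", W0 = 10,
                                   X0 = 4e4, Y0 = 4e4),
                          co_stress, times = grid)
  expect_true(all(diff(tr$states[, "R"]) <= 1e-10))
  expect_true(all(diff(tr$states[, "L"]) >= -1e-10))
})

test_that("the R-replenishment hook resets the energy pool mid-run", {
  scn <- scenario("caf_mono", A0 = 0, W0 = 10, X0 = 8e4,
                  obs_times = c(0, 24, 36, 48, 72))
  plain <- simulate_scenario(scn, caf_pars)
  reset <- simulate_scenario(scn, caf_pars, r_reset = list(time = 36, value = 20))
  i36 <- which(plain$times == 36)
  expect_equal(plain$states[seq_len(i36), ], reset$states[seq_len(i36), ],
               tolerance = 1e-7)
  # after replenishment more energy remains and conversion continues harder
  expect_gt(reset$states[5, "R"], plain$states[5, "R"])
  expect_gt(reset$states[5, "A"], plain$states[5, "A"])
})

test_that("trajectories export tidily and mismatched configurations error", {
  tr <- simulate_scenario(scenario("caf_mono", A0 = 1, X0 = 8e4), caf_pars)
  df <- as.data.frame(tr)
  expect_named(df, c("scenario_id", "time_h", "variable", "value"))
  expect_equal(nrow(df), 4 * 4)
  expect_equal(df$value[df$variable == "A" & df$time_h == 0], 1)

  f <- tempfile(fileext = ".tsv")
  write_trajectories(tr, f)
  back <- read.delim(f)
  expect_equal(back$value, df$value, tolerance = 1e-12)

  expect_error(simulate_scenario(scenario("caf_mono", A0 = 1), co_merged),
               "mono_params")
  expect_error(simulate_scenario(scenario("coculture_merged", Y0 = 4e4),
                                 caf_pars), "co_params")
  expect_error(scenario("caf_mono", obs_times = c(0, 96)), "horizon")
  expect_error(scenario("caf_mono", obs_times = c(24, 48)), "start at 0")
})
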