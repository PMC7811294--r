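th_caf <- params_to_theta(caf_pars)

test_that("a fit started at the optimum stays there", {
  f <- cached("fit_caf_at_truth",
              glnfit(caf_noiseless, init = caf_pars,
                     control = glnfit_control(restarts = 1)))
  expect_s3_class(f, "glnfit")
  expect_lt(f$objective, 1e-10)
  expect_equal(coef(f), th_caf, tolerance = 1e-3)
  expect_true(f$converged)
})

test_that("pinned parameters are returned bit-identical to the input", {
  init <- th_caf * 1.2
  f <- glnfit(caf_noiseless, init = init, free = c("r1", "d1"),
              control = glnfit_control(maxit = 400, restarts = 0))
  pinned <- setdiff(names(init), c("r1", "d1"))
  expect_identical(coef(f)[pinned], init[pinned])
  expect_identical(f$free, c("r1", "d1"))
})

test_that("fitting is deterministic given data, init and options", {
  init <- th_caf * 1.5
  ctl <- glnfit_control(maxit = 300, restarts = 0)
  f1 <- glnfit(caf_noiseless, init = init, free = c("r1", "d1", "k1"),
               control = ctl)
  f2 <- glnfit(caf_noiseless, init = init, free = c("r1", "d1", "k1"),
               control = ctl)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$objective, f2$objective)
})

test_that("sensitive parameters are recovered from a x2-perturbed start", {
  # all 12 parameters free; the sensitive ones must come back
  f <- cached("fit_caf_x2",
              glnfit(caf_noiseless, init = th_caf * 2,
                     control = glnfit_control(maxit = 4000, restarts = 6)))
  rel <- abs(coef(f)[c("r1", "d1", "k1")] / th_caf[c("r1", "d1", "k1")] - 1)
  expect_lt(max(rel), 0.05)
  # fitted objective far below the objective at the perturbed start
  expect_lt(f$objective, 1e-6 * f$value_at_init)
})

test_that("free-mask validation and accessors behave", {
  expect_error(glnfit(caf_noiseless, init = caf_pars, free = "nope"),
               "unknown free parameter")
  init0 <- th_caf
  init0["r2"] <- 0
  expect_error(glnfit(caf_noiseless, init = init0, free = c("r1", "r2")),
               "strictly positive")
  # default free mask drops the inert K2 when r2 = 0
  dcc <- generate_data(design_spec("CC", noise = 0), cc_pars)
  expect_false("K2" %in% glnamm:::default_free(params_to_theta(cc_pars), "CC"))
  expect_false("r2" %in% glnamm:::default_free(params_to_theta(cc_pars), "CC"))
  # evaluate-only fit (all pinned)
  f0 <- glnfit(caf_noiseless, init = caf_pars, free = character())
  expect_identical(coef(f0), th_caf)
  expect_lt(f0$objective, 1e-12)

  f <- cached("fit_caf_at_truth",
              glnfit(caf_noiseless, init = caf_pars,
                     control = glnfit_control(restarts = 1)))
  res <- residuals(f)
  expect_length(res, nrow(caf_noiseless))
  expect_lt(max(abs(res)), 1e-5)
  fit_tab <- fitted(f)
  expect_named(fit_tab, c("scenario_id", "time_h", "stream", "value"))
  pr <- predict(f)
  expect_length(pr, 8)
  expect_s3_class(pr[[1]], "gln_traj")
  expect_output(print(summary(f)), "objective")
})

test_that("the coculture refit strategy frees only the two growth rates", {
  dco <- generate_data(design_spec("coculture", noise = 0), co_merged)
  init <- params_to_theta(co_merged)
  init["caf.r1"] <- init["caf.r1"] * 3
  init["cc.r1"] <- init["cc.r1"] * 0.5
  f <- glnfit(dco, init = init,
              control = glnfit_control(maxit = 500, restarts = 1))
  expect_identical(f$free, c("caf.r1", "cc.r1"))
  pinned <- setdiff(names(init), f$free)
  expect_identical(coef(f)[pinned], init[pinned])
  truth <- params_to_theta(co_merged)
  expect_equal(coef(f)[["caf.r1"]], truth[["caf.r1"]], tolerance = 0.02)
  expect_equal(coef(f)[["cc.r1"]], truth[["cc.r1"]], tolerance = 0.02)
})
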