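test_that("cancer cells on ammonium alone decline monotonically", {
  grid <- seq(0, 72, by = 4)
  out <- run_monoculture_suite("CC", gln_doses = numeric(),
                               nh4_doses = 25, obs_times = grid)
  cells <- out$summary$cells
  expect_true(all(diff(cells) < 0))
})

test_that("CAFs convert supplied glutamine nearly entirely to ammonium", {
  out <- run_monoculture_suite("CAF", gln_doses = 4, nh4_doses = numeric())
  s <- out$summary
  final <- s[s$time_h == 72, ]
  expect_gt(final$NH4_mM, final$Gln_mM)
  expect_lt(final$Gln_mM, 0.2 * 4)  # most of the 4 mM consumed
  # CAFs grow on glutamine
  expect_gt(final$cells, 8e4)
})

test_that("no dose and no basal production leaves the medium empty", {
  p <- caf_pars
  p["h"] <- 0
  out <- run_monoculture_suite("CAF", params = p, gln_doses = 0,
                               nh4_doses = numeric())
  expect_equal(out$summary$Gln_mM, rep(0, 4), tolerance = 1e-12)
  expect_equal(out$summary$NH4_mM, rep(0, 4), tolerance = 1e-12)
})

test_that("identical cell types seeded 1:1 stay at 50% composition", {
  p <- co_params(caf_pars, caf_pars)
  out <- run_coculture_suite(params = p, nh4_doses = 5, gln_dose = numeric())
  expect_equal(out$composition$pct_cc, rep(50, 4), tolerance = 1e-9)
})

test_that("the merged coculture holds composition near 1:1 at 5 mM NH4+", {
  out <- run_coculture_suite(variant = "coculture_merged", nh4_doses = 5,
                             gln_dose = numeric())
  expect_true(all(out$composition$pct_cc >= 40 & out$composition$pct_cc <= 60))
})

test_that("the stress factor accumulates and depresses the population", {
  st <- run_coculture_suite(variant = "coculture_stress", nh4_doses = 5,
                            gln_dose = numeric())
  tr <- st$trajectories[[1]]
  L <- tr$states[, "L"]
  expect_gt(L[3], 0)          # L(48) > 0
  expect_gt(L[4], L[3])       # L nondecreasing
  me <- run_coculture_suite(variant = "coculture_merged", nh4_doses = 5,
                            gln_dose = numeric())
  expect_lt(st$composition$cells_total[4], me$composition$cells_total[4])
})

test_that("renormalized fibroblasts accelerate the population decline", {
  rn <- run_renormalization_comparison(dose = 5)
  expect_lte(rn$delta$total_normalized[4], rn$delta$total_merged[4])
  expect_true(all(rn$delta$Gln_normalized <= rn$delta$Gln_merged + 1e-12))
  # if the CAFs already lack the conversion, both runs coincide
  p0 <- published_params("coculture_merged")
  p0$caf["k2"] <- 0
  rn0 <- run_renormalization_comparison(params = p0, dose = 5)
  expect_equal(rn0$delta$total_merged, rn0$delta$total_normalized,
               tolerance = 1e-10)
})

test_that("reports are deterministic, round-trippable, and valid when empty", {
  rn <- run_renormalization_comparison(dose = 5)
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  f1 <- write_report(list(renorm = rn["delta"]), d1, seed = 1)
  f2 <- write_report(list(renorm = rn["delta"]), d2, seed = 1)
  t1 <- file.path(d1, "renorm_delta.tsv")
  expect_true(file.exists(t1))
  expect_identical(readLines(t1), readLines(file.path(d2, "renorm_delta.tsv")))
  back <- read.delim(t1)
  expect_equal(back$total_merged, rn$delta$total_merged, tolerance = 1e-10)

  d3 <- file.path(tempdir(), "rep3")
  files <- write_report(list(), d3)
  expect_true(file.exists(file.path(d3, "run_info.txt")))
  empty <- write_report(list(nothing = data.frame(a = numeric(),
                                                  b = character())),
                        d3)
  expect_identical(readLines(file.path(d3, "nothing.tsv")), "a\tb")
})
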