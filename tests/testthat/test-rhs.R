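test_that("derivatives vanish without cells and respect hand-substituted rates", {
  # every term carries a factor X (or Y)
  d <- mono_rhs(c(A = 3, W = 7, R = 20, X = 0), caf_pars)
  expect_identical(unname(d), rep(0, 4))
  d <- co_rhs(c(A = 3, W = 7, R = 20, X = 0, Y = 0), co_merged)
  expect_identical(unname(d), rep(0, 5))

  # starved CAF culture: NH4+ builds up at h*X, energy drains at k3*R*X
  d <- mono_rhs(c(A = 0, W = 0, R = 20, X = 8e4), caf_pars)
  expect_equal(unname(d["A"]), 0)
  expect_equal(unname(d["W"]), 1.28e-3, tolerance = 1e-12)
  expect_equal(unname(d["R"]), -0.336, tolerance = 1e-12)
})

test_that("A + W is conserved when yields are 1 and basal production 0", {
  p <- caf_pars
  p["c1"] <- 1; p["c2"] <- 1; p["h"] <- 0
  set.seed(11)
  for (i in 1:25) {
    s <- c(A = runif(1, 0, 5), W = runif(1, 0, 25), R = runif(1, 0, 20),
           X = runif(1, 0, 2e5))
    d <- mono_rhs(s, p)
    expect_equal(unname(d["A"] + d["W"]), 0, tolerance = 1e-18)
  }
})

test_that("coculture RHS reduces to the monoculture RHS when one type is absent", {
  set.seed(12)
  for (i in 1:10) {
    s <- c(A = runif(1, 0, 4), W = runif(1, 0, 25), R = runif(1, 0, 20),
           X = runif(1, 1, 2e5))
    dm <- mono_rhs(s, structure(co_merged$caf, class = "mono_params"))
    dc <- co_rhs(c(s, Y = 0), co_merged)
    expect_equal(dc[c("A", "W", "R", "X")], dm, tolerance = 1e-15)
    # and symmetrically for the cancer cells
    dm2 <- mono_rhs(s, structure(co_merged$cc, class = "mono_params"))
    dc2 <- co_rhs(c(s[c("A", "W", "R")], X = 0, Y = unname(s["X"])), co_merged)
    expect_equal(unname(dc2[c("A", "W", "R", "Y")]), unname(dm2),
                 tolerance = 1e-15)
  }
})

test_that("stress factor is produced at g*X*Y and only acts through L", {
  d <- co_rhs(c(A = 0, W = 0, R = 20, X = 4e4, Y = 4e4, L = 0),
              co_stress, variant = "coculture_stress")
  expect_equal(unname(d["L"]), 1120, tolerance = 1e-12)
  # at L = 0 the stress growth equations equal the merged-model ones
  co_same_r <- co_params(structure(co_stress$caf, class = "mono_params"),
                         structure(co_stress$cc, class = "mono_params"))
  dm <- co_rhs(c(A = 2, W = 5, R = 20, X = 4e4, Y = 4e4), co_same_r)
  ds <- co_rhs(c(A = 2, W = 5, R = 20, X = 4e4, Y = 4e4, L = 0),
               co_stress, variant = "coculture_stress")
  expect_equal(ds[c("X", "Y")], dm[c("X", "Y")], tolerance = 1e-15)
  # with L > 0 both types lose an extra m*L^2 per capita
  L <- 5e4
  dsL <- co_rhs(c(A = 2, W = 5, R = 20, X = 4e4, Y = 4e4, L = L),
                co_stress, variant = "coculture_stress")
  expect_equal(unname(dsL["X"] - ds["X"]), -co_stress$m * L^2 * 4e4,
               tolerance = 1e-9)
})

test_that("normalized variant removes only the CAF recycling terms", {
  s <- c(A = 1, W = 10, R = 20, X = 4e4, Y = 4e4)
  dn <- co_rhs(s, co_merged, variant = "coculture_normalized")
  pz <- co_merged
  pz$caf["k2"] <- 0
  dz <- co_rhs(s, pz, variant = "coculture_merged")
  expect_equal(dn, dz, tolerance = 1e-15)
})

test_that("each state derivative is nonnegative on its zero boundary", {
  set.seed(13)
  for (i in 1:40) {
    base <- c(A = runif(1, 0, 4), W = runif(1, 0, 25), R = runif(1, 0, 20),
              X = runif(1, 0, 2e5))
    for (comp in names(base)) {
      s <- base
      s[comp] <- 0
      d <- mono_rhs(s, caf_pars)
      expect_gte(unname(d[comp]), 0)
    }
    co_s <- c(base, Y = runif(1, 0, 2e5), L = runif(1, 0, 1e5))
    for (comp in names(co_s)) {
      s <- co_s
      s[comp] <- 0
      d <- co_rhs(s, co_stress, variant = "coculture_stress")
      expect_gte(unname(d[comp]), 0)
    }
    # R never increases, L never decreases
    expect_lte(unname(mono_rhs(base, caf_pars)["R"]), 0)
    expect_lte(unname(co_rhs(co_s, co_stress, "coculture_stress")["R"]), 0)
    expect_gte(unname(co_rhs(co_s, co_stress, "coculture_stress")["L"]), 0)
  }
})

test_that("invalid states and configurations are rejected", {
  expect_error(mono_rhs(c(A = -1, W = 0, R = 20, X = 1e4), caf_pars),
               "nonnegative")
  expect_error(mono_rhs(c(A = 1, W = 0, R = 20), caf_pars), "named components")
  # stress variant without an L state, or without the stress constants
  expect_error(co_rhs(c(A = 1, W = 0, R = 20, X = 1, Y = 1), co_stress,
                      variant = "coculture_stress"),
               "named components")
  expect_error(co_rhs(c(A = 1, W = 0, R = 20, X = 1, Y = 1, L = 0), co_merged,
                      variant = "coculture_stress"),
               "stress variant needs g")
})
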