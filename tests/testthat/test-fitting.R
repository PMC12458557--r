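test_that("dual-decay fit inverts its forward model across the parameter grid", {
  times <- seq(0, 0.144, length.out = 9)
  for (r in c(1, 7, 30, 100)) {
    for (ss in c(0, 0.3, 0.6, 0.9)) {
      fm <- dualDecayForward(times, 1, r, ss)
      fit <- fitDualDecay(times, fm$plus, fm$minus)
      expect_true(fit@converged)
      expect_equal(fit@r, r, tolerance = 1e-6)
      expect_equal(fit@ss, ss, tolerance = 1e-6)
      expect_equal(fit@si0, 1, tolerance = 1e-6)
    }
  }
})

test_that("dual fit with zero steady state reduces to the monoexponential fit", {
  times <- seq(0, 0.3, length.out = 8)
  fm <- dualDecayForward(times, 1, 12, 0)
  dual <- fitDualDecay(times, fm$plus, fm$minus)
  mono <- fitMonoexp(times, fm$plus)
  expect_equal(dual@r, mono@r, tolerance = 1e-8)
  expect_lt(dual@ss, 1e-6)
  ## fitted curves pass through +/- SI0 at t = 0
  expect_equal(dual@si0, fm$plus[1L], tolerance = 1e-8)
})

test_that("dual fit restores signs of magnitude-valued -Z input", {
  times <- seq(0, 0.144, length.out = 9)
  fm <- dualDecayForward(times, 1, 15, 0.3)
  fit <- fitDualDecay(times, fm$plus, abs(fm$minus))
  expect_equal(fit@r, 15, tolerance = 1e-6)
  expect_equal(fit@ss, 0.3, tolerance = 1e-6)
})

test_that("dual fit input validation", {
  expect_error(fitDualDecay(c(0, 0.1), c(1, 0.5), c(-1, 0)), "3 time points")
  expect_error(fitDualDecay(c(0.1, 0.2, 0.3), rep(1, 3), rep(-1, 3)),
               "include 0")
  expect_error(fitDualDecay(c(0, 0.1, 0.2), c(1, NA, 0.5), rep(-1, 3)),
               "finite")
})

test_that("monotone identifiability: larger true rate gives larger fitted rate", {
  times <- seq(0, 0.144, length.out = 9)
  rTrue <- c(2, 5, 10, 20, 40, 80)
  rHat <- vapply(rTrue, function(r) {
    fm <- dualDecayForward(times, 1, r, 0.2)
    fitDualDecay(times, fm$plus, fm$minus)@r
  }, numeric(1))
  expect_true(all(diff(rHat) > 0))
})

test_that("dual fit is robust at SNR 50 across seeded replicates", {
  times <- seq(0, 0.144, length.out = 9)
  set.seed(42)
  relErr <- replicate(100, {
    fm <- dualDecayForward(times, 1, 20, 0.1)
    fit <- fitDualDecay(times, fm$plus + rnorm(9, 0, 0.02),
                        fm$minus + rnorm(9, 0, 0.02))
    abs(fit@r - 20) / 20
  })
  expect_lt(stats::median(relErr), 0.05)
})

test_that("monoexponential fit recovers the CW time grid example", {
  times <- c(0, 18, 36, 54) * 1e-3
  fit <- fitMonoexp(times, exp(-times / 0.040))
  expect_equal(1 / fit@r, 0.040, tolerance = 1e-6)
  ## constant signal: rate pinned at the lower bound 0
  flat <- fitMonoexp(times, rep(2, 4))
  expect_lt(flat@r, 1e-6)
  ## noise-only non-positive input is flagged, not fitted
  bad <- fitMonoexp(times, c(-0.1, -0.05, -0.2, -0.01))
  expect_false(bad@converged)
  expect_error(fitMonoexp(c(0, 1), c(1, 0)), "3 time points")
})

test_that("B1 nutation fit recovers frequencies on the hard-pulse grid", {
  durs <- seq(0, 1e-3, by = 0.125e-3)
  expect_equal(fitB1Nutation(durs, abs(cos(2 * pi * 620 * durs))), 620,
               tolerance = 1 / 620)
  expect_equal(fitB1Nutation(durs, abs(cos(2 * pi * 625 * durs))), 625,
               tolerance = 1 / 625)
  expect_error(fitB1Nutation(durs, rep(1, 9)), "no identifiable")
  expect_error(fitB1Nutation(durs[1:4], rep(1, 4)), "5 durations")
  expect_error(fitB1Nutation(c(0, 1e-4, 3e-4, 4e-4, 9e-4), rep(0.5, 5)),
               "uniform")
})

test_that("B1 fit matches Bloch-simulated nutation of a hard pulse", {
  sys <- waterSystem()
  durs <- seq(0, 1e-3, by = 0.125e-3)
  si <- vapply(durs, function(d) {
    if (d == 0) return(1)
    abs(utils::tail(propagate(sys, hardPulse(620, d)), 1)[, "MzB"])
  }, numeric(1))
  expect_equal(fitB1Nutation(durs, si), 620, tolerance = 1 / 620)
})

test_that("map fitting fills only the mask and excludes failed pixels", {
  times <- seq(0, 0.144, length.out = 5)
  nx <- 6L
  plus <- minus <- array(0, c(nx, nx, 5))
  fm <- dualDecayForward(times, 1, 1 / 0.05, 0.1)
  for (k in 1:5) {
    plus[, , k] <- fm$plus[k]
    minus[, , k] <- fm$minus[k]
  }
  mask <- matrix(FALSE, nx, nx)
  mask[2:5, 2:5] <- TRUE
  ## poison one masked pixel so its fit cannot converge
  plus[3, 3, ] <- 0
  minus[3, 3, ] <- 0
  maps <- fitMap(plus, minus, times, mask)
  expect_true(all(is.na(tMap(maps)[!mask])))
  expect_true(is.na(tMap(maps)[3, 3]))
  fitted <- tMap(maps)[mask & is.finite(tMap(maps))]
  expect_equal(fitted, rep(0.05, 15), tolerance = 1e-6)
  expect_equal(ssMap(maps)[2, 2], 0.1, tolerance = 1e-6)
  expect_error(fitMap(plus, NULL, times, mask), "seriesMinus")
  expect_error(fitMap(plus, minus, times[1:3], mask), "weightings")
  expect_error(fitMap(plus, minus, times, mask[1:3, 1:3]), "mask")
})

test_that("map units are seconds and convert to the reported milliseconds", {
  times <- seq(0, 0.144, length.out = 5)
  fm <- dualDecayForward(times, 1, 1 / 0.0591, 0.15)
  plus <- array(rep(fm$plus, each = 4), c(2, 2, 5))
  minus <- array(rep(fm$minus, each = 4), c(2, 2, 5))
  maps <- fitMap(plus, minus, times, matrix(TRUE, 2, 2))
  expect_equal(tMap(maps)[1, 1], 0.0591, tolerance = 1e-6)
  expect_equal(tMap(maps)[1, 1] * 1e3, 59.1, tolerance = 1e-3)
})
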