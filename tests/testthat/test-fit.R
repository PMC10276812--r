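noiselessCurve <- function(vHalf, slope, amplitude = 1) {
  v <- vGrid()
  availabilityCurve(v, boltzmannAvailability(
    v, boltzmannParams(vHalf, slope, amplitude)))
}

test_that("Boltzmann fit recovers generating parameters from clean data", {
  cases <- list(c(-75.2, 7.9, 1), c(-82.6, 8.4, 1), c(-60, 5, 0.55))
  for (cs in cases) {
    fit <- fitBoltzmann(noiselessCurve(cs[1], cs[2], cs[3]))
    expect_true(isConverged(fit))
    expect_equal(vHalf(fit), cs[1], tolerance = 1e-6)
    expect_equal(slopeFactor(fit), cs[2], tolerance = 1e-6)
    expect_equal(amplitude(fit), cs[3], tolerance = 1e-6)
  }
})

test_that("degenerate availability input is flagged, not fitted", {
  v <- vGrid()
  flat <- availabilityCurve(v, rep(1, length(v)))
  fit <- fitBoltzmann(flat)
  expect_false(isConverged(fit))
  expect_match(fit@message, "degenerate")
})

test_that("fit objective is non-increasing across optimizer iterations", {
  set.seed(42)
  v <- vGrid()
  y <- pmax(0, boltzmannAvailability(v, ctrlParams()) +
              rnorm(length(v), 0, 0.03))
  fit <- fitBoltzmann(availabilityCurve(v, y))
  expect_true(isConverged(fit))
  expect_gt(length(fit@trace), 1)
  expect_true(all(diff(fit@trace) <= 1e-12))

  d <- c(300, 1000, 3000, 10000, 30000)
  set.seed(43)
  yy <- pmin(1, pmax(0, 1 / (1 + 1820 / d) + rnorm(5, 0, 0.03)))
  hf <- fitHill(doseResponseCurve(d, yy))
  expect_true(all(diff(hf@trace) <= 1e-12))
})

test_that("Hill fit recovers IC50 and Hill coefficient from clean data", {
  d <- c(300, 1000, 3000, 10000, 30000)
  for (cs in list(c(1820, 1), c(4280, 1), c(2500, 1.6))) {
    y <- 1 / (1 + (cs[1] / d)^cs[2])
    fit <- fitHill(doseResponseCurve(d, y))
    expect_true(isConverged(fit))
    expect_equal(ic50(fit), cs[1], tolerance = 1e-6)
    expect_equal(hillCoef(fit), cs[2], tolerance = 1e-6)
  }
  ## half-maximal inhibition at D = IC50 by definition
  y <- 1 / (1 + 1820 / d)
  expect_equal(1 / (1 + (1820 / 1820)^1), 0.5)
  ## fixing the Hill coefficient still recovers IC50
  fit1 <- fitHill(doseResponseCurve(d, y), fixHillN = 1)
  expect_equal(ic50(fit1), 1820, tolerance = 1e-6)
  expect_identical(hillCoef(fit1), 1)
})

test_that("all-zero inhibition is flagged as non-converged", {
  d <- c(300, 1000, 3000, 10000, 30000)
  fit <- fitHill(doseResponseCurve(d, rep(0, 5)))
  expect_false(isConverged(fit))
  expect_match(fit@message, "degenerate")
  expect_error(fitHill(doseResponseCurve(c(300, 1000), c(0.2, 0.4))),
               "at least 3")
})
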