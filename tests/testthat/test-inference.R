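test_that("drift correction is exact subtraction", {
  ## the study's reported means: -10.9 mV with drug, -3.6 mV drift
  expect_equal(driftCorrectedShift(-10.9, -3.6), -7.3, tolerance = 1e-12)
  expect_identical(driftCorrectedShift(-5.1, 0), -5.1)
  expect_identical(driftCorrectedShift(-3.6, -3.6), 0)
  expect_error(driftCorrectedShift(NA, 0), "finite")
})

test_that("resting-state Kd follows one-site occupancy", {
  expect_equal(inferKdRest(0.5, 300), 300)      # half block at Kd
  expect_identical(inferKdRest(1, 300), Inf)    # no resting binding
  expect_equal(inferKdRest(0.75, 300), 900)     # hand evaluation
  expect_error(inferKdRest(0, 300), "\\(0, 1\\]")
  expect_error(inferKdRest(-0.1, 300), "\\(0, 1\\]")
})

test_that("inactivated-state Kd inverts the shift equation", {
  ## zero shift: equal affinities
  expect_equal(inferKdInact(0, 7.9, 300, 360), 360, tolerance = 1e-12)
  ## inverse of the worked shift example: -7.9*ln(7) back to 50 nM
  ki <- inferKdInact(-15.37, 7.9, 300, Inf)
  expect_lt(abs(ki - 50), 0.1)
  ## exact round trip with the forward model
  for (kr in c(180, 360, Inf)) for (kiTrue in c(25, 50, 120)) {
    m <- stateBindingModel(300, kr, kiTrue, 7.9)
    back <- inferKdInact(coupledShift(m), 7.9, 300, kr)
    expect_equal(back, kiTrue, tolerance = 1e-9)
  }
  ## a depolarizing shift inconsistent with inactivated binding
  expect_error(inferKdInact(5, 7.9, 300, Inf),
               class = "statenav_no_binding")
})

test_that("end-to-end analysis inverts the generating model", {
  g <- genPairedAvailability(defaultModel(), ctrlParams(),
                             noise = noiseSpec(0, 1))
  res <- analyzeStateDependence(g$control, g$drug, g$restingBlock)
  expect_equal(kdInact(res), 50, tolerance = 1e-3)
  expect_equal(kdRest(res), 360, tolerance = 1e-3)
  expect_equal(res@rawShift, coupledShift(defaultModel()),
               tolerance = 1e-6)
  ## inference inverts generation across a (Kr, Ki, D) grid
  for (kr in c(180, 360, Inf)) for (ki in c(25, 100)) {
    m <- stateBindingModel(300, kr, ki, 7.9)
    g <- genPairedAvailability(m, ctrlParams(), noise = noiseSpec(0, 1))
    res <- analyzeStateDependence(g$control, g$drug, g$restingBlock)
    expect_equal(kdInact(res), ki, tolerance = 1e-3)
  }
})

test_that("identical curves with no block give the no-binding sentinels", {
  g <- genPairedAvailability(stateBindingModel(0, Inf, 50, 7.9),
                             ctrlParams(), noise = noiseSpec(0, 1))
  res <- analyzeStateDependence(g$control, g$drug, restingBlock = 1)
  expect_identical(res@correctedShift, 0)
  expect_identical(kdRest(res), Inf)
  expect_identical(kdInact(res), Inf)
})

test_that("stage failures are annotated with the failing stage", {
  v <- vGrid()
  flat <- availabilityCurve(v, rep(1, length(v)))
  g <- genPairedAvailability(defaultModel(), ctrlParams(),
                             noise = noiseSpec(0, 1))
  expect_error(analyzeStateDependence(flat, g$drug, g$restingBlock),
               "stage 'fit_control'")
  expect_error(analyzeStateDependence(g$control, g$drug, -1),
               "stage 'infer_kd_rest'")
})

test_that("recovered Ki is unbiased in the noiseless limit and its spread grows with noise", {
  recover <- function(sd, seeds) {
    vapply(seeds, function(s) {
      g <- genPairedAvailability(defaultModel(), ctrlParams(),
                                 noise = noiseSpec(sd, s))
      tryCatch(kdInact(analyzeStateDependence(g$control, g$drug,
                                              g$restingBlock)),
               error = function(e) NA_real_)
    }, numeric(1))
  }
  ## median recovery within 10% of truth at the default noise level
  ki02 <- recover(0.02, 1:200)
  expect_lt(abs(median(ki02, na.rm = TRUE) - 50) / 50, 0.10)
  ## bias vanishes and spread shrinks as noise goes to zero
  ki0 <- recover(0, 1:5)
  ki01 <- recover(0.01, 1:60)
  ki03 <- recover(0.03, 1:60)
  expect_lt(max(abs(ki0 - 50)), 0.01)
  expect_lt(stats::IQR(ki01, na.rm = TRUE),
            stats::IQR(ki03, na.rm = TRUE))
})

test_that("per-cell shifts are averaged, then aggregated", {
  expect_equal(averageShift(c(-10, -8, -6)), -8)
  expect_error(averageShift(numeric()), "non-empty")
  cohort <- genPairedCohort(defaultModel(), ctrlParams(),
                            noise = noiseSpec(0, 7), nCells = 4,
                            cellVHalfSd = 2)
  shifts <- vapply(cohort, function(cell) {
    fc <- fitBoltzmann(cell$control)
    fd <- fitBoltzmann(cell$drug)
    vHalf(fd) - vHalf(fc)
  }, numeric(1))
  ## every cell's noiseless shift equals the model prediction even
  ## though the cells have different midpoints
  expect_equal(unname(averageShift(shifts)),
               coupledShift(defaultModel()), tolerance = 1e-5)
})
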