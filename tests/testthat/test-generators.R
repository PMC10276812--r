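test_that("noiseless generators reproduce the analytic curves exactly", {
  g <- genAvailability(ctrlParams(), vGrid(), noiseSpec(0, 1))
  expect_identical(g@availability,
                   boltzmannAvailability(vGrid(), ctrlParams()))
  d <- genDoseResponse(1820, 1, noise = noiseSpec(0, 1))
  expect_identical(d@inhibition, 1 / (1 + 1820 / d@conc))
  ## half inhibition exactly at the IC50
  d2 <- genDoseResponse(1820, 1, concs = c(500, 1820, 5000, 20000, 50000),
                        noise = noiseSpec(0, 1))
  expect_equal(d2@inhibition[2], 0.5)
  ## inhibition strictly increasing on the assay grid
  expect_true(all(diff(d@inhibition) > 0))
  expect_error(genAvailability(ctrlParams(), numeric(), noiseSpec(0, 1)),
               "non-empty")
})

test_that("generators are deterministic under a fixed seed", {
  a1 <- genAvailability(ctrlParams(), vGrid(), noiseSpec(0.02, 11))
  a2 <- genAvailability(ctrlParams(), vGrid(), noiseSpec(0.02, 11))
  expect_identical(a1@availability, a2@availability)
  ## changing only the seed changes only the noise
  a3 <- genAvailability(ctrlParams(), vGrid(), noiseSpec(0.02, 12))
  expect_false(identical(a1@availability, a3@availability))
  expect_identical(a1@voltage, a3@voltage)
  ## distinct substreams give distinct noise
  a4 <- genAvailability(ctrlParams(), vGrid(), noiseSpec(0.02, 11),
                        stream = 1L)
  expect_false(identical(a1@availability, a4@availability))
  ## generator calls do not disturb the caller RNG state
  set.seed(99); before <- rnorm(1)
  set.seed(99)
  invisible(genAvailability(ctrlParams(), vGrid(), noiseSpec(0.02, 5)))
  expect_identical(rnorm(1), before)
})

test_that("noise is additive, zero-mean Gaussian on normalized current", {
  v <- rep(-75.2, 1000)
  g <- genAvailability(ctrlParams(), v, noiseSpec(0.02, 21))
  expect_lt(abs(mean(g@availability) - 0.5), 0.002)
  expect_lt(abs(sd(g@availability) - 0.02), 0.004)
  expect_true(all(g@availability >= 0))
})

test_that("paired generator applies the shift and resting block", {
  ## no drug: identical noiseless curves
  g0 <- genPairedAvailability(stateBindingModel(0, 360, 50, 7.9),
                              ctrlParams(), noise = noiseSpec(0, 1))
  expect_identical(g0$control@availability, g0$drug@availability)
  expect_identical(g0$restingBlock, 1)
  ## Ki = 50, Kr = Inf at 300 nM: drug midpoint -75.2 - 7.9 ln 7
  g <- genPairedAvailability(stateBindingModel(300, Inf, 50, 7.9),
                             ctrlParams(), noise = noiseSpec(0, 1))
  fit <- fitBoltzmann(g$drug)
  expect_equal(vHalf(fit), -90.57, tolerance = 1e-3)
  expect_identical(g$restingBlock, 1)
  ## finite Kr scales the drug curve by the resting block
  g2 <- genPairedAvailability(defaultModel(), ctrlParams(),
                              noise = noiseSpec(0, 1))
  expect_equal(g2$restingBlock, 1 / (1 + 300 / 360))
  fit2 <- fitBoltzmann(g2$drug)
  expect_equal(amplitude(fit2), g2$restingBlock, tolerance = 1e-6)
})

test_that("kinetic dataset wraps the simulator and shows the drug signature", {
  sch <- buildScheme()
  ds <- genKineticDataset(sch, drugConc = 0, noise = noiseSpec(0, 1),
                          recoveryTimes = c(1, 2, 5, 10, 20, 50, 100,
                                            300, 1000, 3000))
  ## zero noise reproduces the simulator output exactly at a spot check
  occ <- steadyState(sch, -100, 0)
  occ <- propagateOccupancy(occ, rateMatrix(sch, -40, 0), 300)
  occ <- propagateOccupancy(occ, rateMatrix(sch, -100, 0), 10)
  expect_identical(ds$recovery$availability[4], availabilityOf(occ, sch))
  ## drug-free fast recovery matches the calibrated 2-ms time constant:
  ## fit a single exponential to the early recovery phase
  early <- ds$recovery[ds$recovery$time_ms <= 10, ]
  fit <- minpack.lm::nls.lm(
    par = c(aInf = 0.95, amp = 0.9, tau = 1),
    fn = function(p) early$availability -
      (p[1] - p[2] * exp(-early$time_ms / p[3])))
  expect_lt(abs(fit$par[["tau"]] - 2) / 2, 0.05)
  ## entry into slowly-recovering states at 20 ms: drug >> drug-free
  dsD <- genKineticDataset(sch, drugConc = 300, noise = noiseSpec(0, 1))
  ds0 <- genKineticDataset(sch, drugConc = 0, noise = noiseSpec(0, 1))
  e20 <- function(x) x$entry$slow_fraction[x$entry$duration_ms == 20]
  expect_lt(e20(ds0), 0.05)
  expect_gt(e20(dsD), 0.15)
  expect_gt(e20(dsD), 3 * e20(ds0))
})

test_that("structural fixtures carry their planted geometry", {
  fx <- genStructureFixtures()
  hb <- detectHbonds(fx$hbondTriad, "LIG")
  expect_equal(nrow(hb), 1)
  expect_equal(hb$dist, 2.8, tolerance = 1e-9)
  expect_equal(hb$angle, 170, tolerance = 1e-6)
  expect_equal(nrow(detectHbonds(fx$hbondDecoy, "LIG")), 0)
  st <- detectPiStacks(fx$ringsParallel, "LIG", paste0("C", 1:6))
  expect_equal(nrow(st), 1)
  expect_equal(st$centroidDist, 4, tolerance = 1e-9)
  ## planted rotation: per-atom displacement 2 sin(phi/2) * r_perp
  xyz <- as.matrix(atoms(fx$chain)[, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  rPerp <- sqrt((xyz[, 1] - ctr[1])^2 + (xyz[, 2] - ctr[2])^2)
  expect_equal(fx$planted$displacement,
               2 * sin(fx$planted$angle * pi / 360) * rPerp,
               tolerance = 1e-9)
  expect_equal(structureRmsd(fx$chain, fx$chainRotated),
               fx$planted$preRmsd, tolerance = 1e-9)
  sup <- superpose(fx$chain, fx$chainRotated)
  expect_lt(sup@rmsd, 1e-6)
})
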