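test_that("default calibrated scheme reproduces its availability targets", {
  sch <- buildScheme()
  ## midpoint by construction, despite the series slow-inactivated state
  expect_lt(abs(steadyState(sch, -75.2, 0)[["R"]] - 0.5), 1e-6)
  ## stationary availability matches the target Boltzmann across the grid
  for (V in c(-120, -100, -85, -70, -55)) {
    expect_lt(abs(steadyState(sch, V, 0)[["R"]] -
                  boltzmannAvailability(V, ctrlParams())), 1e-9)
  }
  ## relaxation-time calibration: 1/|Q_RR'|-style two-state tau at the
  ## two calibration voltages (R<->IF rates only)
  for (tt in list(c(-40, 3), c(-100, 2))) {
    Q <- rateMatrix(sch, tt[1], 0)
    expect_equal(1 / (Q["R", "IF"] + Q["IF", "R"]), tt[2],
                 tolerance = 1e-9)
  }
})

test_that("with no drug the dynamics reduce to the drug-free scheme", {
  sch <- buildScheme()
  ss <- steadyState(sch, -70, 0)
  expect_equal(sum(ss[c("RD", "IFD", "ISD")]), 0)
  ## zero on-rate: drug-bound states stay unreachable even at 300 nM
  sch0 <- buildScheme(onRate = 0)
  occ <- setNames(c(1, 0, 0, 0, 0, 0), sch0@states)
  occ <- propagateOccupancy(occ, rateMatrix(sch0, -80, 300), 60000)
  expect_equal(sum(occ[c("RD", "IFD", "ISD")]), 0, tolerance = 1e-12)
  expect_equal(occ[["R"]], boltzmannAvailability(-80, ctrlParams()),
               tolerance = 1e-6)
})

test_that("kinetic steady-state midpoint shift matches the analytic model", {
  sch <- buildScheme()
  m <- defaultModel()
  cur <- availabilityFromScheme(sch, vGrid(), drugConc = 300,
                                normalize = "max", init = "stationary")
  fit <- fitBoltzmann(cur)
  expect_true(isConverged(fit))
  expect_lt(abs((vHalf(fit) - (-75.2)) - coupledShift(m)), 0.1)
})

test_that("equilibrium block at -70 mV matches the two-state partition function", {
  sch <- buildScheme()
  ssF <- steadyState(sch, -70, 0)
  ssD <- steadyState(sch, -70, 300)
  U <- exp((-70 + 75.2) / 7.9)
  analytic <- (1 + U) / (1 + 300 / 360 + U * (1 + 300 / 50))
  rel <- availabilityOf(ssD, sch) / availabilityOf(ssF, sch)
  expect_equal(rel, analytic, tolerance = 1e-9)
  ## full equilibration blocks more deeply (~0.19) than the two-minute
  ## application (~0.29): the two-minute figure is pre-steady-state
  expect_lt(rel, 0.2)
})

test_that("detailed balance holds for the built scheme and is enforced", {
  sch <- buildScheme()
  db <- checkDetailedBalance(sch, v = c(-120, -75, -40),
                             drugConc = c(0, 30, 300))
  expect_lt(db$maxError, 1e-8)
  ## an inconsistent override is rejected with a cycle/edge diagnostic
  expect_error(
    buildScheme(rateOverrides = list(
      "RD->IFD" = function(v, d) 0.2)),
    "detailed balance")
})

test_that("infeasible relaxation-time pairs are rejected", {
  ## recovery slower than depolarized inactivation at these voltages is
  ## not realizable with a single-barrier partition in (0, 1)
  expect_error(buildScheme(tauFast = 2, tauRec = 200), "relax")
})

test_that("random reversible schemes conserve probability and balance flux", {
  for (i in 1:20) {
    n <- sample(3:6, 1)
    sch <- randomReversibleScheme(n, seed = 1000 + i)
    db <- checkDetailedBalance(sch, v = -70, drugConc = 0)
    expect_lt(db$maxError, 1e-8)
    set.seed(2000 + i)
    occ <- runif(n); occ <- setNames(occ / sum(occ), sch@states)
    Q <- rateMatrix(sch, -70, 0)
    for (t in c(0.1, 5, 200)) {
      occT <- propagateOccupancy(occ, Q, t)
      expect_lt(abs(sum(occT) - 1), 1e-9)
      expect_true(all(occT >= -1e-12))
    }
  }
})

test_that("matrix-exponential propagation matches fine-step integration", {
  for (i in 1:10) {
    sch <- randomReversibleScheme(sample(3:5, 1), seed = 3000 + i)
    Q <- rateMatrix(sch, -70, 0)
    occ <- steadyState(sch, -70, 0)
    set.seed(4000 + i)
    occ0 <- runif(length(occ)); occ0 <- setNames(occ0 / sum(occ0),
                                                 names(occ))
    for (t in c(1, 20)) {
      expect_lt(max(abs(propagateOccupancy(occ0, Q, t) -
                        fineStepOccupancy(occ0, Q, t))), 1e-6)
    }
  }
})

test_that("invalid generators are rejected by the scheme class", {
  expect_error(kineticScheme(c("A", "B"), function(v, d)
    matrix(c(-1, 1, 2, -2), 2, 2, byrow = TRUE) * -1),
    "off-diagonal")
  expect_error(kineticScheme(c("A", "B"), function(v, d)
    matrix(c(-1, 2, 1, -1), 2, 2, byrow = TRUE)),
    "sum to zero")
})
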