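test_that("protocol validation catches bad epochs and measurement points", {
  expect_error(voltageProtocol(voltage = -40, duration = 0), "duration")
  expect_error(voltageProtocol(voltage = c(-100, -40),
                               duration = c(10, -5)), "duration")
  expect_error(voltageProtocol(voltage = -40, duration = 10,
                               measureEpoch = 2), "epoch index")
  expect_error(voltageProtocol(voltage = -40, duration = 10,
                               measureEpoch = 1, measureTime = 20),
               "within their epoch")
})

test_that("vanishing epoch duration leaves occupancy unchanged", {
  sch <- buildScheme()
  occ <- steadyState(sch, -100, 0)
  expect_identical(propagateOccupancy(occ, rateMatrix(sch, -40, 0), 0),
                   occ)
  prot <- voltageProtocol(voltage = c(-100, -40), duration = c(1, 1e-9))
  sim <- simulateProtocol(sch, prot)
  expect_lt(max(abs(sim@finalOccupancy - occ)), 1e-9)
})

test_that("two-state relaxation matches the closed form", {
  a <- 0.3; b <- 0.12   # ms^-1
  sch <- kineticScheme(c("R", "IF"), function(v, d) {
    Q <- matrix(c(-a, a, b, -b), 2, 2, byrow = TRUE,
                dimnames = list(c("R", "IF"), c("R", "IF")))
    Q
  })
  tau <- 1 / (a + b)
  analytic <- function(t) b / (a + b) + a / (a + b) * exp(-(a + b) * t)
  occ0 <- c(R = 1, IF = 0)
  Q <- rateMatrix(sch, -70, 0)
  for (t in c(tau, 5 * tau)) {
    expect_equal(propagateOccupancy(occ0, Q, t)[["R"]], analytic(t),
                 tolerance = 1e-10)
  }
})

test_that("simulated availability protocol reproduces the generating Boltzmann", {
  sch <- buildScheme()
  cur <- availabilityFromScheme(sch, vGrid(), prepulseDuration = 5000,
                                drugConc = 0)
  expect_lt(max(abs(cur@availability -
                    boltzmannAvailability(cur@voltage, ctrlParams()))),
            0.005)
})

test_that("non-finite rates abort the simulation with a diagnostic", {
  sch <- kineticScheme(c("A", "B"), function(v, d) {
    r <- if (v > -50) Inf else 0.1
    matrix(c(-r, r, 0.1, -0.1), 2, 2, byrow = TRUE)
  })
  prot <- voltageProtocol(voltage = c(-100, -40), duration = c(1, 1))
  expect_error(simulateProtocol(sch, prot), "non-finite rates")
})

test_that("readouts respect the conducting-state set", {
  schNo <- buildScheme(drugBoundConducts = FALSE)
  schYes <- buildScheme(drugBoundConducts = TRUE)
  ssNo <- steadyState(schNo, -120, 300)
  expect_equal(availabilityOf(ssNo, schNo), ssNo[["R"]])
  expect_equal(availabilityOf(ssNo, schYes), ssNo[["R"]] + ssNo[["RD"]])
})

test_that("slowly-recovering fraction behaves across conditioning and drug", {
  sch <- buildScheme()
  expect_error(slowlyRecoveringFraction(sch, 20, criterionTime = 0),
               "criterionTime")
  ## no conditioning: the baseline unavailable fraction at holding
  base <- slowlyRecoveringFraction(sch, 0, drugConc = 0)
  expect_equal(base, 1 - boltzmannAvailability(-100, ctrlParams()),
               tolerance = 1e-6)
  ## drug-free 20-ms conditioning: almost no entry into slow states
  expect_lt(slowlyRecoveringFraction(sch, 20, drugConc = 0), 0.05)
  ## 300 nM drug: substantial slowly-recovering fraction at 20 ms
  expect_gt(slowlyRecoveringFraction(sch, 20, drugConc = 300), 0.15)
})
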