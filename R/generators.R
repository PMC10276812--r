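## Seeded synthetic-data generators. Every input the analysis chain
## consumes can be produced here: Boltzmann-shaped availability with
## additive Gaussian noise, coupled-equilibrium control/drug pairs,
## Hill-shaped dose-inhibition data, kinetic recovery/entry time
## courses, and toy atomic-coordinate fixtures with planted geometry.
## A single integer seed expands deterministically into per-curve
## substreams: the same seed and parameters give bit-identical output,
## and changing only the seed changes only the noise.

#' Construct a noise specification
#'
#' @param sd standard deviation of additive Gaussian noise on
#'   normalized current (default 0.02, roughly the scatter of
#'   patch-clamp availability points).
#' @param seed integer seed.
#' @return a [NoiseSpec-class].
#' @export
noiseSpec <- function(sd = 0.02, seed = 1L) {
  new("NoiseSpec", sd = as.numeric(sd), seed = as.integer(seed))
}

## deterministic substream: derive a 31-bit seed from (seed, stream)
## and evaluate `expr` under it without disturbing the caller's RNG
.substreamSeed <- function(seed, stream) {
  as.integer(((as.numeric(seed) %% 2147483647) * 69069 +
              1000003 * (stream %% 10007)) %% 2147483647)
}

.withSubstream <- function(seed, stream, expr) {
  hasSeed <- exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE)
  old <- if (hasSeed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (hasSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(.substreamSeed(seed, stream))
  expr
}

#' Generate a synthetic availability curve
#'
#' Boltzmann availability evaluated on a voltage grid plus additive
#' Gaussian noise, clipped below at 0. With `sd = 0` the output equals
#' [boltzmannAvailability()] pointwise.
#'
#' @param params generating [BoltzmannParams-class].
#' @param voltages prepulse voltage grid (mV), non-empty.
#' @param noise a [NoiseSpec-class].
#' @param stream integer substream index (distinct curves from one
#'   seed).
#' @param drugConc,label,prepulseDuration metadata stored on the curve.
#' @return an [AvailabilityCurve-class].
#' @export
genAvailability <- function(params, voltages = seq(-130, -20, by = 5),
                            noise = noiseSpec(), stream = 0L,
                            drugConc = 0, label = "synthetic",
                            prepulseDuration = 5000) {
  stopifnot(is(params, "BoltzmannParams"), is(noise, "NoiseSpec"))
  validObject(params); validObject(noise)
  if (!length(voltages)) stop("voltage grid must be non-empty")
  h <- boltzmannAvailability(voltages, params)
  if (noise@sd > 0) {
    eps <- .withSubstream(noise@seed, stream,
                          rnorm(length(voltages), 0, noise@sd))
    h <- pmax(0, h + eps)
  }
  availabilityCurve(voltages, h, prepulseDuration = prepulseDuration,
                    drugConc = drugConc, label = label)
}

#' Generate a paired control/drug availability dataset
#'
#' Under the coupled-equilibrium model the drug curve is the control
#' Boltzmann shifted by [coupledShift()] and scaled by the resting
#' block \eqn{1/(1 + D/K_r)}; the resting block is returned alongside
#' for the inference chain. Noise is applied independently to the two
#' curves (substreams `stream` and `stream + 1`).
#'
#' @param model a [StateBindingModel-class].
#' @param control control-curve [BoltzmannParams-class]; its slope
#'   should match `model@slope`.
#' @param voltages prepulse voltage grid (mV).
#' @param noise a [NoiseSpec-class].
#' @param stream integer substream index.
#' @return list with elements `control` and `drug`
#'   ([AvailabilityCurve-class]) and `restingBlock` (numeric).
#' @export
genPairedAvailability <- function(model,
                                  control = boltzmannParams(-75.2, 7.9),
                                  voltages = seq(-130, -20, by = 5),
                                  noise = noiseSpec(), stream = 0L) {
  stopifnot(is(model, "StateBindingModel"))
  validObject(model)
  block <- 1 / (1 + model@drugConc / model@kdRest)
  drugPars <- boltzmannParams(control@vHalf + coupledShift(model),
                              control@slope,
                              control@amplitude * block)
  list(
    control = genAvailability(control, voltages, noise, stream,
                              drugConc = 0, label = "control"),
    drug = genAvailability(drugPars, voltages, noise, stream + 1L,
                           drugConc = model@drugConc, label = "drug"),
    restingBlock = block)
}

#' Generate a multi-cell cohort of paired availability curves
#'
#' Emulates cell-to-cell variability by jittering the control midpoint
#' across cells (Gaussian, `cellVHalfSd`); within each cell the drug
#' curve follows the same binding model. Shifts should then be averaged
#' per cell and across cells (see [averageShift()]).
#'
#' @inheritParams genPairedAvailability
#' @param nCells number of cells.
#' @param cellVHalfSd between-cell standard deviation of the control
#'   midpoint (mV, default 2).
#' @return list of per-cell pair lists as in [genPairedAvailability()].
#' @export
genPairedCohort <- function(model, control = boltzmannParams(-75.2, 7.9),
                            voltages = seq(-130, -20, by = 5),
                            noise = noiseSpec(), nCells = 6,
                            cellVHalfSd = 2) {
  jit <- .withSubstream(noise@seed, 9999L,
                        rnorm(nCells, 0, cellVHalfSd))
  lapply(seq_len(nCells), function(i) {
    ctrl <- boltzmannParams(control@vHalf + jit[i], control@slope,
                            control@amplitude)
    genPairedAvailability(model, ctrl, voltages, noise,
                          stream = 10L * i)
  })
}

#' Generate a synthetic dose-response curve
#'
#' Hill-shaped fractional inhibition
#' \eqn{1/(1 + (IC_{50}/D)^{n})} on a concentration grid, plus additive
#' Gaussian noise clipped to \[0, 1\].
#'
#' @param ic50 half-maximal inhibitory concentration (nM).
#' @param hillN Hill coefficient (default 1).
#' @param concs concentration grid (nM); default is the five-point
#'   log-spaced assay grid 0.3-30 uM.
#' @param noise a [NoiseSpec-class].
#' @param stream integer substream index.
#' @param label condition label.
#' @return a [DoseResponseCurve-class].
#' @export
genDoseResponse <- function(ic50, hillN = 1,
                            concs = c(300, 1000, 3000, 10000, 30000),
                            noise = noiseSpec(), stream = 0L,
                            label = "synthetic") {
  stopifnot(ic50 > 0, hillN > 0, all(concs > 0), is(noise, "NoiseSpec"))
  y <- 1 / (1 + (ic50 / concs)^hillN)
  if (noise@sd > 0) {
    eps <- .withSubstream(noise@seed, stream,
                          rnorm(length(concs), 0, noise@sd))
    y <- pmin(1, pmax(0, y + eps))
  }
  doseResponseCurve(concs, y, label = label)
}

#' Generate kinetic recovery and entry time-course tables
#'
#' Wraps [simulateProtocol()] over the two standard kinetic assays:
#' recovery from inactivation (conditioning step, then availability as
#' a function of the recovery interval at the recovery voltage) and
#' entry into slowly-recovering states (availability deficit after a
#' fixed recovery interval, as a function of conditioning duration).
#' With `noise@sd = 0` the tables reproduce the simulator output
#' exactly.
#'
#' @param scheme a [KineticScheme-class].
#' @param drugConc drug concentration (nM); the cell is equilibrated in
#'   drug at holding before each sweep.
#' @param noise a [NoiseSpec-class].
#' @param conditioningDurations conditioning durations for the entry
#'   table (ms).
#' @param recoveryTimes recovery intervals for the recovery table (ms);
#'   default 25 points log-spaced from 1 ms to 3 s.
#' @param conditioningVoltage conditioning voltage (mV).
#' @param holding holding/recovery voltage (mV).
#' @param recoveryConditioning conditioning duration used for the
#'   recovery table (ms, default 300).
#' @param criterionTime recovery interval defining "slowly recovering"
#'   in the entry table (ms, default 100).
#' @return list of data.frames: `recovery` (`time_ms`, `availability`)
#'   and `entry` (`duration_ms`, `slow_fraction`), each carrying
#'   `drug_conc`.
#' @export
genKineticDataset <- function(scheme, drugConc = 0, noise = noiseSpec(0, 1),
                              conditioningDurations =
                                c(1, 3, 10, 20, 50, 100, 300),
                              recoveryTimes =
                                exp(seq(log(1), log(3000),
                                        length.out = 25)),
                              conditioningVoltage = -40, holding = -100,
                              recoveryConditioning = 300,
                              criterionTime = 100) {
  stopifnot(is(scheme, "KineticScheme"), is(noise, "NoiseSpec"))
  occ0 <- steadyState(scheme, holding, drugConc)
  Qc <- rateMatrix(scheme, conditioningVoltage, drugConc)
  Qh <- rateMatrix(scheme, holding, drugConc)

  occC <- propagateOccupancy(occ0, Qc, recoveryConditioning)
  rec <- vapply(recoveryTimes, function(t)
    availabilityOf(propagateOccupancy(occC, Qh, t), scheme), numeric(1))
  ent <- vapply(conditioningDurations, function(dur) {
    occ <- if (dur > 0) propagateOccupancy(occ0, Qc, dur) else occ0
    1 - availabilityOf(propagateOccupancy(occ, Qh, criterionTime), scheme)
  }, numeric(1))

  if (noise@sd > 0) {
    rec <- pmax(0, rec + .withSubstream(noise@seed, 101L,
                  rnorm(length(rec), 0, noise@sd)))
    ent <- pmin(1, pmax(0, ent + .withSubstream(noise@seed, 102L,
                  rnorm(length(ent), 0, noise@sd))))
  }
  list(
    recovery = data.frame(time_ms = recoveryTimes, availability = rec,
                          drug_conc = drugConc),
    entry = data.frame(duration_ms = conditioningDurations,
                       slow_fraction = ent, drug_conc = drugConc))
}

## ---- structural fixtures ------------------------------------------------

.structureFromRows <- function(rows, source) {
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(chain = r[[1]], resno = as.integer(r[[2]]), resid = r[[3]],
               elety = r[[4]], elesy = r[[5]], x = r[[6]], y = r[[7]],
               z = r[[8]])))
  rownames(df) <- NULL
  new("Structure", atoms = df, source = source)
}

## regular planar hexagon of CC bonds (1.39 A) centered at `center`,
## lying in the plane spanned by `u`, `v` (orthonormal)
.hexRing <- function(center, u, v, chain, resno, resid, prefix = "C") {
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  lapply(seq_along(ang), function(i) {
    p <- center + 1.39 * (cos(ang[i]) * u + sin(ang[i]) * v)
    list(chain, resno, resid, paste0(prefix, i), "C", p[1], p[2], p[3])
  })
}

#' Generate toy structural fixtures with planted geometry
#'
#' Builds small [Structure-class] objects with exactly-known geometry
#' for testing the interaction and superposition operations:
#'
#' * `hbondTriad`: a serine C-beta/O-gamma donor and a ligand hydroxyl
#'   acceptor at 2.8 Angstrom donor-acceptor distance and a 170 degree
#'   donor angle (a clear hydrogen bond);
#' * `hbondDecoy`: the same arrangement stretched to 4.5 Angstrom
#'   (beyond the heavy-atom cutoff);
#' * `ringsParallel`: a phenylalanine ring and a parallel ligand ring
#'   at 4.0 Angstrom centroid distance (a clear pi-stack);
#' * `ringsPerpendicular`: the same rings with the ligand ring rotated
#'   90 degrees (fails the interplanar-angle criterion);
#' * `chain` / `chainRotated`: a 12-atom C-alpha chain and a copy
#'   rotated by `plantedAngle` degrees about the z axis through its
#'   centroid, with the exact per-atom displacements and pre-alignment
#'   RMSD returned in `planted`.
#'
#' @param plantedAngle rotation angle for the chain copy (degrees,
#'   default 20).
#' @param writeDir optional directory; if given, each fixture is also
#'   written as a minimal PDB file (synthetic coordinates, named
#'   `synthetic-<name>.pdb`).
#' @return named list of [Structure-class] objects plus `planted`, a
#'   list with the rotation matrix, per-atom displacements and
#'   pre-alignment RMSD of the chain pair.
#' @export
genStructureFixtures <- function(plantedAngle = 20, writeDir = NULL) {
  ## (a) hydrogen-bond triad: CB-OG ... O1(ligand), 2.8 A, 170 deg at OG
  theta <- (180 - 170) * pi / 180   # deviation from straight
  acc <- c(2.8 * cos(theta), 2.8 * sin(theta), 0)
  triad <- .structureFromRows(list(
    list("A", 10L, "SER", "CB", "C", -1.43, 0, 0),
    list("A", 10L, "SER", "OG", "O", 0, 0, 0),
    list("L", 900L, "LIG", "C1", "C", acc[1] + 1.4, acc[2], acc[3]),
    list("L", 900L, "LIG", "O1", "O", acc[1], acc[2], acc[3])),
    "fixture:hbond-triad")
  ## (d) decoy: same geometry at 4.5 A donor-acceptor distance
  acc2 <- c(4.5 * cos(theta), 4.5 * sin(theta), 0)
  decoy <- .structureFromRows(list(
    list("A", 10L, "SER", "CB", "C", -1.43, 0, 0),
    list("A", 10L, "SER", "OG", "O", 0, 0, 0),
    list("L", 900L, "LIG", "C1", "C", acc2[1] + 1.4, acc2[2], acc2[3]),
    list("L", 900L, "LIG", "O1", "O", acc2[1], acc2[2], acc2[3])),
    "fixture:hbond-decoy")

  ## (b) parallel rings 4.0 A apart along the ring normal (z)
  ex <- c(1, 0, 0); ey <- c(0, 1, 0); ez <- c(0, 0, 1)
  pheRing <- .hexRing(c(0, 0, 0), ex, ey, "A", 387L, "PHE", "C")
  ## PHE template atom names
  for (i in seq_along(pheRing))
    pheRing[[i]][[4]] <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")[i]
  ligRingPar <- .hexRing(c(0, 0, 4.0), ex, ey, "L", 900L, "LIG", "C")
  ringsParallel <- .structureFromRows(c(pheRing, ligRingPar),
                                      "fixture:rings-parallel")
  ligRingPerp <- .hexRing(c(0, 0, 4.0), ex, ez, "L", 900L, "LIG", "C")
  ringsPerpendicular <- .structureFromRows(c(pheRing, ligRingPerp),
                                           "fixture:rings-perpendicular")

  ## (c) 12-atom CA chain and a copy rotated about z through the centroid
  n <- 12L
  xyz <- cbind(x = seq(0, 3.8 * (n - 1), by = 3.8),
               y = 1.5 * sin(seq_len(n)), z = 0.8 * cos(seq_len(n)))
  chainRows <- lapply(seq_len(n), function(i)
    list("A", i, "ALA", "CA", "C", xyz[i, 1], xyz[i, 2], xyz[i, 3]))
  chain <- .structureFromRows(chainRows, "fixture:chain")
  phi <- plantedAngle * pi / 180
  R <- matrix(c(cos(phi), sin(phi), 0,
                -sin(phi), cos(phi), 0,
                0, 0, 1), 3, 3)
  ctr <- colMeans(xyz)
  rot <- sweep(sweep(xyz, 2, ctr) %*% R, 2, ctr, "+")
  chainRotRows <- lapply(seq_len(n), function(i)
    list("A", i, "ALA", "CA", "C", rot[i, 1], rot[i, 2], rot[i, 3]))
  chainRotated <- .structureFromRows(chainRotRows, "fixture:chain-rotated")
  disp <- sqrt(rowSums((rot - xyz)^2))
  ## closed form: |p' - p| = 2 sin(phi/2) * (distance to rotation axis)
  planted <- list(rotation = R, angle = plantedAngle,
                  displacement = disp,
                  preRmsd = sqrt(mean(disp^2)))

  out <- list(hbondTriad = triad, hbondDecoy = decoy,
              ringsParallel = ringsParallel,
              ringsPerpendicular = ringsPerpendicular,
              chain = chain, chainRotated = chainRotated,
              planted = planted)
  if (!is.null(writeDir)) {
    dir.create(writeDir, showWarnings = FALSE, recursive = TRUE)
    for (nm in setdiff(names(out), "planted"))
      writeStructure(out[[nm]],
                     file.path(writeDir,
                               paste0("synthetic-", nm, ".pdb")))
  }
  out
}
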