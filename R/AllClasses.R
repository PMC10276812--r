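## S4 classes for the gating/binding models, measured curves, fit results
## and structural annotation. Validity methods enforce the physical
## constraints (positive slope factors, probability vectors, proper
## rotations) so downstream code can assume them.

#' Boltzmann availability parameters
#'
#' Two-parameter sigmoid describing steady-state channel availability,
#' \eqn{h(V) = A / (1 + \exp((V - V_{1/2})/k))} with slope factor
#' \eqn{k > 0}, so availability decreases with depolarization.
#'
#' @slot vHalf midpoint voltage \eqn{V_{1/2}} (mV).
#' @slot slope slope factor \eqn{k} (mV, strictly positive).
#' @slot amplitude maximal availability (dimensionless, default 1).
#' @export
setClass("BoltzmannParams",
  representation(vHalf = "numeric", slope = "numeric", amplitude = "numeric"),
  prototype(amplitude = 1))

setValidity("BoltzmannParams", function(object) {
  msg <- character()
  ## vHalf may be NA (carried by flagged, non-converged fits)
  if (length(object@vHalf) != 1L || is.nan(object@vHalf) ||
      is.infinite(object@vHalf))
    msg <- c(msg, "'vHalf' must be a single number (NA allowed)")
  for (s in c("slope", "amplitude")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, sprintf("'%s' must be a single finite number", s))
  }
  if (length(object@slope) == 1L && is.finite(object@slope) &&
      object@slope <= 0)
    msg <- c(msg, "slope factor must be strictly positive")
  if (length(object@amplitude) == 1L && is.finite(object@amplitude) &&
      object@amplitude <= 0)
    msg <- c(msg, "amplitude must be strictly positive")
  if (length(msg)) msg else TRUE
})

#' Coupled-equilibrium (modulated-receptor) state-binding model
#'
#' A drug at concentration `drugConc` binds resting channels with
#' dissociation constant `kdRest` and inactivated channels with
#' `kdInact`. `kdRest` may be `Inf` (no resting-state binding).
#' `slope` is the Boltzmann slope factor shared with the drug-free
#' availability curve.
#'
#' @slot drugConc drug concentration (nM, >= 0).
#' @slot kdRest resting-state dissociation constant (nM, > 0, may be `Inf`).
#' @slot kdInact inactivated-state dissociation constant (nM, > 0).
#' @slot slope Boltzmann slope factor (mV, > 0).
#' @export
setClass("StateBindingModel",
  representation(drugConc = "numeric", kdRest = "numeric",
                 kdInact = "numeric", slope = "numeric"))

setValidity("StateBindingModel", function(object) {
  msg <- character()
  if (length(object@drugConc) != 1L || !is.finite(object@drugConc) ||
      object@drugConc < 0)
    msg <- c(msg, "drugConc must be a single number >= 0")
  if (length(object@kdRest) != 1L || is.na(object@kdRest) ||
      object@kdRest <= 0)
    msg <- c(msg, "kdRest must be > 0 (Inf allowed)")
  if (length(object@kdInact) != 1L || !is.finite(object@kdInact) ||
      object@kdInact <= 0)
    msg <- c(msg, "kdInact must be a single finite number > 0")
  if (length(object@slope) != 1L || !is.finite(object@slope) ||
      object@slope <= 0)
    msg <- c(msg, "slope must be a single finite number > 0")
  if (length(msg)) msg else TRUE
})

#' Markov scheme of channel gating with state-dependent drug binding
#'
#' Labeled states with a voltage- and concentration-dependent rate
#' matrix. `rateFun(v, drugConc)` returns the infinitesimal generator
#' Q (ms^-1): off-diagonal `Q[i, j]` is the rate from state i to state
#' j, rows sum to zero. `conducting` names the states counted as
#' available in a test-pulse readout.
#'
#' @slot states ordered state labels.
#' @slot rateFun function(v, drugConc) -> generator matrix (ms^-1).
#' @slot conducting labels of conducting (available) states.
#' @slot params list of calibration parameters used to build the scheme.
#' @export
setClass("KineticScheme",
  representation(states = "character", rateFun = "function",
                 conducting = "character", params = "list"),
  prototype(params = list()))

setValidity("KineticScheme", function(object) {
  msg <- character()
  if (length(object@states) < 2L || anyDuplicated(object@states))
    msg <- c(msg, "need >= 2 distinct state labels")
  if (!all(object@conducting %in% object@states))
    msg <- c(msg, "conducting states must be a subset of 'states'")
  ## probe the generator once at a hyperpolarized voltage, no drug
  Q <- tryCatch(object@rateFun(-100, 0), error = function(e) e)
  if (inherits(Q, "error")) {
    msg <- c(msg, paste("rateFun failed at probe voltage:",
                        conditionMessage(Q)))
  } else {
    n <- length(object@states)
    if (!is.matrix(Q) || any(dim(Q) != n)) {
      msg <- c(msg, "rateFun must return an n x n matrix")
    } else {
      off <- Q; diag(off) <- 0
      if (any(off < 0)) msg <- c(msg, "off-diagonal rates must be >= 0")
      if (max(abs(rowSums(Q))) > 1e-9 * max(1, max(abs(Q))))
        msg <- c(msg, "generator rows must sum to zero")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Piecewise-constant voltage-clamp protocol
#'
#' @slot epochs data.frame with columns `voltage` (mV) and `duration`
#'   (ms, > 0), in order of execution.
#' @slot measure data.frame with columns `epoch` (index) and `time`
#'   (offset within the epoch, ms; `NA` means the end of the epoch) at
#'   which availability is read out.
#' @slot label free-text protocol label.
#' @export
setClass("VoltageProtocol",
  representation(epochs = "data.frame", measure = "data.frame",
                 label = "character"),
  prototype(measure = data.frame(epoch = integer(), time = numeric()),
            label = ""))

setValidity("VoltageProtocol", function(object) {
  msg <- character()
  ep <- object@epochs
  if (!all(c("voltage", "duration") %in% names(ep)))
    msg <- c(msg, "epochs needs 'voltage' and 'duration' columns")
  else {
    if (nrow(ep) < 1L) msg <- c(msg, "need at least one epoch")
    if (any(!is.finite(ep$voltage)))
      msg <- c(msg, "epoch voltages must be finite")
    if (any(!is.finite(ep$duration)) || any(ep$duration <= 0))
      msg <- c(msg, "epoch durations must be > 0")
  }
  me <- object@measure
  if (nrow(me)) {
    if (!all(c("epoch", "time") %in% names(me)))
      msg <- c(msg, "measure needs 'epoch' and 'time' columns")
    else if (all(c("voltage", "duration") %in% names(ep))) {
      if (any(me$epoch < 1L | me$epoch > nrow(ep)))
        msg <- c(msg, "measurement epoch index out of range")
      else {
        tt <- me$time
        ok <- is.na(tt) | (tt >= 0 & tt <= ep$duration[me$epoch])
        if (!all(ok))
          msg <- c(msg, "measurement times must fall within their epoch")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Steady-state availability curve
#'
#' Normalized peak test-pulse current versus conditioning prepulse
#' voltage.
#'
#' @slot voltage prepulse voltages (mV).
#' @slot availability normalized current (>= 0, finite).
#' @slot prepulseDuration prepulse duration (ms; 5000 for steady-state,
#'   50 for fast inactivation).
#' @slot testVoltage test-pulse voltage (mV).
#' @slot drugConc drug concentration (nM).
#' @slot label condition label.
#' @export
setClass("AvailabilityCurve",
  representation(voltage = "numeric", availability = "numeric",
                 prepulseDuration = "numeric", testVoltage = "numeric",
                 drugConc = "numeric", label = "character"),
  prototype(prepulseDuration = 5000, testVoltage = 10, drugConc = 0,
            label = ""))

setValidity("AvailabilityCurve", function(object) {
  msg <- character()
  if (length(object@voltage) != length(object@availability))
    msg <- c(msg, "voltage and availability must have equal length")
  if (length(object@voltage) < 5L)
    msg <- c(msg, "need at least 5 points")
  if (any(!is.finite(object@availability)) || any(object@availability < 0))
    msg <- c(msg, "availability values must be finite and >= 0")
  if (any(!is.finite(object@voltage)))
    msg <- c(msg, "voltages must be finite")
  if (length(msg)) msg else TRUE
})

#' Boltzmann fit result
#'
#' @slot params fitted [BoltzmannParams-class].
#' @slot rss residual sum of squares.
#' @slot converged logical convergence flag; non-converged fits carry
#'   the reason in `message`.
#' @slot se standard errors (vHalf, slope, amplitude) from the fit
#'   covariance, `NA` when unavailable.
#' @slot trace residual-sum-of-squares trace across optimizer
#'   iterations.
#' @slot message diagnostic text.
#' @export
setClass("BoltzmannFit",
  representation(params = "BoltzmannParams", rss = "numeric",
                 converged = "logical", se = "numeric", trace = "numeric",
                 message = "character"),
  prototype(se = c(vHalf = NA_real_, slope = NA_real_,
                   amplitude = NA_real_),
            trace = numeric(), message = ""))

#' Dose-response (concentration-inhibition) curve
#'
#' @slot conc drug concentrations (nM, > 0).
#' @slot inhibition fractional inhibition in \[0, 1\].
#' @slot label condition label.
#' @export
setClass("DoseResponseCurve",
  representation(conc = "numeric", inhibition = "numeric",
                 label = "character"),
  prototype(label = ""))

setValidity("DoseResponseCurve", function(object) {
  msg <- character()
  if (length(object@conc) != length(object@inhibition))
    msg <- c(msg, "conc and inhibition must have equal length")
  if (any(!is.finite(object@conc)) || any(object@conc <= 0))
    msg <- c(msg, "concentrations must be finite and > 0")
  if (any(!is.finite(object@inhibition)) ||
      any(object@inhibition < 0 | object@inhibition > 1))
    msg <- c(msg, "inhibition must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Hill fit result
#'
#' @slot ic50 half-maximal inhibitory concentration (nM).
#' @slot hillN Hill coefficient.
#' @slot rss residual sum of squares.
#' @slot converged logical convergence flag.
#' @slot se standard errors (ic50, hillN), `NA` when unavailable.
#' @slot trace objective trace across optimizer iterations.
#' @slot message diagnostic text.
#' @export
setClass("HillFit",
  representation(ic50 = "numeric", hillN = "numeric", rss = "numeric",
                 converged = "logical", se = "numeric", trace = "numeric",
                 message = "character"),
  prototype(se = c(ic50 = NA_real_, hillN = NA_real_), trace = numeric(),
            message = ""))

#' Shift analysis: from paired availability curves to Kd values
#'
#' Result of the coupled-equilibrium analysis of a control/drug pair of
#' availability curves: raw midpoint shift, drift correction, and the
#' inferred resting- and inactivated-state dissociation constants.
#'
#' @slot rawShift drug-minus-control midpoint shift (mV).
#' @slot controlDrift time-dependent midpoint drift measured in drug-free
#'   control experiments (mV).
#' @slot correctedShift `rawShift - controlDrift` (mV), exact.
#' @slot kdRest resting-state dissociation constant (nM, may be `Inf`).
#' @slot kdInact inactivated-state dissociation constant (nM).
#' @slot controlFit,drugFit the underlying [BoltzmannFit-class] objects.
#' @export
setClass("ShiftAnalysis",
  representation(rawShift = "numeric", controlDrift = "numeric",
                 correctedShift = "numeric", kdRest = "numeric",
                 kdInact = "numeric", controlFit = "BoltzmannFit",
                 drugFit = "BoltzmannFit"))

setValidity("ShiftAnalysis", function(object) {
  if (!identical(object@correctedShift,
                 object@rawShift - object@controlDrift))
    "correctedShift must equal rawShift - controlDrift exactly"
  else TRUE
})

#' Atomic structure
#'
#' Minimal container for atomic coordinates: one row per atom with
#' chain id, residue number and name, atom name, element symbol and
#' Cartesian coordinates in Angstrom.
#'
#' @slot atoms data.frame with columns `chain`, `resno`, `resid`,
#'   `elety` (atom name), `elesy` (element symbol), `x`, `y`, `z`.
#' @slot source free-text provenance label (file path or generator).
#' @export
setClass("Structure",
  representation(atoms = "data.frame", source = "character"),
  prototype(source = ""))

setValidity("Structure", function(object) {
  msg <- character()
  need <- c("chain", "resno", "resid", "elety", "elesy", "x", "y", "z")
  if (!all(need %in% names(object@atoms)))
    msg <- c(msg, paste("atoms must have columns:",
                        paste(need, collapse = ", ")))
  else {
    xyz <- as.matrix(object@atoms[, c("x", "y", "z")])
    if (nrow(xyz) && any(!is.finite(xyz)))
      msg <- c(msg, "coordinates must be finite")
    ## a residue number must name a single residue within its chain
    key <- unique(object@atoms[, c("chain", "resno", "resid")])
    if (anyDuplicated(paste(key$chain, key$resno)))
      msg <- c(msg, "residue numbering must be unique within a chain")
  }
  if (length(msg)) msg else TRUE
})

#' Ligand interaction report
#'
#' @slot contacts data.frame: residues with any heavy atom within the
#'   contact cutoff of the ligand (`chain`, `resno`, `resid`,
#'   `minDist`).
#' @slot hbonds data.frame of hydrogen bonds (donor/acceptor atoms,
#'   heavy-atom distance, donor angle, `noAngle` flag).
#' @slot pistacks data.frame of aromatic stacking contacts (residue,
#'   centroid distance, interplanar angle).
#' @slot ligand ligand residue name.
#' @slot cutoffs list of the geometric criteria used.
#' @export
setClass("InteractionReport",
  representation(contacts = "data.frame", hbonds = "data.frame",
                 pistacks = "data.frame", ligand = "character",
                 cutoffs = "list"))

#' Rigid-body superposition result
#'
#' @slot rotation 3x3 proper rotation matrix applied to the mobile
#'   structure (det = +1).
#' @slot translation length-3 translation vector (Angstrom).
#' @slot rmsd root-mean-square deviation over the paired selection
#'   after alignment (Angstrom).
#' @slot perResidue data.frame of per-residue displacements between
#'   paired representative atoms after alignment.
#' @export
setClass("SuperpositionResult",
  representation(rotation = "matrix", translation = "numeric",
                 rmsd = "numeric", perResidue = "data.frame"))

setValidity("SuperpositionResult", function(object) {
  msg <- character()
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) msg <- c(msg, "rotation must be 3x3")
  else {
    if (max(abs(crossprod(R) - diag(3))) > 1e-8)
      msg <- c(msg, "rotation must be orthonormal within 1e-8")
    if (abs(det(R) - 1) > 1e-8)
      msg <- c(msg, "rotation must be proper (det = +1)")
  }
  if (length(object@rmsd) != 1L || !is.finite(object@rmsd) ||
      object@rmsd < 0)
    msg <- c(msg, "rmsd must be a single number >= 0")
  if (length(msg)) msg else TRUE
})

#' Gaussian measurement-noise specification
#'
#' Additive Gaussian noise on normalized current, with a single integer
#' seed that is expanded deterministically into per-curve substreams.
#'
#' @slot sd noise standard deviation (fraction of normalized current,
#'   >= 0).
#' @slot seed integer seed.
#' @export
setClass("NoiseSpec",
  representation(sd = "numeric", seed = "integer"),
  prototype(sd = 0.02, seed = 1L))

setValidity("NoiseSpec", function(object) {
  msg <- character()
  if (length(object@sd) != 1L || !is.finite(object@sd) || object@sd < 0)
    msg <- c(msg, "sd must be a single number >= 0")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (length(msg)) msg else TRUE
})

#' Simulated protocol trajectory
#'
#' @slot trajectory long-format data.frame (`time_ms`, `epoch`, `state`,
#'   `occupancy`) sampled along the protocol.
#' @slot readouts data.frame of availability readouts at the
#'   measurement points (`epoch`, `time_ms`, `availability`), where
#'   availability is the summed occupancy of conducting states.
#' @slot finalOccupancy named occupancy vector at the end of the
#'   protocol.
#' @slot protocol the [VoltageProtocol-class] that was run.
#' @slot drugConc drug concentration during the run (nM).
#' @export
setClass("ProtocolTrajectory",
  representation(trajectory = "data.frame", readouts = "data.frame",
                 finalOccupancy = "numeric", protocol = "VoltageProtocol",
                 drugConc = "numeric"))
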