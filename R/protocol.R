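## Voltage-clamp protocol simulation. Voltages are piecewise constant,
## so each epoch is propagated exactly with the matrix exponential of
## the generator (no time-stepping error).

#' Construct a voltage protocol
#'
#' @param voltage epoch voltages (mV).
#' @param duration epoch durations (ms, > 0), recycled against
#'   `voltage`.
#' @param measureEpoch indices of epochs at which availability is read
#'   out (default: the last epoch).
#' @param measureTime read-out offsets within the measurement epochs
#'   (ms; `NA` = end of epoch), recycled against `measureEpoch`.
#' @param label free-text label.
#' @return a [VoltageProtocol-class].
#' @examples
#' ## 5-s conditioning prepulse followed by a brief test readout
#' voltageProtocol(voltage = c(-100, -70, 10), duration = c(1000, 5000, 10),
#'                 measureEpoch = 3, measureTime = 0)
#' @export
voltageProtocol <- function(voltage, duration, measureEpoch = NULL,
                            measureTime = NA_real_, label = "") {
  ep <- data.frame(voltage = as.numeric(voltage),
                   duration = rep_len(as.numeric(duration),
                                      length(voltage)))
  if (is.null(measureEpoch)) measureEpoch <- nrow(ep)
  me <- data.frame(epoch = as.integer(measureEpoch),
                   time = rep_len(as.numeric(measureTime),
                                  length(measureEpoch)))
  new("VoltageProtocol", epochs = ep, measure = me, label = label)
}

#' Simulate a voltage protocol
#'
#' Propagates the occupancy vector through each constant-voltage epoch
#' exactly (matrix exponential of the generator; see
#' [propagateOccupancy()]). Availability readouts are the summed
#' occupancy of the scheme's conducting states at the measurement
#' points; by default drug-bound resting channels do not conduct (set
#' via `buildScheme(drugBoundConducts = )`).
#'
#' @param scheme a [KineticScheme-class].
#' @param protocol a [VoltageProtocol-class].
#' @param drugConc drug concentration during the run (nM).
#' @param init either a named occupancy vector or
#'   `"equilibrate-at-first-epoch"` (default): start from the
#'   stationary occupancy at the first epoch's voltage.
#' @param nSample number of trajectory sample points per epoch (0 =
#'   epoch boundaries only).
#' @return a [ProtocolTrajectory-class].
#' @export
simulateProtocol <- function(scheme, protocol, drugConc = 0,
                             init = "equilibrate-at-first-epoch",
                             nSample = 0) {
  stopifnot(is(scheme, "KineticScheme"), is(protocol, "VoltageProtocol"))
  validObject(protocol)
  ep <- protocol@epochs
  if (identical(init, "equilibrate-at-first-epoch")) {
    occ <- steadyState(scheme, ep$voltage[1], drugConc)
  } else {
    stopifnot(is.numeric(init), length(init) == length(scheme@states))
    if (abs(sum(init) - 1) > 1e-9)
      stop("initial occupancy must sum to 1")
    occ <- setNames(as.numeric(init), scheme@states)
  }

  tr <- list()
  t0 <- 0
  addSample <- function(t, epoch, occ)
    data.frame(time_ms = t, epoch = epoch, state = scheme@states,
               occupancy = as.numeric(occ))
  tr[[1]] <- addSample(0, 1L, occ)
  ro <- data.frame(epoch = integer(), time_ms = numeric(),
                   availability = numeric())
  me <- protocol@measure

  for (e in seq_len(nrow(ep))) {
    Q <- rateMatrix(scheme, ep$voltage[e], drugConc)
    dur <- ep$duration[e]
    ## interior samples and measurement offsets inside this epoch
    offs <- numeric()
    if (nSample > 0) offs <- seq(0, dur, length.out = nSample + 1L)[-1]
    mIdx <- which(me$epoch == e)
    mOff <- ifelse(is.na(me$time[mIdx]), dur, me$time[mIdx])
    pts <- sort(unique(c(offs, mOff, dur)))
    prev <- 0
    occAt <- occ
    for (tp in pts) {
      occAt <- propagateOccupancy(occAt, Q, tp - prev)
      prev <- tp
      if (tp %in% offs || tp == dur)
        tr[[length(tr) + 1L]] <- addSample(t0 + tp, e, occAt)
      hits <- mIdx[mOff == tp]
      if (length(hits))
        ro <- rbind(ro, data.frame(
          epoch = e, time_ms = t0 + tp,
          availability = availabilityOf(occAt, scheme)))
    }
    occ <- occAt
    t0 <- t0 + dur
  }
  traj <- do.call(rbind, tr)
  rownames(traj) <- NULL
  new("ProtocolTrajectory", trajectory = traj, readouts = ro,
      finalOccupancy = occ, protocol = protocol, drugConc = drugConc)
}

#' Steady-state availability curve from a kinetic scheme
#'
#' Runs the standard availability protocol: equilibrate at the holding
#' potential (in drug, if present), apply a long conditioning prepulse
#' at each voltage, and read the conducting occupancy at the end of the
#' prepulse.
#'
#' @param scheme a [KineticScheme-class].
#' @param voltages prepulse voltage grid (mV).
#' @param prepulseDuration prepulse length (ms, default 5000).
#' @param holding holding potential (mV, default -100).
#' @param drugConc drug concentration (nM).
#' @param normalize `"max"` (default: normalize to the curve's own
#'   maximum), `"none"` (raw conducting occupancy), or a positive
#'   number to divide by (e.g. the drug-free maximum of the same
#'   protocol).
#' @param init `"holding"` (default): equilibrate at the holding
#'   potential (in drug, if present) and run the finite prepulse, as
#'   the experiment does -- with slow drug binding the prepulse curve
#'   then differs from the true equilibrium; `"stationary"`: read the
#'   exact stationary availability at each prepulse voltage.
#' @param label curve label.
#' @return an [AvailabilityCurve-class].
#' @export
availabilityFromScheme <- function(scheme, voltages = seq(-130, -20, by = 5),
                                   prepulseDuration = 5000, holding = -100,
                                   drugConc = 0, normalize = "max",
                                   init = c("holding", "stationary"),
                                   label = "simulated") {
  init <- match.arg(init)
  raw <- vapply(voltages, function(V) {
    if (init == "stationary")
      return(availabilityOf(steadyState(scheme, V, drugConc), scheme))
    prot <- voltageProtocol(voltage = c(holding, V),
                            duration = c(1, prepulseDuration),
                            measureEpoch = 2L)
    sim <- simulateProtocol(scheme, prot, drugConc = drugConc)
    sim@readouts$availability[1]
  }, numeric(1))
  avail <- if (identical(normalize, "max")) raw / max(raw)
           else if (identical(normalize, "none")) raw
           else if (is.numeric(normalize) && normalize > 0) raw / normalize
           else stop("normalize must be 'max', 'none' or a positive number")
  new("AvailabilityCurve", voltage = as.numeric(voltages),
      availability = avail, prepulseDuration = prepulseDuration,
      testVoltage = 10, drugConc = drugConc, label = label)
}

#' Fraction of channels in slowly-recovering states
#'
#' After a depolarizing conditioning step, the fraction of channels not
#' yet available `criterionTime` ms into repolarization measures entry
#' into slowly-recovering states (slow inactivation, and drug-bound
#' states whose recovery requires unbinding).
#'
#' @param scheme a [KineticScheme-class].
#' @param conditioningDuration conditioning step length (ms; 0 = no
#'   conditioning, giving the baseline unavailable fraction at
#'   holding).
#' @param conditioningVoltage conditioning voltage (mV, default -40).
#' @param drugConc drug concentration (nM); the cell is equilibrated in
#'   drug at the holding potential before conditioning.
#' @param holding holding potential (mV, default -100).
#' @param recoveryVoltage recovery voltage (mV, default -100).
#' @param criterionTime recovery time defining "slow" (ms, > 0;
#'   default 100).
#' @return fraction in \[0, 1\]: `1 - availability` at `criterionTime`.
#' @export
slowlyRecoveringFraction <- function(scheme, conditioningDuration,
                                     conditioningVoltage = -40,
                                     drugConc = 0, holding = -100,
                                     recoveryVoltage = -100,
                                     criterionTime = 100) {
  if (!is.numeric(criterionTime) || criterionTime <= 0)
    stop("criterionTime must be > 0")
  if (conditioningDuration < 0)
    stop("conditioningDuration must be >= 0")
  occ <- steadyState(scheme, holding, drugConc)
  if (conditioningDuration > 0)
    occ <- propagateOccupancy(
      occ, rateMatrix(scheme, conditioningVoltage, drugConc),
      conditioningDuration)
  occ <- propagateOccupancy(
    occ, rateMatrix(scheme, recoveryVoltage, drugConc), criterionTime)
  1 - availabilityOf(occ, scheme)
}
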