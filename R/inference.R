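## The analysis chain from measured availability curves to
## state-specific dissociation constants: Boltzmann fits of control and
## drug curves, drift correction of the midpoint shift, resting-state
## Kd from the residual block at hyperpolarized holding, and the
## closed-form inversion of the coupled-equilibrium shift equation for
## the inactivated-state Kd.

#' Construct an availability curve
#'
#' @param voltage prepulse voltages (mV), >= 5 points.
#' @param availability normalized current (finite, >= 0).
#' @param prepulseDuration prepulse length (ms; 5000 steady-state,
#'   50 fast inactivation).
#' @param testVoltage test-pulse voltage (mV).
#' @param drugConc drug concentration (nM).
#' @param label condition label.
#' @return an [AvailabilityCurve-class].
#' @export
availabilityCurve <- function(voltage, availability,
                              prepulseDuration = 5000, testVoltage = 10,
                              drugConc = 0, label = "") {
  new("AvailabilityCurve", voltage = as.numeric(voltage),
      availability = as.numeric(availability),
      prepulseDuration = prepulseDuration, testVoltage = testVoltage,
      drugConc = drugConc, label = label)
}

#' Construct a dose-response curve
#'
#' @param conc drug concentrations (nM, > 0).
#' @param inhibition fractional inhibition in \[0, 1\].
#' @param label condition label.
#' @return a [DoseResponseCurve-class].
#' @export
doseResponseCurve <- function(conc, inhibition, label = "") {
  new("DoseResponseCurve", conc = as.numeric(conc),
      inhibition = as.numeric(inhibition), label = label)
}

#' Drift-corrected availability-midpoint shift
#'
#' Steady-state inactivation midpoints drift slowly during whole-cell
#' recordings, so the average drug-induced shift is corrected by
#' subtracting the average shift measured in time-matched drug-free
#' controls: `correctedShift = rawShift - controlDrift`, exactly.
#'
#' @param rawShift average midpoint shift measured with drug (mV).
#' @param controlDrift average midpoint shift in drug-free controls
#'   over the matching interval (mV).
#' @return corrected shift (mV).
#' @examples
#' driftCorrectedShift(-10.9, -3.6)  # -7.3 mV
#' @export
driftCorrectedShift <- function(rawShift, controlDrift) {
  if (!is.finite(rawShift) || !is.finite(controlDrift))
    stop("rawShift and controlDrift must be finite")
  rawShift - controlDrift
}

#' Resting-state dissociation constant from residual block
#'
#' At strongly hyperpolarized holding potentials essentially all
#' channels are resting, so the fraction of current remaining in drug,
#' `restingBlock` = b, reflects one-site resting-state occupancy:
#' \eqn{K_r = D\,b / (1 - b)}. Full current (b = 1) means no detectable
#' resting binding and returns `Inf`.
#'
#' @param restingBlock fraction of control current remaining with drug
#'   at hyperpolarized holding (0 < b <= 1).
#' @param drugConc drug concentration D (nM).
#' @return resting-state Kd (nM; `Inf` when b = 1).
#' @export
inferKdRest <- function(restingBlock, drugConc) {
  if (!is.finite(restingBlock) || restingBlock <= 0 || restingBlock > 1)
    stop("restingBlock must lie in (0, 1]")
  if (restingBlock == 1) return(Inf)
  drugConc * restingBlock / (1 - restingBlock)
}

#' Inactivated-state dissociation constant from the midpoint shift
#'
#' Closed-form inversion of the coupled-equilibrium shift equation
#' (see [coupledShift()]):
#' \deqn{K_i = \frac{D}{(1 + D/K_r)\,e^{-\Delta V/k} - 1}}
#' with the signed (hyperpolarizing = negative) shift \eqn{\Delta V}.
#' A shift of zero returns \eqn{K_i = K_r} (equal affinities). A
#' depolarizing shift large enough to make the bracket non-positive is
#' inconsistent with inactivated-state binding and raises an error of
#' class `statenav_no_binding`.
#'
#' @param shift corrected midpoint shift (mV, typically <= 0).
#' @param slope Boltzmann slope factor (mV, > 0); by convention the
#'   control fit's slope.
#' @param drugConc drug concentration (nM, > 0).
#' @param kdRest resting-state Kd (nM, may be `Inf`).
#' @return inactivated-state Kd (nM).
#' @examples
#' inferKdInact(-7.9 * log(7), slope = 7.9, drugConc = 300,
#'              kdRest = Inf)  # 50 nM
#' @export
inferKdInact <- function(shift, slope, drugConc, kdRest) {
  if (!is.finite(shift)) stop("shift must be finite")
  if (!is.numeric(slope) || slope <= 0) stop("slope must be > 0")
  if (!is.numeric(drugConc) || drugConc <= 0)
    stop("drugConc must be > 0")
  if (is.na(kdRest) || kdRest <= 0) stop("kdRest must be > 0")
  bracket <- (1 + drugConc / kdRest) * exp(-shift / slope) - 1
  if (bracket < 1e-300)
    stop(errorCondition(
      paste0("shift (", format(shift), " mV) is inconsistent with ",
             "inactivated-state binding (apparent affinity not tighter ",
             "than resting)"),
      class = c("statenav_no_binding", "error", "condition")))
  drugConc / bracket
}

#' Full state-dependence analysis of a control/drug curve pair
#'
#' Composes the analysis chain: Boltzmann fits of both curves, raw
#' midpoint shift, drift correction, resting-state Kd from the residual
#' block, and the closed-form inactivated-state Kd. The slope used in
#' the inversion is the control fit's slope, as the coupled-equilibrium
#' model assumes a common slope factor.
#'
#' @param control,drug [AvailabilityCurve-class] objects on the same
#'   prepulse grid and duration.
#' @param restingBlock fraction of current remaining with drug at
#'   hyperpolarized holding (0 < b <= 1).
#' @param controlDrift drift correction (mV, default 0).
#' @return a [ShiftAnalysis-class].
#' @examples
#' m <- stateBindingModel(300, 360, 50, 7.9)
#' g <- genPairedAvailability(m, boltzmannParams(-75.2, 7.9),
#'                            noise = noiseSpec(0, 1))
#' res <- analyzeStateDependence(g$control, g$drug, g$restingBlock)
#' kdInact(res)  # recovers 50 nM
#' @export
analyzeStateDependence <- function(control, drug, restingBlock,
                                   controlDrift = 0) {
  stopifnot(is(control, "AvailabilityCurve"), is(drug, "AvailabilityCurve"))
  if (length(control@voltage) != length(drug@voltage) ||
      max(abs(control@voltage - drug@voltage)) > 1e-9)
    stop("control and drug curves must share the prepulse voltage grid")
  if (control@prepulseDuration != drug@prepulseDuration)
    stop("control and drug curves must share the prepulse duration")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(errorCondition(
        paste0("stage '", name, "': ", conditionMessage(e)),
        class = c("statenav_stage_error", class(e)[1], "error",
                  "condition"))))
  }
  ctrlFit <- stage("fit_control", {
    f <- fitBoltzmann(control)
    if (!f@converged) stop("control Boltzmann fit did not converge: ",
                           f@message)
    f
  })
  drugFit <- stage("fit_drug", {
    f <- fitBoltzmann(drug)
    if (!f@converged) stop("drug Boltzmann fit did not converge: ",
                           f@message)
    f
  })
  rawShift <- vHalf(drugFit) - vHalf(ctrlFit)
  corrected <- stage("drift_correction",
                     driftCorrectedShift(rawShift, controlDrift))
  kr <- stage("infer_kd_rest",
              inferKdRest(restingBlock, drug@drugConc))
  ki <- stage("infer_kd_inact", {
    if (corrected == 0 && is.infinite(kr)) Inf
    else inferKdInact(corrected, slopeFactor(ctrlFit), drug@drugConc, kr)
  })
  new("ShiftAnalysis", rawShift = rawShift, controlDrift = controlDrift,
      correctedShift = corrected, kdRest = kr, kdInact = ki,
      controlFit = ctrlFit, drugFit = drugFit)
}

#' Average per-cell midpoint shifts
#'
#' Multi-cell experiments are aggregated by averaging the shift within
#' each cell first and then across cells (rather than pooling points
#' into one fit).
#'
#' @param shifts numeric vector of per-cell midpoint shifts (mV).
#' @return mean shift (mV).
#' @export
averageShift <- function(shifts) {
  if (!length(shifts) || any(!is.finite(shifts)))
    stop("shifts must be a non-empty finite vector")
  mean(shifts)
}
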