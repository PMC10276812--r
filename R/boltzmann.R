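## Closed-form pieces of the coupled-equilibrium (modulated-receptor)
## model: the Boltzmann availability curve, the predicted midpoint
## shift for state-dependent binding, and the state-weighted apparent
## dissociation constant.

#' Construct Boltzmann availability parameters
#'
#' @param vHalf midpoint voltage (mV).
#' @param slope slope factor (mV, strictly positive). The sign
#'   convention is \eqn{h(V) = A/(1 + \exp((V - V_{1/2})/k))}, i.e.
#'   availability decreases with depolarization.
#' @param amplitude maximal availability (default 1).
#' @return a [BoltzmannParams-class] object.
#' @examples
#' ctrl <- boltzmannParams(vHalf = -75.2, slope = 7.9)
#' boltzmannAvailability(-75.2, ctrl)  # 0.5 at the midpoint
#' @export
boltzmannParams <- function(vHalf, slope, amplitude = 1) {
  new("BoltzmannParams", vHalf = as.numeric(vHalf),
      slope = as.numeric(slope), amplitude = as.numeric(amplitude))
}

#' Construct a state-binding (coupled-equilibrium) model
#'
#' @param drugConc drug concentration (nM, >= 0).
#' @param kdRest resting-state dissociation constant (nM; `Inf` means
#'   no resting-state binding).
#' @param kdInact inactivated-state dissociation constant (nM).
#' @param slope Boltzmann slope factor of the drug-free availability
#'   curve (mV).
#' @return a [StateBindingModel-class] object.
#' @examples
#' m <- stateBindingModel(drugConc = 300, kdRest = 360, kdInact = 50,
#'                        slope = 7.9)
#' coupledShift(m)
#' @export
stateBindingModel <- function(drugConc, kdRest, kdInact, slope) {
  new("StateBindingModel", drugConc = as.numeric(drugConc),
      kdRest = as.numeric(kdRest), kdInact = as.numeric(kdInact),
      slope = as.numeric(slope))
}

#' Boltzmann steady-state availability
#'
#' Evaluates \eqn{h(V) = A / (1 + \exp((V - V_{1/2})/k))}. With
#' \eqn{k > 0} the curve decreases with depolarization and saturates at
#' the amplitude \eqn{A} for strongly hyperpolarized voltages.
#'
#' @param v voltage(s), mV.
#' @param params a [BoltzmannParams-class] object.
#' @return availability fraction(s) in \[0, amplitude\].
#' @export
boltzmannAvailability <- function(v, params) {
  stopifnot(is(params, "BoltzmannParams"))
  validObject(params)
  params@amplitude / (1 + exp((v - params@vHalf) / params@slope))
}

#' Predicted availability-midpoint shift from state-dependent binding
#'
#' Under the coupled-equilibrium model, a drug at concentration D with
#' resting-state constant \eqn{K_r} and inactivated-state constant
#' \eqn{K_i} shifts the availability midpoint by
#' \deqn{\Delta V_{1/2} = -k \,\ln\frac{1 + D/K_i}{1 + D/K_r},}
#' negative (hyperpolarizing) when \eqn{K_i < K_r}, zero when D = 0 or
#' \eqn{K_i = K_r}.
#'
#' @param model a [StateBindingModel-class].
#' @return midpoint shift in mV.
#' @examples
#' ## 300 nM of an inactivated-state-selective drug (Ki = 50 nM,
#' ## no resting binding) on a 7.9 mV slope: -7.9 * log(7)
#' coupledShift(stateBindingModel(300, Inf, 50, 7.9))
#' @export
coupledShift <- function(model) {
  stopifnot(is(model, "StateBindingModel"))
  validObject(model)
  D <- model@drugConc
  -model@slope * log((1 + D / model@kdInact) / (1 + D / model@kdRest))
}

#' Apparent dissociation constant at a given availability
#'
#' With a fraction `h` of channels resting and `1 - h` inactivated, the
#' coupled-equilibrium apparent affinity is the occupancy-weighted
#' harmonic combination \eqn{1/K_{app} = h/K_r + (1 - h)/K_i}, so
#' \eqn{K_{app}} moves continuously and monotonically from \eqn{K_i}
#' (h = 0) to \eqn{K_r} (h = 1).
#'
#' @param h fraction of channels in the resting state, in \[0, 1\].
#' @param model a [StateBindingModel-class].
#' @return apparent dissociation constant (nM).
#' @export
apparentKd <- function(h, model) {
  stopifnot(is(model, "StateBindingModel"))
  validObject(model)
  if (any(!is.finite(h)) || any(h < 0 | h > 1))
    stop("'h' must lie in [0, 1]")
  1 / (h / model@kdRest + (1 - h) / model@kdInact)
}
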