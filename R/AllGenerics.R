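#' @title Accessor generics
#' @description Accessors for the fitted-parameter and model classes:
#'   `vHalf()`, `slopeFactor()` and `amplitude()` for Boltzmann
#'   parameters and fits, `drugConc()`, `kdRest()` and `kdInact()` for
#'   binding models and shift analyses, `ic50()` and `hillCoef()` for
#'   Hill fits, `atoms()` for structures, and `isConverged()` for fit
#'   results.
#' @param object an object of the documented classes.
#' @return the corresponding scalar, vector or data.frame.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("vHalf", function(object) standardGeneric("vHalf"))
#' @rdname accessors
#' @export
setGeneric("slopeFactor", function(object) standardGeneric("slopeFactor"))
#' @rdname accessors
#' @export
setGeneric("amplitude", function(object) standardGeneric("amplitude"))
#' @rdname accessors
#' @export
setGeneric("drugConc", function(object) standardGeneric("drugConc"))
#' @rdname accessors
#' @export
setGeneric("kdRest", function(object) standardGeneric("kdRest"))
#' @rdname accessors
#' @export
setGeneric("kdInact", function(object) standardGeneric("kdInact"))
#' @rdname accessors
#' @export
setGeneric("ic50", function(object) standardGeneric("ic50"))
#' @rdname accessors
#' @export
setGeneric("hillCoef", function(object) standardGeneric("hillCoef"))
#' @rdname accessors
#' @export
setGeneric("atoms", function(object) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))
#' @rdname accessors
#' @export
setGeneric("correctedShift", function(object)
  standardGeneric("correctedShift"))

setMethod("vHalf", "BoltzmannParams", function(object) object@vHalf)
setMethod("slopeFactor", "BoltzmannParams", function(object) object@slope)
setMethod("amplitude", "BoltzmannParams", function(object) object@amplitude)
setMethod("vHalf", "BoltzmannFit", function(object) object@params@vHalf)
setMethod("slopeFactor", "BoltzmannFit", function(object)
  object@params@slope)
setMethod("amplitude", "BoltzmannFit", function(object)
  object@params@amplitude)
setMethod("slopeFactor", "StateBindingModel", function(object) object@slope)
setMethod("drugConc", "StateBindingModel", function(object) object@drugConc)
setMethod("kdRest", "StateBindingModel", function(object) object@kdRest)
setMethod("kdInact", "StateBindingModel", function(object) object@kdInact)
setMethod("kdRest", "ShiftAnalysis", function(object) object@kdRest)
setMethod("kdInact", "ShiftAnalysis", function(object) object@kdInact)
setMethod("correctedShift", "ShiftAnalysis", function(object)
  object@correctedShift)
setMethod("ic50", "HillFit", function(object) object@ic50)
setMethod("hillCoef", "HillFit", function(object) object@hillN)
setMethod("atoms", "Structure", function(object) object@atoms)
setMethod("isConverged", "BoltzmannFit", function(object) object@converged)
setMethod("isConverged", "HillFit", function(object) object@converged)

#' @title Coerce curves to data.frame
#' @description `as.data.frame` methods for [AvailabilityCurve-class]
#'   (columns `prepulse_mV`, `current_norm`) and
#'   [DoseResponseCurve-class] (columns `conc_nM`, `inhibition`),
#'   matching the delimited-text schemas used on disk.
#' @param x the curve object.
#' @param row.names,optional,... ignored, present for generic
#'   compatibility.
#' @return a data.frame.
#' @name curve-coercion
NULL

#' @rdname curve-coercion
#' @export
setMethod("as.data.frame", "AvailabilityCurve",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(prepulse_mV = x@voltage, current_norm = x@availability)
  })

#' @rdname curve-coercion
#' @export
setMethod("as.data.frame", "DoseResponseCurve",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(conc_nM = x@conc, inhibition = x@inhibition)
  })
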