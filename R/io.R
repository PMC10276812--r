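## Delimited-text and JSON input/output. All tables are comma
## separated with "." decimal and a single header line; fit results and
## interaction reports are JSON records.

#' Read / write availability curves
#'
#' Availability curves are stored as CSV with header
#' `prepulse_mV,current_norm`. Metadata (prepulse duration, drug
#' concentration, label) is supplied by the caller on read.
#'
#' @param path file path.
#' @param ... metadata passed to [availabilityCurve()].
#' @return [readAvailabilityCurve()] returns an
#'   [AvailabilityCurve-class]; the writers return `path` invisibly.
#' @export
readAvailabilityCurve <- function(path, ...) {
  df <- read.csv(path)
  need <- c("prepulse_mV", "current_norm")
  if (!all(need %in% names(df)))
    stop("expected columns ", paste(need, collapse = ", "), " in ", path)
  availabilityCurve(df$prepulse_mV, df$current_norm, ...)
}

#' @rdname readAvailabilityCurve
#' @param curve the curve to write.
#' @export
writeAvailabilityCurve <- function(curve, path) {
  stopifnot(is(curve, "AvailabilityCurve"))
  write.csv(as.data.frame(curve), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Read / write dose-response curves
#'
#' Dose-response curves are stored as CSV with header
#' `conc_nM,inhibition`.
#'
#' @param path file path.
#' @param ... metadata passed to [doseResponseCurve()].
#' @return [readDoseResponseCurve()] returns a
#'   [DoseResponseCurve-class]; the writer returns `path` invisibly.
#' @export
readDoseResponseCurve <- function(path, ...) {
  df <- read.csv(path)
  need <- c("conc_nM", "inhibition")
  if (!all(need %in% names(df)))
    stop("expected columns ", paste(need, collapse = ", "), " in ", path)
  doseResponseCurve(df$conc_nM, df$inhibition, ...)
}

#' @rdname readDoseResponseCurve
#' @param curve the curve to write.
#' @export
writeDoseResponseCurve <- function(curve, path) {
  stopifnot(is(curve, "DoseResponseCurve"))
  write.csv(as.data.frame(curve), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Write a trajectory as tidy delimited text
#'
#' Long format with columns `time_ms`, `epoch`, `state`, `occupancy`.
#'
#' @param sim a [ProtocolTrajectory-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(sim, path) {
  stopifnot(is(sim, "ProtocolTrajectory"))
  write.csv(sim@trajectory, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## fit results as plain lists for JSON emission
.fitRecord <- function(fit) {
  if (is(fit, "BoltzmannFit"))
    list(model = "boltzmann",
         estimate = list(vHalf = vHalf(fit), slope = slopeFactor(fit),
                         amplitude = amplitude(fit)),
         se = as.list(fit@se), rss = fit@rss,
         converged = fit@converged, message = fit@message)
  else if (is(fit, "HillFit"))
    list(model = "hill",
         estimate = list(ic50 = ic50(fit), hillN = hillCoef(fit)),
         se = as.list(fit@se), rss = fit@rss,
         converged = fit@converged, message = fit@message)
  else stop("unsupported fit object")
}

#' Write a fit result as a JSON record
#'
#' Emits parameter estimates, standard errors from the fit covariance,
#' the residual sum of squares and the convergence flag.
#'
#' @param fit a [BoltzmannFit-class] or [HillFit-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeFitResult <- function(fit, path) {
  jsonlite::write_json(.fitRecord(fit), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' Write a shift analysis as a JSON record
#'
#' @param analysis a [ShiftAnalysis-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeShiftAnalysis <- function(analysis, path) {
  stopifnot(is(analysis, "ShiftAnalysis"))
  rec <- list(rawShift_mV = analysis@rawShift,
              controlDrift_mV = analysis@controlDrift,
              correctedShift_mV = analysis@correctedShift,
              kdRest_nM = if (is.finite(analysis@kdRest))
                analysis@kdRest else "Inf",
              kdInact_nM = analysis@kdInact,
              controlFit = .fitRecord(analysis@controlFit),
              drugFit = .fitRecord(analysis@drugFit))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Write an interaction report as JSON
#'
#' @param report an [InteractionReport-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeInteractionReport <- function(report, path) {
  stopifnot(is(report, "InteractionReport"))
  rec <- list(ligand = report@ligand, cutoffs = report@cutoffs,
              contacts = report@contacts, hbonds = report@hbonds,
              pistacks = report@pistacks)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Write a per-residue displacement table
#'
#' @param sup a [SuperpositionResult-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeDisplacementTable <- function(sup, path) {
  stopifnot(is(sup, "SuperpositionResult"))
  write.csv(sup@perResidue, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
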