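## show() methods: one-glance summaries of the main objects.

setMethod("show", "BoltzmannParams", function(object) {
  cat(sprintf("Boltzmann availability: V1/2 = %.2f mV, k = %.2f mV, A = %.3f\n",
              object@vHalf, object@slope, object@amplitude))
})

setMethod("show", "StateBindingModel", function(object) {
  cat("Coupled-equilibrium state-binding model\n")
  cat(sprintf("  D = %g nM, Kr = %s nM, Ki = %g nM, k = %g mV\n",
              object@drugConc,
              if (is.finite(object@kdRest)) format(object@kdRest) else "Inf",
              object@kdInact, object@slope))
  cat(sprintf("  predicted midpoint shift: %.2f mV\n",
              coupledShift(object)))
})

setMethod("show", "KineticScheme", function(object) {
  cat(sprintf("Kinetic scheme: %d states (%s)\n", length(object@states),
              paste(object@states, collapse = ", ")))
  cat(sprintf("  conducting: %s\n",
              paste(object@conducting, collapse = ", ")))
  p <- object@params
  if (length(p))
    cat(sprintf(
      "  calibration: V1/2 = %g mV, k = %g mV, Kr = %s nM, Ki = %g nM\n",
      p$vHalf, p$slope,
      if (is.finite(p$kdRest)) format(p$kdRest) else "Inf", p$kdInact))
})

setMethod("show", "VoltageProtocol", function(object) {
  cat(sprintf("Voltage protocol%s: %d epoch(s), %.4g ms total\n",
              if (nzchar(object@label))
                paste0(" '", object@label, "'") else "",
              nrow(object@epochs), sum(object@epochs$duration)))
})

setMethod("show", "AvailabilityCurve", function(object) {
  cat(sprintf(
    "Availability curve%s: %d points, %g-ms prepulses, D = %g nM\n",
    if (nzchar(object@label)) paste0(" '", object@label, "'") else "",
    length(object@voltage), object@prepulseDuration, object@drugConc))
})

setMethod("show", "BoltzmannFit", function(object) {
  if (object@converged)
    cat(sprintf(
      "Boltzmann fit: V1/2 = %.3f mV, k = %.3f mV, A = %.4f (rss %.3g)\n",
      vHalf(object), slopeFactor(object), amplitude(object), object@rss))
  else
    cat("Boltzmann fit: NOT converged --", object@message, "\n")
})

setMethod("show", "DoseResponseCurve", function(object) {
  cat(sprintf("Dose-response curve%s: %d concentrations\n",
              if (nzchar(object@label))
                paste0(" '", object@label, "'") else "",
              length(object@conc)))
})

setMethod("show", "HillFit", function(object) {
  if (object@converged)
    cat(sprintf("Hill fit: IC50 = %.4g nM, n = %.3f (rss %.3g)\n",
                object@ic50, object@hillN, object@rss))
  else
    cat("Hill fit: NOT converged --", object@message, "\n")
})

setMethod("show", "ShiftAnalysis", function(object) {
  cat("State-dependence analysis\n")
  cat(sprintf("  raw shift %.2f mV, drift %.2f mV, corrected %.2f mV\n",
              object@rawShift, object@controlDrift,
              object@correctedShift))
  cat(sprintf("  Kd(resting) = %s nM, Kd(inactivated) = %.4g nM\n",
              if (is.finite(object@kdRest)) format(object@kdRest)
              else "Inf", object@kdInact))
})

setMethod("show", "Structure", function(object) {
  a <- object@atoms
  cat(sprintf("Structure [%s]: %d atoms, %d residues, chains: %s\n",
              object@source, nrow(a),
              nrow(unique(a[, c("chain", "resno")])),
              paste(sort(unique(a$chain)), collapse = ", ")))
})

setMethod("show", "InteractionReport", function(object) {
  cat(sprintf(
    "Interaction report for ligand %s: %d contact residue(s), %d H-bond(s), %d pi-stack(s)\n",
    object@ligand, nrow(object@contacts), nrow(object@hbonds),
    nrow(object@pistacks)))
})

setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf("Superposition: rmsd = %.4f A over %d residue(s)\n",
              object@rmsd, nrow(object@perResidue)))
})

setMethod("show", "ProtocolTrajectory", function(object) {
  cat(sprintf(
    "Protocol trajectory: %d sample(s), %d readout(s), D = %g nM\n",
    nrow(object@trajectory), nrow(object@readouts), object@drugConc))
})

setMethod("show", "NoiseSpec", function(object) {
  cat(sprintf("Gaussian noise: sd = %g, seed = %d\n", object@sd,
              object@seed))
})
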