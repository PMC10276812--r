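## Configuration-driven pipeline: synth -> simulate -> fit -> infer
## (-> annotate), with full validation before any stage runs and a
## provenance record sufficient to regenerate every output.

.configError <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("statenav_config_error", "error",
                                "condition")))
}

.checkKeys <- function(block, allowed, where) {
  bad <- setdiff(names(block), allowed)
  if (length(bad))
    .configError("unknown key(s) in ", where, ": ",
                 paste(bad, collapse = ", "))
}

.num1 <- function(x, name, lo = -Inf, hi = Inf, allowInf = FALSE) {
  if (is.null(x) || length(x) != 1L || !is.numeric(x) ||
      (!allowInf && !is.finite(x)) || x < lo || x > hi)
    .configError("'", name, "' must be a single number in [",
                 lo, ", ", hi, "]")
  as.numeric(x)
}

#' Read and validate a pipeline configuration
#'
#' Configurations are YAML (JSON is a YAML subset). Unknown keys are
#' rejected; every omitted parameter receives its documented default
#' and the fully resolved configuration is echoed into the provenance
#' record by [runPipeline()]. See `system.file("extdata",
#' "demo_config.yaml", package = "statenav")` for a complete example.
#'
#' @param path path to a YAML/JSON configuration file.
#' @return validated configuration list (class `statenav_config`).
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) .configError("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validateRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param cfg a configuration list (as parsed from YAML/JSON).
#' @export
validateRunConfig <- function(cfg) {
  if (!is.list(cfg)) .configError("config must be a mapping")
  .checkKeys(cfg, c("seed", "output_dir", "stages", "model", "noise",
                    "voltages", "control_drift", "dose_response",
                    "simulate", "structure"), "config")
  out <- list()
  out$seed <- as.integer(.num1(cfg$seed %||% 1, "seed"))
  if (is.null(cfg$output_dir) || !is.character(cfg$output_dir))
    .configError("'output_dir' must be a path string")
  out$output_dir <- cfg$output_dir
  stages <- cfg$stages %||% c("synth", "fit", "infer")
  known <- c("synth", "simulate", "fit", "infer", "annotate")
  if (!all(stages %in% known))
    .configError("unknown stage(s): ",
                 paste(setdiff(stages, known), collapse = ", "))
  out$stages <- stages

  m <- cfg$model %||% list()
  .checkKeys(m, c("v_half", "slope", "amplitude", "kd_rest", "kd_inact",
                  "drug_conc", "on_rate"), "model")
  out$model <- list(
    v_half = .num1(m$v_half %||% -75.2, "model.v_half"),
    slope = .num1(m$slope %||% 7.9, "model.slope", lo = 1e-6),
    amplitude = .num1(m$amplitude %||% 1, "model.amplitude", lo = 1e-9),
    kd_rest = .num1(m$kd_rest %||% 360, "model.kd_rest", lo = 1e-9,
                    allowInf = TRUE),
    kd_inact = .num1(m$kd_inact %||% 50, "model.kd_inact", lo = 1e-9),
    drug_conc = .num1(m$drug_conc %||% 300, "model.drug_conc", lo = 0),
    on_rate = .num1(m$on_rate %||% 4.72e-5, "model.on_rate", lo = 0))

  no <- cfg$noise %||% list()
  .checkKeys(no, "sd", "noise")
  out$noise <- list(sd = .num1(no$sd %||% 0, "noise.sd", lo = 0))

  vg <- cfg$voltages %||% list()
  out$voltages <- if (is.numeric(vg) && length(vg) > 1L) {
    ## already a resolved grid (e.g. a re-validated configuration)
    if (any(!is.finite(vg))) .configError("voltages must be finite")
    as.numeric(vg)
  } else {
    .checkKeys(vg, c("from", "to", "by"), "voltages")
    seq(.num1(vg$from %||% -130, "voltages.from"),
        .num1(vg$to %||% -20, "voltages.to"),
        by = .num1(vg$by %||% 5, "voltages.by", lo = 1e-9))
  }
  if (length(out$voltages) < 5L)
    .configError("voltage grid must have at least 5 points")
  out$control_drift <- .num1(cfg$control_drift %||% 0, "control_drift")

  if (!is.null(cfg$dose_response)) {
    dr <- cfg$dose_response
    .checkKeys(dr, c("ic50", "hill_n", "concs", "fix_hill_n"),
               "dose_response")
    concs <- dr$concs %||% c(300, 1000, 3000, 10000, 30000)
    if (!is.numeric(unlist(concs)) || any(unlist(concs) <= 0))
      .configError("dose_response.concs must be positive")
    out$dose_response <- list(
      ic50 = .num1(dr$ic50 %||% 1820, "dose_response.ic50", lo = 1e-9),
      hill_n = .num1(dr$hill_n %||% 1, "dose_response.hill_n",
                     lo = 1e-3),
      concs = as.numeric(unlist(concs)),
      fix_hill_n = if (is.null(dr$fix_hill_n)) NULL
                   else .num1(dr$fix_hill_n, "dose_response.fix_hill_n",
                              lo = 1e-3))
  }

  if (!is.null(cfg$simulate)) {
    si <- cfg$simulate
    .checkKeys(si, c("protocol", "holding", "duration_ms",
                     "prepulse_ms"), "simulate")
    prot <- si$protocol %||% "application"
    if (!prot %in% c("application", "availability"))
      .configError("simulate.protocol must be 'application' or ",
                   "'availability'")
    out$simulate <- list(
      protocol = prot,
      holding = .num1(si$holding %||% -70, "simulate.holding"),
      duration_ms = .num1(si$duration_ms %||% 120000,
                          "simulate.duration_ms", lo = 1e-9),
      prepulse_ms = .num1(si$prepulse_ms %||% 5000,
                          "simulate.prepulse_ms", lo = 1e-9))
  }

  if (!is.null(cfg$structure)) {
    st <- cfg$structure
    .checkKeys(st, c("holo", "apo", "ligand", "ring_atoms",
                     "contact_cutoff", "hbond_dmax", "hbond_angle_min",
                     "stack_centroid_max", "stack_angle_max"),
               "structure")
    if (is.null(st$holo) || !is.character(st$holo))
      .configError("structure.holo must be a file path")
    out$structure <- list(
      holo = st$holo, apo = st$apo, ligand = st$ligand %||% "CBD",
      ring_atoms = unlist(st$ring_atoms),
      contact_cutoff = .num1(st$contact_cutoff %||% 4.5,
                             "structure.contact_cutoff", lo = 0),
      hbond_dmax = .num1(st$hbond_dmax %||% 3.5, "structure.hbond_dmax",
                         lo = 0),
      hbond_angle_min = .num1(st$hbond_angle_min %||% 120,
                              "structure.hbond_angle_min", 0, 180),
      stack_centroid_max = .num1(st$stack_centroid_max %||% 5.5,
                                 "structure.stack_centroid_max", lo = 0),
      stack_angle_max = .num1(st$stack_angle_max %||% 30,
                              "structure.stack_angle_max", 0, 90))
  }
  class(out) <- c("statenav_config", "list")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the configured analysis pipeline
#'
#' Executes the requested stages in order -- `synth` (generate paired
#' availability curves and, if configured, dose-response data),
#' `simulate` (kinetic-scheme simulation: drug application time course
#' or availability protocol), `fit` (Boltzmann/Hill fits), `infer`
#' (full state-dependence analysis) and `annotate` (structure
#' annotation) -- writing each product into `output_dir` together with
#' a provenance record (`provenance.json`: fully resolved
#' configuration, package version, seed). Identical configuration and
#' seed give byte-identical outputs; provenance deliberately records
#' no wall-clock information. A stage failure aborts with the stage
#' name; outputs of earlier stages are preserved.
#'
#' @param config path to a config file, or a list already validated by
#'   [validateRunConfig()].
#' @return invisibly, a list with the in-memory results per stage and
#'   the written file paths.
#' @export
runPipeline <- function(config) {
  cfg <- if (is.character(config)) readRunConfig(config)
         else validateRunConfig(unclass(config))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  results <- list()
  emit <- function(name) {
    files <<- c(files, file.path(cfg$output_dir, name))
    file.path(cfg$output_dir, name)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cls <- if (inherits(e, "statenav_config_error"))
        "statenav_config_error" else "statenav_numeric_error"
      stop(errorCondition(
        paste0("pipeline stage '", name, "' failed: ",
               conditionMessage(e)),
        class = c(cls, "error", "condition")))
    })
  }

  model <- stateBindingModel(cfg$model$drug_conc, cfg$model$kd_rest,
                             cfg$model$kd_inact, cfg$model$slope)
  control <- boltzmannParams(cfg$model$v_half, cfg$model$slope,
                             cfg$model$amplitude)
  noise <- noiseSpec(cfg$noise$sd, cfg$seed)

  if ("synth" %in% cfg$stages) stage("synth", {
    pair <- genPairedAvailability(model, control, cfg$voltages, noise)
    writeAvailabilityCurve(pair$control, emit("control_curve.csv"))
    writeAvailabilityCurve(pair$drug, emit("drug_curve.csv"))
    results$synth <- pair
    if (!is.null(cfg$dose_response)) {
      dr <- genDoseResponse(cfg$dose_response$ic50,
                            cfg$dose_response$hill_n,
                            cfg$dose_response$concs, noise,
                            stream = 5L)
      writeDoseResponseCurve(dr, emit("dose_response.csv"))
      results$synth$doseResponse <- dr
    }
  })

  if ("simulate" %in% cfg$stages) stage("simulate", {
    sch <- buildScheme(vHalf = cfg$model$v_half, slope = cfg$model$slope,
                       kdRest = cfg$model$kd_rest,
                       kdInact = cfg$model$kd_inact,
                       onRate = cfg$model$on_rate)
    si <- cfg$simulate %||% list(protocol = "application",
                                 holding = -70, duration_ms = 120000,
                                 prepulse_ms = 5000)
    if (si$protocol == "application") {
      prot <- voltageProtocol(voltage = rep(si$holding, 2),
                              duration = c(1, si$duration_ms),
                              measureEpoch = 2L)
      free <- steadyState(sch, si$holding, 0)
      sim <- simulateProtocol(sch, prot,
                              drugConc = cfg$model$drug_conc,
                              init = free, nSample = 120)
      writeTrajectory(sim, emit("application_trajectory.csv"))
      results$simulate <- list(
        trajectory = sim,
        relCurrent = sim@readouts$availability[1] /
          availabilityOf(free, sch))
    } else {
      cur <- availabilityFromScheme(
        sch, cfg$voltages, prepulseDuration = si$prepulse_ms,
        drugConc = cfg$model$drug_conc)
      writeAvailabilityCurve(cur, emit("simulated_availability.csv"))
      results$simulate <- list(curve = cur)
    }
  })

  if ("fit" %in% cfg$stages) stage("fit", {
    if (is.null(results$synth))
      stop("fit stage requires the synth stage")
    fc <- fitBoltzmann(results$synth$control)
    fd <- fitBoltzmann(results$synth$drug)
    writeFitResult(fc, emit("fit_control.json"))
    writeFitResult(fd, emit("fit_drug.json"))
    results$fit <- list(control = fc, drug = fd)
    if (!is.null(results$synth$doseResponse)) {
      fh <- fitHill(results$synth$doseResponse,
                    fixHillN = cfg$dose_response$fix_hill_n)
      writeFitResult(fh, emit("fit_ic50.json"))
      results$fit$hill <- fh
    }
  })

  if ("infer" %in% cfg$stages) stage("infer", {
    if (is.null(results$synth))
      stop("infer stage requires the synth stage")
    ana <- analyzeStateDependence(results$synth$control,
                                  results$synth$drug,
                                  results$synth$restingBlock,
                                  controlDrift = cfg$control_drift)
    writeShiftAnalysis(ana, emit("shift_analysis.json"))
    results$infer <- ana
  })

  if ("annotate" %in% cfg$stages) stage("annotate", {
    st <- cfg$structure
    if (is.null(st)) stop("annotate stage requires a structure block")
    holo <- readStructure(st$holo)
    rep_ <- interactionReport(
      holo, st$ligand,
      ligandRing = if (length(st$ring_atoms)) st$ring_atoms else NULL,
      contactCutoff = st$contact_cutoff, dMax = st$hbond_dmax,
      angleMin = st$hbond_angle_min,
      centroidMax = st$stack_centroid_max,
      angleMax = st$stack_angle_max)
    writeInteractionReport(rep_, emit("interactions.json"))
    results$annotate <- list(report = rep_)
    if (!is.null(st$apo)) {
      apo <- readStructure(st$apo)
      sup <- superpose(apo, holo, onUnmatched = "drop")
      writeDisplacementTable(sup, emit("displacements.csv"))
      results$annotate$superposition <- sup
    }
  })

  prov <- list(package = "statenav",
               version = as.character(packageVersion("statenav")),
               seed = cfg$seed,
               config = unclass(cfg))
  provPath <- emit("provenance.json")
  jsonlite::write_json(prov, provPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(list(results = results, files = files, config = cfg))
}
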