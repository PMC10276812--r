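## Least-squares curve fitting (Levenberg-Marquardt via minpack.lm).
## Both fits record the objective trace so convergence behaviour can be
## audited, and flag rather than silently return degenerate solutions.

.LM_CONTROL <- function()
  minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10, maxiter = 500)

#' Fit a Boltzmann function to an availability curve
#'
#' Least-squares fit of \eqn{A / (1 + \exp((V - V_{1/2})/k))} to
#' normalized current versus prepulse voltage. The midpoint is
#' initialized where the curve crosses half its maximum (linear
#' interpolation), the slope at 8 mV, the amplitude at the maximum.
#' Slope is bounded to (0.5, 30) mV; fits ending on a bound, failing to
#' converge, or given degenerate input (no spread, no half-maximum
#' crossing) are returned with `converged = FALSE` and a message.
#'
#' @param curve an [AvailabilityCurve-class] with >= 5 points.
#' @return a [BoltzmannFit-class].
#' @examples
#' v <- seq(-130, -20, by = 5)
#' cc <- availabilityCurve(v, boltzmannAvailability(
#'   v, boltzmannParams(-75.2, 7.9)))
#' fit <- fitBoltzmann(cc)
#' vHalf(fit); slopeFactor(fit)
#' @export
fitBoltzmann <- function(curve) {
  stopifnot(is(curve, "AvailabilityCurve"))
  validObject(curve)
  v <- curve@voltage
  y <- curve@availability
  fail <- function(msg)
    new("BoltzmannFit",
        params = boltzmannParams(NA_real_, 1, 1), rss = NA_real_,
        converged = FALSE, message = msg)

  if (diff(range(y)) < 1e-12)
    return(fail("degenerate input: no spread in availability"))
  amp0 <- max(y)
  half <- amp0 / 2
  ord <- order(v)
  vs <- v[ord]; ys <- y[ord]
  cross <- which(diff(ys <= half) != 0)
  v0 <- if (length(cross)) {
    i <- cross[1]
    vs[i] + (half - ys[i]) * (vs[i + 1] - vs[i]) / (ys[i + 1] - ys[i])
  } else NA_real_
  if (!is.finite(v0))
    return(fail("degenerate input: curve never crosses half-maximum"))

  resid <- function(p) y - p[3] / (1 + exp((v - p[1]) / p[2]))
  lower <- c(-Inf, 0.5, 1e-6)
  upper <- c(Inf, 30, Inf)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(vHalf = v0, slope = 8, amplitude = amp0),
                       lower = lower, upper = upper, fn = resid,
                       control = .LM_CONTROL()),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(fail(paste("optimizer error:", conditionMessage(fit))))

  est <- fit$par
  onBound <- est[["slope"]] <= lower[2] + 1e-9 ||
    est[["slope"]] >= upper[2] - 1e-9
  converged <- fit$info %in% 1:4 && !onBound
  se <- tryCatch({
    s <- summary(fit)$coefficients[, "Std. Error"]
    setNames(as.numeric(s), c("vHalf", "slope", "amplitude"))
  }, error = function(e)
    c(vHalf = NA_real_, slope = NA_real_, amplitude = NA_real_))
  new("BoltzmannFit",
      params = boltzmannParams(est[["vHalf"]], est[["slope"]],
                               est[["amplitude"]]),
      rss = fit$deviance, converged = converged, se = se,
      trace = as.numeric(fit$rsstrace),
      message = if (converged) "" else if (onBound)
        "slope at bound" else paste("nls.lm info", fit$info))
}

#' Fit a Hill equation to a dose-response curve
#'
#' Least-squares fit of fractional inhibition
#' \eqn{1 / (1 + (IC_{50}/D)^{n})} versus concentration. IC50 is fitted
#' on a log scale (guaranteeing positivity) and initialized by
#' log-linear interpolation at 50% inhibition; the Hill coefficient is
#' bounded to (0.2, 5) and initialized at 1, or held fixed with
#' `fixHillN`.
#'
#' @param curve a [DoseResponseCurve-class] with >= 3 concentrations.
#' @param fixHillN optional fixed Hill coefficient (e.g. 1); if `NULL`
#'   (default) the coefficient is fitted.
#' @return a [HillFit-class].
#' @examples
#' d <- c(300, 1000, 3000, 10000, 30000)  # nM
#' cur <- doseResponseCurve(d, 1 / (1 + 1820 / d))
#' ic50(fitHill(cur))  # 1820 nM
#' @export
fitHill <- function(curve, fixHillN = NULL) {
  stopifnot(is(curve, "DoseResponseCurve"))
  validObject(curve)
  if (length(curve@conc) < 3L)
    stop("need at least 3 concentrations")
  d <- curve@conc
  y <- curve@inhibition
  fail <- function(msg)
    new("HillFit", ic50 = NA_real_, hillN = NA_real_, rss = NA_real_,
        converged = FALSE, message = msg)
  if (max(y) < 1e-12)
    return(fail("degenerate input: no inhibition at any concentration"))
  if (diff(range(y)) < 1e-12)
    return(fail("degenerate input: no spread in inhibition"))

  ## init log-IC50 by interpolating log-concentration at 50% inhibition
  ord <- order(d)
  ld <- log(d[ord]); ys <- y[ord]
  l0 <- if (any(ys >= 0.5) && any(ys <= 0.5))
    approx(ys, ld, xout = 0.5, ties = mean)$y
  else ld[which.min(abs(ys - 0.5))]

  model <- function(lic50, n) 1 / (1 + exp(n * (lic50 - log(d))))
  if (is.null(fixHillN)) {
    resid <- function(p) y - model(p[1], p[2])
    par0 <- c(lic50 = l0, n = 1)
    lower <- c(-Inf, 0.2); upper <- c(Inf, 5)
  } else {
    stopifnot(is.numeric(fixHillN), fixHillN > 0)
    resid <- function(p) y - model(p[1], fixHillN)
    par0 <- c(lic50 = l0)
    lower <- -Inf; upper <- Inf
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                       fn = resid, control = .LM_CONTROL()),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(fail(paste("optimizer error:", conditionMessage(fit))))

  ic <- exp(fit$par[["lic50"]])
  n <- if (is.null(fixHillN)) fit$par[["n"]] else fixHillN
  onBound <- is.null(fixHillN) &&
    (n <= 0.2 + 1e-9 || n >= 5 - 1e-9)
  converged <- fit$info %in% 1:4 && !onBound
  se <- tryCatch({
    s <- summary(fit)$coefficients[, "Std. Error"]
    c(ic50 = ic * as.numeric(s[1]),   # delta method from log scale
      hillN = if (is.null(fixHillN)) as.numeric(s[2]) else 0)
  }, error = function(e) c(ic50 = NA_real_, hillN = NA_real_))
  new("HillFit", ic50 = ic, hillN = n, rss = fit$deviance,
      converged = converged, se = se,
      trace = as.numeric(fit$rsstrace),
      message = if (converged) "" else if (onBound)
        "Hill coefficient at bound" else paste("nls.lm info", fit$info))
}
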