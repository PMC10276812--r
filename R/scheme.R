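## Six-state Markov scheme of Na_v gating with state-dependent drug
## binding:
##
##      R  <->  IF  <->  IS          (drug-free gating)
##      |        |        |          (binding, on-rate kon*D; off-rates
##      RD <-> IFD  <-> ISD           kon*Kr resp. kon*Ki)
##
## R: resting/closed, IF: fast-inactivated, IS: slow-inactivated;
## D-suffixed states are drug-bound. Slow inactivation is entered via
## IF only. Drug-bound gating uses the same rate law with the midpoint
## shifted by -k*ln(Kr/Ki), which enforces detailed balance around both
## binding cycles by construction.

STATE_LABELS <- c("R", "IF", "IS", "RD", "IFD", "ISD")

#' Construct a kinetic scheme from an explicit rate function
#'
#' Low-level constructor for arbitrary Markov gating schemes; most
#' users want [buildScheme()]. `rateFun(v, drugConc)` must return the
#' infinitesimal generator (ms^-1) over `states` with rows summing to
#' zero.
#'
#' @param states ordered state labels.
#' @param rateFun function(v, drugConc) -> generator matrix.
#' @param conducting labels of states counted as available.
#' @param params optional list of parameters to carry along.
#' @return a [KineticScheme-class].
#' @export
kineticScheme <- function(states, rateFun, conducting = states[1],
                          params = list()) {
  new("KineticScheme", states = states, rateFun = rateFun,
      conducting = conducting, params = params)
}

#' Rate (generator) matrix of a scheme at fixed voltage and drug
#'
#' @param scheme a [KineticScheme-class].
#' @param v membrane voltage (mV).
#' @param drugConc drug concentration (nM).
#' @return the generator matrix Q (ms^-1); `Q[i, j]` is the transition
#'   rate from state i to state j.
#' @export
rateMatrix <- function(scheme, v, drugConc = 0) {
  stopifnot(is(scheme, "KineticScheme"))
  Q <- scheme@rateFun(v, drugConc)
  if (any(!is.finite(Q)))
    stop(sprintf("non-finite rates at V = %g mV, D = %g nM", v, drugConc))
  dimnames(Q) <- list(scheme@states, scheme@states)
  Q
}

#' Build the default six-state gating/binding scheme
#'
#' Constructs the scheme R/IF/IS plus drug-bound counterparts, with
#' single-barrier (exponential) voltage dependence of the R<->IF rates
#' partitioned so that (i) the steady-state availability curve equals
#' the target Boltzmann (`vHalf`, `slope`) exactly, including the
#' series slow-inactivated occupancy, and (ii) the R<->IF relaxation
#' time constant equals `tauFast` at `vFast` and `tauRec` at `vRec`.
#' The voltage-partitioning fraction and the rate prefactor are solved
#' from those two time constants. Drug binding uses a common on-rate to
#' all states; off-rates follow from `kdRest` (resting) and `kdInact`
#' (fast- and slow-inactivated). Drug-bound gating rates are the same
#' rate law with the midpoint shifted by `-slope * log(kdRest/kdInact)`,
#' which makes every closed cycle satisfy detailed balance; one
#' dependent rate per cycle is fixed that way and the result is
#' verified numerically with [checkDetailedBalance()].
#'
#' @param vHalf,slope target availability midpoint (mV) and slope
#'   factor (mV) of the drug-free curve.
#' @param tauFast R<->IF relaxation time constant (ms) at `vFast`.
#' @param vFast voltage for `tauFast` (mV), default -40.
#' @param tauRec R<->IF relaxation time constant (ms) at `vRec`
#'   (recovery from fast inactivation).
#' @param vRec voltage for `tauRec` (mV), default -100.
#' @param tauSlowEntry IF -> IS time constant (ms), voltage-independent.
#' @param tauSlowRec IS -> IF time constant (ms), voltage-independent.
#' @param kdRest,kdInact resting/inactivated dissociation constants
#'   (nM); `kdRest = Inf` disables resting-state binding.
#' @param onRate drug association rate constant, nM^-1 s^-1, common to
#'   all states. The default is calibrated so that a simulated
#'   two-minute application of 300 nM at a -70 mV holding potential
#'   reduces the test-pulse current to 0.29 of control.
#' @param drugBoundConducts if `TRUE`, drug-bound resting channels (RD)
#'   count as available in readouts; default `FALSE` (resting-state
#'   binding blocks current).
#' @param rateOverrides optional named list `"FROM->TO" = function(v,
#'   drugConc)` replacing individual derived rates (expert use; the
#'   detailed-balance check still runs and rejects inconsistent sets).
#' @return a calibrated [KineticScheme-class].
#' @examples
#' sch <- buildScheme()
#' steadyState(sch, v = -75.2, drugConc = 0)[["R"]]  # 0.5 by calibration
#' @export
buildScheme <- function(vHalf = -75.2, slope = 7.9,
                        tauFast = 3, vFast = -40,
                        tauRec = 2, vRec = -100,
                        tauSlowEntry = 2000, tauSlowRec = 200,
                        kdRest = 360, kdInact = 50,
                        onRate = 4.72e-5,
                        drugBoundConducts = FALSE,
                        rateOverrides = list()) {
  stopifnot(slope > 0, tauFast > 0, tauRec > 0, tauSlowEntry > 0,
            tauSlowRec > 0, kdRest > 0, kdInact > 0, onRate >= 0)
  k <- slope
  cIS <- 1 / tauSlowEntry
  dIS <- 1 / tauSlowRec
  ## series IS occupancy would depolarize the observed midpoint; shift
  ## the bare R<->IF midpoint to compensate so the measured curve is
  ## the target Boltzmann exactly
  vhEff <- vHalf + k * log(1 + cIS / dIS)

  ## solve the partitioning fraction delta and prefactor p from the two
  ## relaxation-time targets: 1/tau(V) = p*(e^(delta*x/k)+e^(-(1-delta)*x/k))
  shape <- function(delta, V) {
    x <- V - vhEff
    exp(delta * x / k) + exp(-(1 - delta) * x / k)
  }
  fr <- function(delta) shape(delta, vFast) / shape(delta, vRec) -
    tauRec / tauFast
  sol <- tryCatch(
    uniroot(fr, c(1e-9, 1 - 1e-9), tol = 1e-14),
    error = function(e) stop(
      "cannot realize the requested relaxation-time pair with positive ",
      "single-barrier rates (tauFast at vFast vs tauRec at vRec): ",
      conditionMessage(e)))
  delta <- sol$root
  pref <- 1 / (tauFast * shape(delta, vFast))

  konMs <- onRate / 1000          # nM^-1 ms^-1
  vhDrugEff <- vhEff - k * log(kdRest / kdInact)  # -Inf when kdRest = Inf
  koffRest <- if (is.finite(kdRest)) konMs * kdRest else 0
  bindRest <- if (is.finite(kdRest)) konMs else 0  # kdRest=Inf: RD unreachable

  rates <- list(
    "R->IF"    = function(v, d) pref * exp(delta * (v - vhEff) / k),
    "IF->R"    = function(v, d) pref * exp(-(1 - delta) * (v - vhEff) / k),
    "IF->IS"   = function(v, d) cIS,
    "IS->IF"   = function(v, d) dIS,
    "RD->IFD"  = function(v, d)
      if (is.finite(kdRest)) pref * exp(delta * (v - vhDrugEff) / k) else 0,
    "IFD->RD"  = function(v, d)
      if (is.finite(kdRest))
        pref * exp(-(1 - delta) * (v - vhDrugEff) / k) else 0,
    "IFD->ISD" = function(v, d) cIS,
    "ISD->IFD" = function(v, d) dIS,
    "R->RD"    = function(v, d) bindRest * d,
    "RD->R"    = function(v, d) koffRest,
    "IF->IFD"  = function(v, d) konMs * d,
    "IFD->IF"  = function(v, d) konMs * kdInact,
    "IS->ISD"  = function(v, d) konMs * d,
    "ISD->IS"  = function(v, d) konMs * kdInact)
  if (length(rateOverrides)) {
    bad <- setdiff(names(rateOverrides), names(rates))
    if (length(bad))
      stop("unknown rate override(s): ", paste(bad, collapse = ", "))
    rates[names(rateOverrides)] <- rateOverrides
  }

  rateFun <- function(v, drugConc) {
    Q <- matrix(0, 6L, 6L, dimnames = list(STATE_LABELS, STATE_LABELS))
    for (nm in names(rates)) {
      ft <- strsplit(nm, "->", fixed = TRUE)[[1]]
      Q[ft[1], ft[2]] <- rates[[nm]](v, drugConc)
    }
    diag(Q) <- -rowSums(Q)
    Q
  }

  scheme <- kineticScheme(
    states = STATE_LABELS, rateFun = rateFun,
    conducting = if (drugBoundConducts) c("R", "RD") else "R",
    params = list(vHalf = vHalf, slope = slope, delta = delta,
                  prefactor = pref, vhEff = vhEff,
                  tauFast = tauFast, vFast = vFast,
                  tauRec = tauRec, vRec = vRec,
                  tauSlowEntry = tauSlowEntry, tauSlowRec = tauSlowRec,
                  kdRest = kdRest, kdInact = kdInact, onRate = onRate,
                  drugBoundConducts = drugBoundConducts))
  db <- checkDetailedBalance(scheme, v = c(vRec, vHalf, vFast),
                             drugConc = c(0, 300))
  if (db$maxError > 1e-8)
    stop("detailed balance violated (relative cycle error ",
         format(db$maxError, digits = 3), ") around cycle ", db$worstCycle)
  scheme
}

#' Stationary (equilibrium) occupancy at fixed voltage and drug
#'
#' Solves the null space of the generator's transpose subject to
#' normalization.
#'
#' @inheritParams rateMatrix
#' @return named occupancy vector summing to 1.
#' @export
steadyState <- function(scheme, v, drugConc = 0) {
  Q <- rateMatrix(scheme, v, drugConc)
  n <- nrow(Q)
  ## restrict to states reachable from the first state so schemes with
  ## unreachable components (e.g. drug-bound states at zero on-rate)
  ## still have a well-defined physical stationary distribution
  reach <- rep(FALSE, n); reach[1] <- TRUE
  repeat {
    new <- reach | (reach %*% (Q > 0) > 0)
    if (all(new == reach)) break
    reach <- as.vector(new)
  }
  idx <- which(reach)
  Qr <- Q[idx, idx, drop = FALSE]
  A <- rbind(t(Qr), rep(1, length(idx)))
  pr <- tryCatch(qr.solve(A, c(rep(0, length(idx)), 1)),
                 error = function(e)
                   stop("stationary distribution is not unique ",
                        "(multiple closed communicating classes)"))
  pi <- numeric(n)
  pi[idx] <- pr
  pi[abs(pi) < 1e-15] <- 0
  setNames(pi / sum(pi), scheme@states)
}

#' Propagate an occupancy vector under constant conditions
#'
#' Exact propagation of the linear master equation
#' \eqn{dp/dt = Q^T p} over a constant-voltage interval via the matrix
#' exponential, \eqn{p(t) = \exp(Q^T t)\,p(0)}.
#'
#' @param occupancy named occupancy vector (sums to 1).
#' @param Q generator matrix (ms^-1) from [rateMatrix()].
#' @param t duration (ms, >= 0).
#' @return occupancy vector after `t` ms.
#' @export
propagateOccupancy <- function(occupancy, Q, t) {
  stopifnot(t >= 0)
  if (t == 0) return(occupancy)
  P <- as.matrix(Matrix::expm(Q * t))   # P[i,j] = Pr(j at t | i at 0)
  out <- as.vector(occupancy %*% P)
  setNames(out, colnames(Q))
}

#' Numerical detailed-balance check
#'
#' At each probe voltage and concentration the stationary occupancy is
#' computed and every edge's net flux
#' \eqn{|\pi_i q_{ij} - \pi_j q_{ji}|} is compared (relative to the
#' largest one-way flux). In addition the Kolmogorov cycle criterion is
#' evaluated on every fundamental cycle of the two-way transition
#' graph: the product of forward rates around the cycle must equal the
#' product of reverse rates.
#'
#' @param scheme a [KineticScheme-class].
#' @param v probe voltages (mV).
#' @param drugConc probe concentrations (nM).
#' @return list with `maxError` (largest relative violation over edges
#'   and cycles) and `worstCycle` (human-readable label of the worst
#'   cycle or edge).
#' @export
checkDetailedBalance <- function(scheme, v = c(-100, -70, -40),
                                 drugConc = c(0, 300)) {
  worst <- 0
  worstLab <- "none"
  for (V in v) for (D in drugConc) {
    Q <- rateMatrix(scheme, V, D)
    pi <- steadyState(scheme, V, D)
    n <- nrow(Q)
    fluxScale <- max(abs(pi * Q), 1e-300)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (Q[i, j] == 0 && Q[j, i] == 0) next
      err <- abs(pi[i] * Q[i, j] - pi[j] * Q[j, i]) / fluxScale
      if (err > worst) {
        worst <- err
        worstLab <- sprintf("edge %s<->%s (V=%g, D=%g)",
                            scheme@states[i], scheme@states[j], V, D)
      }
    }
    for (cyc in .fundamentalCycles(Q)) {
      fwd <- rev <- 1
      m <- length(cyc)
      for (s in seq_len(m)) {
        a <- cyc[s]; b <- cyc[if (s == m) 1L else s + 1L]
        fwd <- fwd * Q[a, b]
        rev <- rev * Q[b, a]
      }
      err <- abs(fwd - rev) / max(abs(fwd), abs(rev), 1e-300)
      if (err > worst) {
        worst <- err
        worstLab <- sprintf("cycle %s (V=%g, D=%g)",
                            paste(scheme@states[cyc], collapse = "->"), V, D)
      }
    }
  }
  list(maxError = worst, worstCycle = worstLab)
}

## fundamental cycles of the graph of two-way edges: BFS spanning tree,
## one cycle per non-tree edge (tree path between its endpoints)
.fundamentalCycles <- function(Q) {
  n <- nrow(Q)
  adj <- (Q > 0) & (t(Q) > 0)
  diag(adj) <- FALSE
  parent <- rep(NA_integer_, n)
  seen <- rep(FALSE, n)
  treeEdge <- matrix(FALSE, n, n)
  cycles <- list()
  for (root in seq_len(n)) {
    if (seen[root]) next
    seen[root] <- TRUE
    queue <- root
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (w in which(adj[u, ])) {
        if (!seen[w]) {
          seen[w] <- TRUE
          parent[w] <- u
          treeEdge[u, w] <- treeEdge[w, u] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
  }
  pathToRoot <- function(x) {
    p <- x
    while (!is.na(parent[x])) { x <- parent[x]; p <- c(p, x) }
    p
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (!adj[i, j] || treeEdge[i, j]) next
    pi_ <- pathToRoot(i); pj <- pathToRoot(j)
    common <- intersect(pi_, pj)
    anc <- common[which.min(match(common, pi_))]
    cyc <- c(pi_[seq_len(match(anc, pi_))],
             rev(pj[seq_len(match(anc, pj) - 1L)]))
    cycles[[length(cycles) + 1L]] <- cyc
  }
  cycles
}

#' Availability of an occupancy vector
#'
#' Summed occupancy of the scheme's conducting states.
#'
#' @param occupancy named occupancy vector.
#' @param scheme a [KineticScheme-class].
#' @return fraction in \[0, 1\].
#' @export
availabilityOf <- function(occupancy, scheme) {
  sum(occupancy[scheme@conducting])
}
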