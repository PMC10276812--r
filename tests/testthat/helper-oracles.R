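## Shared helpers: independent oracles and random-instance builders.

## Random reversible Markov scheme built from stationary weights and
## symmetric edge conductances (q_ij = C_ij / pi_i), which satisfies
## detailed balance by construction. Connectivity via a random spanning
## tree plus random extra edges (so non-trivial cycles occur).
randomReversibleScheme <- function(nStates, seed) {
  set.seed(seed)
  pi <- runif(nStates, 0.1, 1)
  pi <- pi / sum(pi)
  C <- matrix(0, nStates, nStates)
  for (i in 2:nStates) {
    j <- sample.int(i - 1L, 1L)
    C[i, j] <- C[j, i] <- runif(1, 0.02, 1)
  }
  for (i in seq_len(nStates - 1)) for (j in (i + 1):nStates) {
    if (C[i, j] == 0 && runif(1) < 0.35)
      C[i, j] <- C[j, i] <- runif(1, 0.02, 1)
  }
  Q <- C / pi
  diag(Q) <- -rowSums(Q)
  kineticScheme(states = paste0("S", seq_len(nStates)),
                rateFun = function(v, d) Q,
                conducting = "S1",
                params = list(pi = pi))
}

## Fine-step explicit integration of the master equation (independent
## of the matrix-exponential path used by the package).
fineStepOccupancy <- function(occ, Q, t) {
  deriv <- function(tt, y, parms) list(as.vector(y %*% Q))
  out <- deSolve::ode(y = occ, times = c(0, t), func = deriv,
                      parms = NULL, method = "ode45",
                      rtol = 1e-10, atol = 1e-12)
  setNames(as.numeric(out[2, -1]), names(occ))
}

## Random proper rotation (QR of a Gaussian matrix, sign-fixed).
randomRotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

## Default synthetic study conditions used across tests.
ctrlParams <- function() boltzmannParams(vHalf = -75.2, slope = 7.9)
defaultModel <- function() stateBindingModel(drugConc = 300, kdRest = 360,
                                             kdInact = 50, slope = 7.9)
vGrid <- function() seq(-130, -20, by = 5)
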