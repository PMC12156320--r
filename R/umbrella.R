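## Umbrella refinement core: harmonic bias potential over normalized
## observable deviations, the k -> weights map, chi^2, and the two KL
## divergence directions. Reduced units throughout: kBT = 1, so the
## exponent of the reweighting map is simply -V(k); only k/kBT is
## identifiable and k absorbs the temperature.

.checkPreconditioned <- function(obs) {
  if (any(obsClass(obs) == "NOE_UPPER") && !isNoePreconditioned(obs))
    ureInputError("ObservableSet contains NOE upper bounds that are not r^-6 preconditioned; call preconditionNoe() first")
}

## signed sigma-normalized deviation (exp - calc)/sigma, per conformer and
## observable; the building block of both the bias potential and chi^2
.signedDeviation <- function(obs) {
  dev <- sweep(-obs@calcMatrix, 2, obs@expValue, "+")
  sweep(dev, 2, obs@sigma, "/")
}

#' Squared normalized deviation matrix
#'
#' Computes `d2[t, i] = ((exp_i - calc[t, i]) / sigma_i)^2`, the
#' dimensionless quadratic term of the harmonic bias potential. For NOE
#' upper bounds (in preconditioned r^-6 space) with `noeOneSided = TRUE`,
#' a conformer that satisfies the bound contributes 0: only violations are
#' penalized.
#'
#' Observables whose calculated values are constant across all conformers
#' produce a warning: their bias contribution is a constant that cancels in
#' the normalization, so they cannot steer the weights (they still count in
#' chi^2).
#'
#' @param obs an [ObservableSet-class]; NOE bounds must be preconditioned.
#' @param noeOneSided logical, default TRUE.
#' @return N x M non-negative matrix.
#' @export
deviationMatrix <- function(obs, noeOneSided = TRUE) {
  .checkPreconditioned(obs)
  dev <- .signedDeviation(obs)
  if (noeOneSided) {
    noe <- obs@obsClass == "NOE_UPPER"
    if (any(noe)) {
      ## preconditioned space: conformer violates its upper distance bound
      ## iff r^-6 < bound^-6, i.e. the signed deviation is positive
      dev[, noe] <- pmax(dev[, noe, drop = FALSE], 0)
    }
  }
  dev * dev
}

#' Harmonic bias potential per conformer
#'
#' `V[t] = sum_i k_i/2 * d2[t, i]` in kBT units: a sum of harmonic wells in
#' the normalized deviation of each observable, with one force-constant-like
#' parameter `k_i` per observable. A large `k_i` makes the reweighting
#' sensitive to disagreement in observable i.
#'
#' @param k numeric force-constant vector, length M (kBT per squared
#'   normalized deviation).
#' @param d2 N x M matrix from [deviationMatrix()].
#' @return numeric length-N potential (kBT).
#' @export
biasPotential <- function(k, d2) {
  k <- as.numeric(k)
  d2 <- as.matrix(d2)
  if (length(k) != ncol(d2))
    ureDimensionError("k has length %d but d2 has %d observable columns",
                      length(k), ncol(d2))
  if (anyNA(k) || any(!is.finite(k)))
    ureInputError("force constants must be finite")
  drop(d2 %*% (k / 2))
}

#' Refined weights from the force-constant vector
#'
#' The umbrella-reweighting identity: `w_t(k) = w0_t exp(-V_t(k)) / Z`,
#' with `Z = sum_t w0_t exp(-V_t(k))`. At `k = 0` the prior is returned
#' exactly; for any finite k the output is strictly positive wherever the
#' prior is. Normalization is log-sum-exp stabilized.
#'
#' @param k numeric force-constant vector, length M.
#' @param prior an [Ensemble-class] (or normalized weights) of initial weights.
#' @param d2 N x M matrix from [deviationMatrix()].
#' @return An [Ensemble-class] of refined weights.
#' @examples
#' d2 <- matrix(c(1, 0), ncol = 1)
#' weightsFromK(2, c(0.5, 0.5), d2)   # (0.2689, 0.7311) = logistic split
#' @export
weightsFromK <- function(k, prior, d2) {
  ids <- if (is(prior, "Ensemble")) prior@conformerIds else NULL
  w0 <- .asWeights(prior)
  if (sum(w0) <= 0) ureInputError("prior has no positive weight")
  v <- biasPotential(k, d2)
  if (length(v) != length(w0))
    ureDimensionError("prior has %d conformers but d2 has %d rows",
                      length(w0), length(v))
  if (all(k == 0)) {
    w <- w0
  } else {
    logw <- ifelse(w0 > 0, log(w0), -Inf) - v
    m <- max(logw)
    u <- exp(logw - m)
    w <- u / sum(u)
  }
  new("Ensemble", weights = w,
      conformerIds = if (is.null(ids)) paste0("c", seq_along(w)) else ids)
}

#' Mean squared sigma-normalized deviation (chi-squared)
#'
#' `chi2 = (1/M) sum_i ((exp_i - <calc_i>_w) / sigma_i)^2`, with the
#' ensemble averages `<calc_i>_w` taken linearly over the (preconditioned)
#' calculated columns. NOE upper bounds enter one-sided by default: a bound
#' contributes only when the ensemble-averaged `r^-6` falls short of
#' `bound^-6`, i.e. when the effective distance exceeds the bound.
#'
#' @param weights an [Ensemble-class] or normalized numeric weights.
#' @param obs an [ObservableSet-class]; NOE bounds must be preconditioned.
#' @param noeOneSided logical, default TRUE.
#' @return scalar chi-squared (dimensionless).
#' @export
chi2 <- function(weights, obs, noeOneSided = TRUE) {
  .checkPreconditioned(obs)
  w <- .asWeights(weights)
  if (length(w) != nrow(obs@calcMatrix))
    ureDimensionError("weights have %d conformers but calcMatrix has %d rows",
                      length(w), nrow(obs@calcMatrix))
  r <- .chi2Residuals(w, obs, noeOneSided)
  mean(r * r)
}

## signed residuals (exp - <calc>_w)/sigma with the one-sided NOE clamp
.chi2Residuals <- function(w, obs, noeOneSided) {
  avg <- drop(crossprod(obs@calcMatrix, w))
  r <- (obs@expValue - avg) / obs@sigma
  if (noeOneSided) {
    noe <- obs@obsClass == "NOE_UPPER"
    if (any(noe)) r[noe] <- pmax(r[noe], 0)
  }
  r
}

.klCore <- function(p, q) {
  pos <- p > 0
  if (any(q[pos] == 0)) return(Inf)
  sum(p[pos] * log(p[pos] / q[pos]))
}

#' Kullback-Leibler divergence, forward direction
#'
#' `D_KL(P || Q) = sum_x P(x) ln(P(x)/Q(x))` in nats, with P the prior and
#' Q the proposal. Minimizing the forward direction is mode-covering: the
#' proposal is pushed to keep probability wherever the prior has any, the
#' behavior chosen as the default regularizer of the refinement.
#'
#' @param prior,proposal [Ensemble-class] objects or normalized weights of
#'   equal length.
#' @return non-negative divergence in nats; `Inf` if the proposal misses
#'   prior support (cannot happen for [weightsFromK()] output at finite k).
#' @export
klForward <- function(prior, proposal) {
  p <- .asWeights(prior)
  q <- .asWeights(proposal)
  if (length(p) != length(q))
    ureDimensionError("distributions differ in length (%d vs %d)",
                      length(p), length(q))
  .klCore(p, q)
}

#' Kullback-Leibler divergence, reverse direction
#'
#' `D_KL(Q || P) = sum_x Q(x) ln(Q(x)/P(x))`: mode-seeking, and the
#' direction underlying the ensemble-preservation diagnostic.
#'
#' @inheritParams klForward
#' @return non-negative divergence in nats.
#' @export
klReverse <- function(proposal, prior) {
  q <- .asWeights(proposal)
  p <- .asWeights(prior)
  if (length(p) != length(q))
    ureDimensionError("distributions differ in length (%d vs %d)",
                      length(p), length(q))
  .klCore(q, p)
}

#' Refinement cost function
#'
#' `cost(k) = theta * D_KL + chi2`, both terms evaluated at the weights
#' produced by [weightsFromK()]. `theta` balances staying close to the
#' prior (large theta) against agreement with experiment (small theta).
#'
#' @param k numeric force-constant vector.
#' @param theta positive regularization strength.
#' @param prior an [Ensemble-class] or normalized weights.
#' @param obs an [ObservableSet-class].
#' @param d2 N x M deviation matrix; computed from `obs` when NULL.
#' @param klDirection `"forward"` (default) or `"reverse"`.
#' @param noeOneSided logical, default TRUE.
#' @return scalar cost.
#' @export
ureCost <- function(k, theta, prior, obs, d2 = NULL,
                    klDirection = c("forward", "reverse"),
                    noeOneSided = TRUE) {
  klDirection <- match.arg(klDirection)
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0)
    ureInputError("theta must be a positive scalar")
  if (is.null(d2)) d2 <- deviationMatrix(obs, noeOneSided)
  w <- weightsFromK(k, prior, d2)
  dkl <- if (klDirection == "forward") klForward(prior, w) else klReverse(w, prior)
  theta * dkl + chi2(w, obs, noeOneSided)
}
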