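## Minimization of cost(k) = theta * D_KL + chi^2 over the M-dimensional
## force-constant vector. Quasi-Newton (BFGS) from k = 0 with analytic
## gradients, so the optimum can never be worse than the unrefined start
## and the result is deterministic for fixed inputs.
##
## Gradient pieces, with <.>_w the average under w(k) and p the prior:
##   d w_t / d k_i           = w_t (  <d2_i>_w - d2[t,i] ) / 2
##   d <c_j>_w / d k_i       = ( <c_j>_w <d2_i>_w - <c_j d2_i>_w ) / 2
##   d chi2 / d k_i          = -(2/M) sum_j (r_j / sigma_j) d<c_j>_w/dk_i
##   d D_fwd / d k_i         = ( <d2_i>_p - <d2_i>_w ) / 2
##   d D_rev / d k_i         = ( <d2_i>_w sum_t w_t l_t - <l d2_i>_w ) / 2,
##                              l_t = ln(w_t / p_t)
## The one-sided NOE clamp zeroes r_j for satisfied bounds, which also
## zeroes its gradient contribution (subgradient at the boundary).

#' Optimize the force-constant vector of an umbrella refinement
#'
#' Minimizes `theta * D_KL(k) + chi2(k)` over the per-observable force
#' constants k, where the weights follow from [weightsFromK()]. Starts at
#' `k = 0` (the unrefined prior) by default, so the optimized cost is never
#' above the initial chi-squared, and uses analytic gradients with a
#' quasi-Newton method; the result is deterministic for fixed inputs.
#'
#' k is unconstrained in sign by default: a negative force constant is
#' admissible to the optimizer but unphysical for an umbrella potential and
#' is reported by the show method. Set `nonNegativeK = TRUE` to constrain
#' k >= 0.
#'
#' @param theta positive regularization strength; large theta keeps the
#'   ensemble near the prior, small theta prioritizes fit to experiment.
#' @param prior an [Ensemble-class] of initial weights.
#' @param obs an [ObservableSet-class] (NOE bounds preconditioned).
#' @param kInit optional numeric start vector (default all zeros).
#' @param klDirection `"forward"` (mode-covering, default) or `"reverse"`.
#' @param noeOneSided logical, default TRUE.
#' @param nonNegativeK logical, constrain k >= 0 (default FALSE).
#' @param reltol relative tolerance on the cost change (default 1e-8).
#' @param maxit iteration cap (default 1000); hitting it flags
#'   `converged = FALSE` and returns the best iterate.
#' @return A [RefinementResult-class].
#' @examples
#' obs <- ObservableSet("o1", "SHIFT", expValue = 1, sigma = 1,
#'                      calcMatrix = matrix(c(0, 1), ncol = 1))
#' optimizeK(0.2, uniformEnsemble(2), obs)
#' @export
optimizeK <- function(theta, prior, obs, kInit = NULL,
                      klDirection = c("forward", "reverse"),
                      noeOneSided = TRUE, nonNegativeK = FALSE,
                      reltol = 1e-8, maxit = 1000) {
  klDirection <- match.arg(klDirection)
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) ||
      theta <= 0)
    ureInputError("theta must be a positive scalar")
  if (!is(prior, "Ensemble")) prior <- Ensemble(prior)
  if (nObservables(obs) < 1L) ureInputError("empty observable set")
  if (nConformers(obs) != nConformers(prior))
    ureDimensionError("prior has %d conformers but calcMatrix has %d rows",
                      nConformers(prior), nConformers(obs))

  d2 <- deviationMatrix(obs, noeOneSided)
  m <- ncol(d2)
  rng <- apply(obs@calcMatrix, 2, function(x) diff(range(x)))
  if (any(rng == 0))
    warning(sprintf("observable(s) %s are constant across conformers: their bias contribution cancels and reweighting cannot improve them (kept in chi2)",
                    paste(obs@labels[rng == 0], collapse = ", ")))
  p <- prior@weights
  cm <- obs@calcMatrix
  sig <- obs@sigma
  expv <- obs@expValue
  noe <- obs@obsClass == "NOE_UPPER" & noeOneSided
  logp <- ifelse(p > 0, log(p), -Inf)
  d2barP <- drop(crossprod(d2, p))

  if (is.null(kInit)) kInit <- rep(0, m)
  kInit <- as.numeric(kInit)
  if (length(kInit) != m)
    ureDimensionError("kInit has length %d, expected %d", length(kInit), m)
  if (nonNegativeK) kInit <- pmax(kInit, 0)

  wOf <- function(k) {
    logw <- logp - drop(d2 %*% (k / 2))
    u <- exp(logw - max(logw))
    u / sum(u)
  }
  resid <- function(w) {
    r <- (expv - drop(crossprod(cm, w))) / sig
    if (any(noe)) r[noe] <- pmax(r[noe], 0)
    r
  }
  fn <- function(k) {
    w <- wOf(k)
    r <- resid(w)
    dkl <- if (klDirection == "forward") .klCore(p, w) else .klCore(w, p)
    theta * dkl + mean(r * r)
  }
  gr <- function(k) {
    w <- wOf(k)
    r <- resid(w)
    d2bar <- drop(crossprod(d2, w))
    cbar <- drop(crossprod(cm, w))
    a <- r / sig
    cross <- crossprod(cm * w, d2)              # M x M: <c_j d2_i>_w
    gChi <- -(1 / m) * (sum(a * cbar) * d2bar - drop(crossprod(cross, a)))
    gKl <- if (klDirection == "forward") {
      (d2barP - d2bar) / 2
    } else {
      l <- ifelse(w > 0, log(w) - logp, 0)
      (d2bar * sum(w * l) - drop(crossprod(d2, w * l))) / 2
    }
    theta * gKl + gChi
  }

  cost0 <- fn(rep(0, m))
  opt <- if (nonNegativeK) {
    stats::optim(kInit, fn, gr, method = "L-BFGS-B", lower = 0,
                 control = list(maxit = maxit,
                                factr = reltol / .Machine$double.eps))
  } else {
    stats::optim(kInit, fn, gr, method = "BFGS",
                 control = list(maxit = maxit, reltol = reltol))
  }
  kHat <- opt$par
  costHat <- opt$value
  if (costHat > cost0) {            # never worse than the unrefined start
    kHat <- rep(0, m)
    costHat <- cost0
  }

  w <- weightsFromK(kHat, prior, d2)
  chi2Init <- chi2(prior, obs, noeOneSided)
  new("RefinementResult",
      kOpt = stats::setNames(kHat, obs@labels), weightsOpt = w,
      chi2Init = chi2Init, chi2Opt = chi2(w, obs, noeOneSided),
      dklForward = klForward(prior, w), dklReverse = klReverse(w, prior),
      cost = costHat,
      ensemblePreservation = ensemblePreservation(w, prior),
      converged = opt$convergence == 0L,
      nIterations = as.integer(opt$counts[["function"]]),
      theta = theta, klDirection = klDirection)
}
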