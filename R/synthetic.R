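## Synthetic validation systems: a dialanine-like phi/psi dihedral-grid
## ensemble with a Gaussian-basin free-energy surface and Boltzmann prior,
## Karplus-type and linear shift-like observables, parameter-recovery
## fixtures with known ground truth, and the three-state classifier used
## for chignolin-style fast folders.

#' Karplus coefficient set
#'
#' Coefficients of the Karplus relation
#' `J = A cos^2(angle + delta) + B cos(angle + delta) + C` linking a
#' three-bond scalar coupling (Hz) to a backbone dihedral (degrees).
#' `delta` is the phase offset between the measured dihedral and the
#' H-N-C-H angle (commonly -60 degrees for 3J(HN,HA) vs phi).
#'
#' @param A,B,C coefficients in Hz.
#' @param delta phase offset in degrees (default 0).
#' @return named list of class `KarplusCoefficients`.
#' @export
karplusCoefficients <- function(A, B, C, delta = 0) {
  stopifnot(is.finite(A), is.finite(B), is.finite(C), is.finite(delta))
  structure(list(A = A, B = B, C = C, delta = delta),
            class = "KarplusCoefficients")
}

#' Three-bond J coupling via the Karplus equation
#'
#' @param angle dihedral angle(s) in degrees (periodic in 360).
#' @param coeffs a [karplusCoefficients()] set.
#' @return coupling constant(s) in Hz.
#' @examples
#' karplusJ3(60, karplusCoefficients(6.51, -1.76, 1.60))   # 2.3475
#' @export
karplusJ3 <- function(angle, coeffs) {
  stopifnot(inherits(coeffs, "KarplusCoefficients"))
  ca <- cos((angle + coeffs$delta) * pi / 180)
  coeffs$A * ca^2 + coeffs$B * ca + coeffs$C
}

## periodic angular difference in degrees, in (-180, 180]
.angDiff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Build a dihedral-grid ensemble with a Gaussian-basin free energy
#'
#' Discretizes the phi/psi plane into bins (default 36 x 36 bins of 10
#' degrees with centers at -175, -165, ..., +175), evaluates a free-energy
#' surface built from periodic Gaussian wells at the bin centers, and
#' Boltzmann-weights the bins into the prior ensemble. Observables are two
#' Karplus-type J couplings (of phi and of psi, with different literature
#' coefficient sets) plus `nObs - 2` linear shift-like functions of the bin
#' centers whose coefficients are drawn from the seeded generator. The
#' experimental values of the returned [ObservableSet-class] are set to the
#' prior's own ensemble averages, so the untouched system has chi2 = 0;
#' [makeRecoveryFixture()] replaces them with values from a known
#' ground-truth reweighting.
#'
#' @param basins list of basins, each `c(phi, psi, depth, width)`: center
#'   in degrees, depth in kBT, isotropic Gaussian width in degrees. A depth
#'   of 0 contributes nothing (a single zero-depth basin gives the flat,
#'   equipotential surface). Default: a dominant beta-sheet-region basin
#'   plus a weaker alpha-region one, dialanine-like.
#' @param nObs number of observables (>= 2, default 12: matches ten
#'   shift-like plus two coupling observables).
#' @param seed integer seed for the observable coefficient draws.
#' @param phiBins,psiBins bin counts (default 36).
#' @param sigmaShift,sigmaJ total uncertainties assigned to the shift-like
#'   (ppm) and coupling (Hz) observables.
#' @return a [GridSystem-class].
#' @export
makeGridSystem <- function(basins = list(c(-155, 150, 4, 35),
                                         c(-75, 140, 2.5, 30)),
                           nObs = 12, seed = 1,
                           phiBins = 36, psiBins = 36,
                           sigmaShift = 0.5, sigmaJ = 0.8) {
  if (length(basins) == 0L)
    ureInputError("at least one basin is required (use depth 0 for a flat surface)")
  if (nObs < 2L) ureInputError("nObs must be >= 2 (two couplings plus shifts)")
  binW <- 360 / phiBins
  phiC <- -180 + binW / 2 + binW * (seq_len(phiBins) - 1)
  binWp <- 360 / psiBins
  psiC <- -180 + binWp / 2 + binWp * (seq_len(psiBins) - 1)
  grid <- expand.grid(phi = phiC, psi = psiC)
  fe <- rep(0, nrow(grid))
  for (b in basins) {
    if (length(b) != 4L || b[4] <= 0)
      ureInputError("each basin must be c(phi, psi, depth, width > 0)")
    dphi <- .angDiff(grid$phi, b[1])
    dpsi <- .angDiff(grid$psi, b[2])
    fe <- fe - b[3] * exp(-(dphi^2 + dpsi^2) / (2 * b[4]^2))
  }
  prior <- Ensemble(normalizeWeights(exp(-(fe - min(fe)))),
                    conformerIds = sprintf("p%+04d_s%+04d",
                                           as.integer(grid$phi),
                                           as.integer(grid$psi)))

  j1 <- karplusCoefficients(6.51, -1.76, 1.60, delta = -60)  # 3J(HN,HA) vs phi
  j2 <- karplusCoefficients(7.09, -1.42, 1.55, delta = -60)
  calc <- matrix(NA_real_, nrow(grid), nObs)
  calc[, 1] <- karplusJ3(grid$phi, j1)
  calc[, 2] <- karplusJ3(grid$psi, j2)
  nShift <- nObs - 2L
  withSeed(seed, {
    a <- stats::runif(nShift, -0.02, 0.02)   # ppm per degree
    b2 <- stats::runif(nShift, -0.02, 0.02)
    c0 <- stats::runif(nShift, 0, 10)        # ppm offset
  })
  for (j in seq_len(nShift))
    calc[, j + 2L] <- c0[j] + a[j] * grid$phi + b2[j] * grid$psi
  labels <- c("J3_phi", "J3_psi",
              if (nShift > 0) sprintf("CS_%02d", seq_len(nShift)))
  obsClassVec <- c("JCOUPLING", "JCOUPLING", rep("SHIFT", nShift))
  sigma <- c(sigmaJ, sigmaJ, rep(sigmaShift, nShift))
  expv <- drop(crossprod(calc, weights(prior)))
  obs <- ObservableSet(labels = labels, obsClass = obsClassVec,
                       expValue = expv, sigma = sigma, calcMatrix = calc,
                       noePreconditioned = TRUE)
  new("GridSystem", phiBins = as.integer(phiBins),
      psiBins = as.integer(psiBins),
      phiCenters = grid$phi, psiCenters = grid$psi,
      freeEnergy = fe, prior = prior, obs = obs)
}

#' @rdname GridSystem-class
#' @param object a `GridSystem`.
#' @export
setGeneric("priorEnsemble", function(object) standardGeneric("priorEnsemble"))

#' @rdname GridSystem-class
#' @export
setMethod("priorEnsemble", "GridSystem", function(object) object@prior)

#' @rdname GridSystem-class
#' @export
setGeneric("observables", function(object) standardGeneric("observables"))

#' @rdname GridSystem-class
#' @export
setMethod("observables", "GridSystem", function(object) object@obs)

setMethod("show", "GridSystem", function(object) {
  cat("GridSystem:", object@phiBins, "x", object@psiBins,
      "dihedral bins,", nObservables(object@obs), "observables\n")
  cat(sprintf("  free energy range [%.2f, %.2f] kBT\n",
              min(object@freeEnergy), max(object@freeEnergy)))
  invisible(object)
})

#' Parameter-recovery fixture with known ground truth
#'
#' Creates "experimental" values from a known reweighting of the grid
#' system's prior: the ground-truth weights are `weightsFromK(kTrue)`
#' (using the grid's self-consistent deviation matrix), the experimental
#' value of each observable is its ensemble average under those weights
#' plus seeded Gaussian noise of standard deviation `noiseSd * sigma_i`.
#' Everything needed to score recovery is returned.
#'
#' @param grid a [GridSystem-class].
#' @param kTrue numeric ground-truth force constants (length M); by default
#'   drawn once from the seeded generator, uniform in `[0.5, 2]`.
#' @param noiseSd noise level as a multiple of each observable's sigma
#'   (default 0.2).
#' @param seed integer seed (noise and default kTrue).
#' @return list with `prior` ([Ensemble-class]), `obs` (an
#'   [ObservableSet-class] carrying the noisy experimental values),
#'   `kTrue`, `weightsTrue` ([Ensemble-class]) and `targets` (the
#'   noise-free ensemble averages under the truth).
#' @export
makeRecoveryFixture <- function(grid, kTrue = NULL, noiseSd = 0.2, seed = 1) {
  stopifnot(is(grid, "GridSystem"))
  if (noiseSd < 0) ureInputError("noiseSd must be >= 0")
  obs0 <- grid@obs
  m <- nObservables(obs0)
  withSeed(seed, {
    if (is.null(kTrue)) kTrue <- stats::runif(m, 0.5, 2)
    noise <- stats::rnorm(m, 0, 1)
  })
  kTrue <- as.numeric(kTrue)
  if (length(kTrue) != m)
    ureDimensionError("kTrue has length %d, expected %d", length(kTrue), m)
  d2 <- deviationMatrix(obs0)
  wTrue <- weightsFromK(kTrue, grid@prior, d2)
  targets <- drop(crossprod(calcMatrix(obs0), weights(wTrue)))
  expv <- targets + noiseSd * sigmas(obs0) * noise
  obs <- ObservableSet(labels = obsLabels(obs0), obsClass = obsClass(obs0),
                       expValue = expv, sigma = obs0@sigma,
                       calcMatrix = calcMatrix(obs0),
                       noePreconditioned = TRUE)
  list(prior = grid@prior, obs = obs, kTrue = kTrue, weightsTrue = wTrue,
       targets = stats::setNames(targets, obsLabels(obs0)))
}

#' Classify a fast-folder conformer into native / misfolded / unfolded
#'
#' Three-state classification for chignolin-like systems: a conformer is
#' unfolded iff its radius of gyration exceeds `rgThreshold` AND its RMSD
#' to the reference structure exceeds `rmsdThreshold` (both conditions,
#' defaults 6.3 and 3.0 Angstrom). Otherwise the backbone region of Gly-7
#' (beta-PR vs alpha-L) decides between native and misfolded through the
#' supplied mapping. The default mapping assigns beta-PR to native; both
#' assignments occur in the folding literature, so the mapping is explicit
#' and configurable rather than hard-wired.
#'
#' @param gly7Region character vector over `"bPR"`, `"aL"` (aliases
#'   `"betaPR"`, `"alphaL"` accepted).
#' @param rg radius of gyration in Angstrom, >= 0.
#' @param rmsd RMSD to the reference structure in Angstrom, >= 0.
#' @param mapping named character vector region -> state.
#' @param rgThreshold,rmsdThreshold unfolded thresholds in Angstrom.
#' @return character vector over `"native"`, `"misfolded"`, `"unfolded"`;
#'   exactly one state per input.
#' @examples
#' classifyChignolinState("bPR", rg = 5.0, rmsd = 1.0)   # native
#' classifyChignolinState("aL",  rg = 7.0, rmsd = 3.5)   # unfolded
#' @export
classifyChignolinState <- function(gly7Region, rg, rmsd,
                                   mapping = c(bPR = "native",
                                               aL = "misfolded"),
                                   rgThreshold = 6.3, rmsdThreshold = 3.0) {
  region <- as.character(gly7Region)
  region[region %in% c("betaPR", "bpr", "BPR")] <- "bPR"
  region[region %in% c("alphaL", "al", "AL")] <- "aL"
  n <- max(length(region), length(rg), length(rmsd))
  region <- rep_len(region, n)
  rg <- rep_len(as.numeric(rg), n)
  rmsd <- rep_len(as.numeric(rmsd), n)
  if (any(rg < 0) || any(rmsd < 0))
    ureDomainError("rg and rmsd must be non-negative")
  unknown <- setdiff(unique(region), names(mapping))
  if (length(unknown))
    ureInputError("unknown Gly-7 region label(s): %s",
                  paste(unknown, collapse = ", "))
  state <- unname(mapping[region])
  state[rg > rgThreshold & rmsd > rmsdThreshold] <- "unfolded"
  state
}
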