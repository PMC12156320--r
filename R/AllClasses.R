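#' @import methods
NULL

.OBS_CLASSES <- c("SHIFT", "JCOUPLING", "NOE_UPPER")

## condition helpers: cmd wrappers map these onto exit codes
ureInputError <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("ure_input_error", "ure_error", "error")))
}

ureDomainError <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("ure_domain_error", "ure_error", "error")))
}

ureDimensionError <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("ure_dimension_error", "ure_error", "error")))
}

#' Ensemble: weighted set of conformers
#'
#' An `Ensemble` holds one statistical weight per conformer, interpreted as
#' the probability that the conformer occurs. Weights are non-negative and
#' sum to one; zero weights are permitted (sparse priors), and the umbrella
#' reweighting map never introduces new zeros on the prior's support.
#'
#' @slot weights numeric, one probability per conformer, sums to 1.
#' @slot conformerIds character labels, same length as `weights`.
#'
#' @seealso [Ensemble()], [normalizeWeights()], [weightsFromK()]
#' @exportClass Ensemble
setClass("Ensemble",
         representation(weights = "numeric", conformerIds = "character"))

setValidity("Ensemble", function(object) {
  w <- object@weights
  if (length(w) < 1L) return("an ensemble needs at least one conformer")
  if (length(object@conformerIds) != length(w))
    return("conformerIds and weights differ in length")
  if (anyNA(w) || any(!is.finite(w))) return("weights must be finite")
  if (any(w < 0)) return("weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-9) return("weights must sum to 1 (within 1e-9)")
  if (anyDuplicated(object@conformerIds)) return("conformer ids must be unique")
  TRUE
})

#' Construct an Ensemble
#'
#' Weights must already be normalized to within 1e-9; they are renormalized
#' exactly on construction (downstream exponentials amplify drift). Use
#' [normalizeWeights()] to turn raw non-negative masses into weights.
#'
#' @param weights numeric vector of probabilities, summing to 1 within 1e-9.
#' @param conformerIds optional character labels (default `"c1"`, `"c2"`, ...).
#' @return An [Ensemble-class] object.
#' @examples
#' Ensemble(c(0.25, 0.25, 0.5))
#' uniformEnsemble(4)
#' @export
Ensemble <- function(weights, conformerIds = NULL) {
  weights <- as.numeric(weights)
  if (length(weights) < 1L)
    ureInputError("an ensemble needs at least one conformer")
  if (anyNA(weights) || any(!is.finite(weights)))
    ureInputError("ensemble weights must be finite")
  if (any(weights < 0))
    ureInputError("ensemble weights must be non-negative")
  s <- sum(weights)
  if (abs(s - 1) > 1e-9)
    ureInputError("ensemble weights must sum to 1 within 1e-9 (got %.12g); use normalizeWeights() for raw masses", s)
  if (is.null(conformerIds))
    conformerIds <- paste0("c", seq_along(weights))
  new("Ensemble", weights = weights / s,
      conformerIds = as.character(conformerIds))
}

#' @rdname Ensemble
#' @param n number of conformers.
#' @export
uniformEnsemble <- function(n, conformerIds = NULL) {
  Ensemble(rep(1 / n, n), conformerIds = conformerIds)
}

#' ObservableSet: experimental observables and their back-calculated values
#'
#' Couples the experimental side of a refinement (per-observable label,
#' class, measured value and total uncertainty sigma) with the calculated
#' side (an N x M matrix of back-calculated values, one row per conformer).
#' Units follow NMR conventions: ppm for chemical shifts, Hz for
#' three-bond J couplings, Angstrom for NOE distance bounds. `sigma` is the
#' total uncertainty (experimental and back-calculation error combined
#' upstream); no error combination happens here.
#'
#' NOE upper bounds must be preconditioned with [preconditionNoe()] (r to
#' r^-6 linearization) before entering the refinement; the
#' `noePreconditioned` flag tracks this.
#'
#' @slot labels character, observable labels (unique).
#' @slot obsClass character, one of `"SHIFT"`, `"JCOUPLING"`, `"NOE_UPPER"`.
#' @slot expValue numeric experimental values.
#' @slot sigma numeric total uncertainties, strictly positive.
#' @slot calcMatrix numeric N x M matrix of back-calculated values.
#' @slot noePreconditioned logical flag, TRUE after r^-6 linearization.
#' @slot metadata list, e.g. original Angstrom-space NOE bounds for reports.
#'
#' @exportClass ObservableSet
setClass("ObservableSet",
         representation(labels = "character", obsClass = "character",
                        expValue = "numeric", sigma = "numeric",
                        calcMatrix = "matrix",
                        noePreconditioned = "logical", metadata = "list"))

setValidity("ObservableSet", function(object) {
  m <- length(object@labels)
  if (m < 1L) return("at least one observable is required")
  if (length(object@obsClass) != m || length(object@expValue) != m ||
      length(object@sigma) != m)
    return("labels, obsClass, expValue and sigma must have equal length")
  if (!all(object@obsClass %in% .OBS_CLASSES))
    return(sprintf("obsClass entries must be one of %s",
                   paste(.OBS_CLASSES, collapse = ", ")))
  if (anyDuplicated(object@labels)) return("observable labels must be unique")
  if (anyNA(object@sigma) || any(!is.finite(object@sigma)) ||
      any(object@sigma <= 0))
    return("sigma must be strictly positive and finite")
  if (anyNA(object@expValue) || any(!is.finite(object@expValue)))
    return("experimental values must be finite")
  cm <- object@calcMatrix
  if (!is.numeric(cm)) return("calcMatrix must be numeric")
  if (ncol(cm) != m) return("calcMatrix must have one column per observable")
  if (nrow(cm) < 1L) return("calcMatrix must have at least one conformer row")
  if (anyNA(cm) || any(!is.finite(cm))) return("calcMatrix must be finite")
  noe <- object@obsClass == "NOE_UPPER"
  if (any(noe)) {
    if (any(object@expValue[noe] <= 0))
      return("NOE upper bounds must be strictly positive")
    if (any(cm[, noe, drop = FALSE] <= 0))
      return("NOE calculated distances must be strictly positive")
  }
  if (length(object@noePreconditioned) != 1L)
    return("noePreconditioned must be a single logical")
  TRUE
})

#' Construct an ObservableSet
#'
#' @param labels character observable labels.
#' @param obsClass character vector over `"SHIFT"`, `"JCOUPLING"`,
#'   `"NOE_UPPER"` (recycled if length one).
#' @param expValue numeric experimental values (NOE: upper distance bounds in
#'   Angstrom before preconditioning).
#' @param sigma numeric total uncertainties, > 0.
#' @param calcMatrix N x M numeric matrix of back-calculated values
#'   (conformers in rows, observables in columns).
#' @param noePreconditioned logical, whether NOE columns are already in
#'   r^-6 space (default FALSE).
#' @param metadata list of free-form metadata.
#' @return An [ObservableSet-class] object.
#' @examples
#' ObservableSet(labels = c("CA_2", "J3_HNHA"),
#'               obsClass = c("SHIFT", "JCOUPLING"),
#'               expValue = c(52.3, 6.1), sigma = c(0.8, 0.7),
#'               calcMatrix = cbind(c(51.9, 53.0), c(5.2, 7.4)))
#' @export
ObservableSet <- function(labels, obsClass, expValue, sigma, calcMatrix,
                          noePreconditioned = FALSE, metadata = list()) {
  calcMatrix <- as.matrix(calcMatrix)
  if (length(obsClass) == 1L) obsClass <- rep(obsClass, length(labels))
  dimnames(calcMatrix) <- list(NULL, as.character(labels))
  new("ObservableSet", labels = as.character(labels),
      obsClass = as.character(obsClass),
      expValue = as.numeric(expValue), sigma = as.numeric(sigma),
      calcMatrix = calcMatrix,
      noePreconditioned = isTRUE(noePreconditioned), metadata = metadata)
}

#' RefinementResult: diagnostics of one umbrella refinement
#'
#' @slot kOpt numeric, optimized per-observable force constants (kBT per
#'   squared normalized deviation; reduced units, kBT = 1).
#' @slot weightsOpt [Ensemble-class], refined weights.
#' @slot chi2Init,chi2Opt numeric, mean squared sigma-normalized deviation
#'   before/after refinement.
#' @slot dklForward,dklReverse numeric, Kullback-Leibler divergences in nats
#'   between prior and refined weights.
#' @slot cost numeric, value of theta * D_KL + chi^2 at the optimum.
#' @slot ensemblePreservation numeric, percent of the prior ensemble
#'   effectively retained (100 = unchanged).
#' @slot converged logical; FALSE when the iteration cap was hit.
#' @slot nIterations integer, objective evaluations used.
#' @slot theta numeric, regularization strength used.
#' @slot klDirection character, "forward" or "reverse".
#' @exportClass RefinementResult
setClass("RefinementResult",
         representation(kOpt = "numeric", weightsOpt = "Ensemble",
                        chi2Init = "numeric", chi2Opt = "numeric",
                        dklForward = "numeric", dklReverse = "numeric",
                        cost = "numeric", ensemblePreservation = "numeric",
                        converged = "logical", nIterations = "integer",
                        theta = "numeric", klDirection = "character"))

#' ThetaScan: cross-validation scan over the regularization strength
#'
#' @slot thetaGrid numeric, ascending positive theta values.
#' @slot scores data.frame with one row per (theta, fold): `theta`, `fold`,
#'   `trainScore`, `valScore`, `ep`.
#' @slot meanTrain,meanVal,sdVal numeric per-theta aggregates across folds.
#' @slot epCurve numeric, mean ensemble preservation per theta (percent).
#' @slot thetaRecommended numeric, selected theta or `NA` when the scan
#'   yields no recommendation (boundary minimum).
#' @slot nFolds integer; @slot seed integer fold-assignment seed.
#' @exportClass ThetaScan
setClass("ThetaScan",
         representation(thetaGrid = "numeric", scores = "data.frame",
                        meanTrain = "numeric", meanVal = "numeric",
                        sdVal = "numeric", epCurve = "numeric",
                        thetaRecommended = "numeric",
                        nFolds = "integer", seed = "integer"))

#' GridSystem: discretized dihedral-grid ensemble with known ground truth
#'
#' A synthetic phi/psi grid system: the two backbone dihedrals are
#' discretized into bins (default 36 x 36 bins of 10 degrees, centers at
#' -175, -165, ..., +175), a free-energy surface built from Gaussian basins
#' is evaluated at the bin centers, and the prior weights follow from the
#' Boltzmann distribution. Observables are Karplus-type J couplings of phi
#' and psi plus linear shift-like functions of the bin centers.
#'
#' @slot phiBins,psiBins integer bin counts.
#' @slot phiCenters,psiCenters numeric per-conformer bin centers (degrees,
#'   length N = phiBins * psiBins).
#' @slot freeEnergy numeric per-conformer free energy (kBT).
#' @slot prior [Ensemble-class] Boltzmann prior.
#' @slot obs [ObservableSet-class] with experimental values set to the
#'   prior's ensemble averages (a self-consistent baseline; see
#'   [makeRecoveryFixture()]).
#' @exportClass GridSystem
setClass("GridSystem",
         representation(phiBins = "integer", psiBins = "integer",
                        phiCenters = "numeric", psiCenters = "numeric",
                        freeEnergy = "numeric", prior = "Ensemble",
                        obs = "ObservableSet"))
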