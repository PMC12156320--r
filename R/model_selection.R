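## Hyper-parameter selection: theta is picked by k-fold cross-validation
## over the observables (not the conformers). For each theta and fold, k is
## optimized on the training observables only, and the resulting weights
## are scored on the held-out observables with a sigmoid validation score:
## 0.5 means no change, below 0.5 means the refinement also improves
## observables it never saw.

## run code under a fixed seed without disturbing the caller's RNG stream
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Sigmoid cross-validation score
#'
#' `sigmoid(ln(chi2 / chi2Init)) = ratio / (1 + ratio)`: maps the
#' chi-squared ratio between refined and unrefined weights into (0, 1).
#' Exactly 0.5 when nothing changed; below 0.5 when the refinement improved
#' agreement; above 0.5 (on validation data) signals possible overfitting.
#' Scale-invariant in chi-squared.
#'
#' @param chi2Current chi-squared under the weights being scored, >= 0
#'   (an exact 0 is floored at a ratio of 1e-12).
#' @param chi2Init chi-squared under the initial weights, > 0.
#' @return score in (0, 1).
#' @examples
#' validationScore(1, 1)            # 0.5
#' validationScore(exp(-1), 1)      # 1/(1+e) ~ 0.269
#' @export
validationScore <- function(chi2Current, chi2Init) {
  if (!is.numeric(chi2Current) || !is.numeric(chi2Init) ||
      anyNA(c(chi2Current, chi2Init)))
    ureInputError("chi-squared values must be numeric")
  if (any(chi2Init <= 0) || any(chi2Current < 0))
    ureDomainError("validation score needs chi2Init > 0 and chi2 >= 0")
  ratio <- pmax(chi2Current / chi2Init, 1e-12)
  ratio / (1 + ratio)
}

#' Ensemble preservation
#'
#' Percent-scale overfitting diagnostic: the effective fraction of the
#' initial ensemble that survives the reweighting, defined as
#' `100 * exp(-D_KL(w || w0))` (reverse direction). Unchanged weights give
#' exactly 100; collapsing all weight onto one of n equally weighted prior
#' conformers gives `100/n`; values near 0 flag an ensemble carried by a
#' very small number of conformers.
#'
#' @param weights refined [Ensemble-class] or normalized weights.
#' @param prior initial [Ensemble-class] or normalized weights.
#' @return percent in (0, 100].
#' @examples
#' ensemblePreservation(rep(0.25, 4), rep(0.25, 4))   # 100
#' ensemblePreservation(c(1, 0, 0, 0), rep(0.25, 4))  # 25
#' @export
ensemblePreservation <- function(weights, prior) {
  100 * exp(-klReverse(weights, prior))
}

#' Build cross-validation folds over observables
#'
#' Splits the M observable indices into training/validation folds. When
#' `valFraction = 1/nFolds` (the default) the validation sets form a random
#' partition, so every observable is held out exactly once; otherwise each
#' fold draws an independent validation subset of size
#' `round(M * valFraction)` (e.g. a 75/25 split with five folds, useful
#' when M is small). Reproducible for a fixed seed.
#'
#' @param M number of observables, >= 2.
#' @param nFolds number of folds, >= 2.
#' @param valFraction fraction held out per fold (default `1/nFolds`).
#' @param seed integer RNG seed for the assignment.
#' @return list of folds, each `list(train = idx, val = idx, seed = seed)`.
#' @export
makeFolds <- function(M, nFolds = 5, valFraction = 1 / nFolds, seed = 1) {
  if (M < 2) ureInputError("at least 2 observables are required to cross-validate")
  if (nFolds < 2 || nFolds > M)
    ureInputError("nFolds must be between 2 and M")
  nVal <- max(1L, round(M * valFraction))
  if (nVal >= M) ureInputError("valFraction leaves no training observables")
  withSeed(seed, {
    if (abs(valFraction - 1 / nFolds) < 1e-12) {
      perm <- sample.int(M)
      groups <- split(perm, rep(seq_len(nFolds), length.out = M))
      lapply(seq_len(nFolds), function(f) {
        val <- sort(groups[[f]])
        list(train = setdiff(seq_len(M), val), val = val, seed = seed)
      })
    } else {
      lapply(seq_len(nFolds), function(f) {
        val <- sort(sample.int(M, nVal))
        list(train = setdiff(seq_len(M), val), val = val, seed = seed)
      })
    }
  })
}

#' Cross-validate the regularization strength theta
#'
#' For every theta on the grid and every fold, optimizes the force
#' constants on the training observables only, then scores the resulting
#' weights on both the training and the held-out observables with
#' [validationScore()], and records the ensemble preservation of the
#' training-data optimization. Successive thetas are warm-started from the
#' previous optimum (descending the grid from the weakest refinement),
#' which changes nothing about the optimum but saves iterations.
#'
#' @param prior an [Ensemble-class] of initial weights.
#' @param obs an [ObservableSet-class].
#' @param thetaGrid ascending positive thetas (default 40 log-spaced points
#'   in `[1e-3, 1e2]`).
#' @param folds fold list from [makeFolds()]; built from `nFolds`,
#'   `valFraction` and `seed` when NULL.
#' @param nFolds,valFraction,seed fold construction parameters (see
#'   [makeFolds()]).
#' @param ... further arguments to [optimizeK()].
#' @return A [ThetaScan-class]; its `thetaRecommended` slot is filled by
#'   [selectTheta()] with the default policy.
#' @export
crossValidateTheta <- function(prior, obs, thetaGrid = defaultThetaGrid(),
                               folds = NULL, nFolds = 5,
                               valFraction = 1 / nFolds, seed = 1, ...) {
  if (length(thetaGrid) < 1L || any(thetaGrid <= 0) ||
      is.unsorted(thetaGrid, strictly = TRUE))
    ureInputError("thetaGrid must be strictly ascending and positive")
  M <- nObservables(obs)
  if (is.null(folds))
    folds <- makeFolds(M, nFolds = nFolds, valFraction = valFraction,
                       seed = seed)
  if (any(vapply(folds, function(f) length(f$train) == 0L, logical(1))))
    ureInputError("a fold has no training observables")

  nT <- length(thetaGrid)
  rows <- vector("list", length(folds) * nT)
  for (f in seq_along(folds)) {
    trainObs <- obs[folds[[f]]$train]
    valObs <- obs[folds[[f]]$val]
    chi2InitTrain <- chi2(prior, trainObs)
    chi2InitVal <- chi2(prior, valObs)
    kPrev <- NULL
    for (j in rev(seq_len(nT))) {     # large theta first: near k = 0
      th <- thetaGrid[j]
      res <- optimizeK(th, prior, trainObs, kInit = kPrev, ...)
      kPrev <- unname(res@kOpt)
      w <- res@weightsOpt
      rows[[(f - 1L) * nT + j]] <- data.frame(
        theta = th, fold = f,
        trainScore = validationScore(res@chi2Opt, chi2InitTrain),
        valScore = validationScore(chi2(w, valObs), chi2InitVal),
        ep = res@ensemblePreservation)
    }
  }
  scores <- do.call(rbind, rows)
  scores <- scores[order(scores$theta, scores$fold), , drop = FALSE]
  rownames(scores) <- NULL
  agg <- function(v, fun) as.numeric(tapply(v, scores$theta, fun))
  scan <- new("ThetaScan", thetaGrid = thetaGrid, scores = scores,
              meanTrain = agg(scores$trainScore, mean),
              meanVal = agg(scores$valScore, mean),
              sdVal = agg(scores$valScore, stats::sd),
              epCurve = agg(scores$ep, mean),
              thetaRecommended = NA_real_,
              nFolds = length(folds), seed = as.integer(seed))
  scan@thetaRecommended <- selectTheta(scan)
  scan
}

#' Default theta grid
#'
#' 40 log-spaced points in `[1e-3, 1e2]`, bracketing the regularization
#' strengths relevant from strong overfitting to no visible reweighting.
#' @param from,to,length grid bounds and size.
#' @export
defaultThetaGrid <- function(from = 1e-3, to = 1e2, length = 40) {
  exp(seq(log(from), log(to), length.out = length))
}

#' Select theta from a cross-validation scan
#'
#' Returns the theta at the minimum of the mean validation-score curve.
#' Thetas whose mean score lies within `tolerance` (relative, default 1%)
#' of the minimum are tied, and the largest tied theta wins (the weaker,
#' more conservative refinement). If the minimum sits at the top of the
#' grid and the curve is not simply flat, there is no interior minimum and
#' `NA` is returned: no recommendation, the refinement should be inspected
#' manually.
#'
#' @param scan a [ThetaScan-class].
#' @param tolerance relative tie tolerance on the mean score (default 0.01).
#' @return selected theta, or `NA_real_` for "no recommendation".
#' @export
selectTheta <- function(scan, tolerance = 0.01) {
  grid <- scan@thetaGrid
  mv <- scan@meanVal
  if (length(grid) == 0L) ureInputError("empty theta grid")
  lo <- min(mv)
  tied <- which(mv <= lo * (1 + tolerance))
  pick <- max(tied)
  if (pick == length(grid)) {
    flat <- max(mv) <= lo * (1 + tolerance)
    if (!flat) return(NA_real_)     # boundary minimum: curve still falling
  }
  grid[pick]
}
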