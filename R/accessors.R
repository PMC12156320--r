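## Generics and accessor methods. Slot access stays internal; user code goes
## through these.

#' @importFrom stats weights
#' @export
setMethod("weights", "Ensemble", function(object, ...) object@weights)

#' @rdname Ensemble
#' @param object an `Ensemble`.
#' @export
setGeneric("conformerIds", function(object) standardGeneric("conformerIds"))

#' @rdname Ensemble
#' @export
setMethod("conformerIds", "Ensemble", function(object) object@conformerIds)

#' @rdname Ensemble
#' @export
setGeneric("nConformers", function(object) standardGeneric("nConformers"))

#' @rdname Ensemble
#' @export
setMethod("nConformers", "Ensemble", function(object) length(object@weights))

#' @export
setMethod("length", "Ensemble", function(x) length(x@weights))

setMethod("show", "Ensemble", function(object) {
  w <- object@weights
  cat("Ensemble with", length(w), "conformers\n")
  cat(sprintf("  weights: min %.3g, max %.3g, effective fraction %.1f%%\n",
              min(w), max(w), 100 * exp(-sum(w[w > 0] * log(w[w > 0] * length(w))))))
  invisible(object)
})

#' @rdname ObservableSet
#' @param object an `ObservableSet`.
#' @export
setGeneric("obsClass", function(object) standardGeneric("obsClass"))

#' @rdname ObservableSet
#' @export
setMethod("obsClass", "ObservableSet", function(object) object@obsClass)

#' @rdname ObservableSet
#' @export
setGeneric("expValues", function(object) standardGeneric("expValues"))

#' @rdname ObservableSet
#' @export
setMethod("expValues", "ObservableSet", function(object) {
  stats::setNames(object@expValue, object@labels)
})

#' @rdname ObservableSet
#' @export
setGeneric("sigmas", function(object) standardGeneric("sigmas"))

#' @rdname ObservableSet
#' @export
setMethod("sigmas", "ObservableSet", function(object) {
  stats::setNames(object@sigma, object@labels)
})

#' @rdname ObservableSet
#' @export
setGeneric("calcMatrix", function(object) standardGeneric("calcMatrix"))

#' @rdname ObservableSet
#' @export
setMethod("calcMatrix", "ObservableSet", function(object) object@calcMatrix)

#' @rdname ObservableSet
#' @export
setGeneric("obsLabels", function(object) standardGeneric("obsLabels"))

#' @rdname ObservableSet
#' @export
setMethod("obsLabels", "ObservableSet", function(object) object@labels)

#' @rdname ObservableSet
#' @export
setGeneric("nObservables", function(object) standardGeneric("nObservables"))

#' @rdname ObservableSet
#' @export
setMethod("nObservables", "ObservableSet", function(object) length(object@labels))

#' @rdname ObservableSet
#' @export
setMethod("nConformers", "ObservableSet", function(object) nrow(object@calcMatrix))

#' @rdname ObservableSet
#' @export
setGeneric("isNoePreconditioned", function(object) standardGeneric("isNoePreconditioned"))

#' @rdname ObservableSet
#' @export
setMethod("isNoePreconditioned", "ObservableSet",
          function(object) object@noePreconditioned)

#' Subset an ObservableSet by observable
#'
#' Selects observables (columns); all conformers are kept. Used by the
#' cross-validation to form training and validation sets.
#'
#' @param x an `ObservableSet`.
#' @param i integer, logical or character index over observables.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "ObservableSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@labels)
  new("ObservableSet", labels = x@labels[i], obsClass = x@obsClass[i],
      expValue = x@expValue[i], sigma = x@sigma[i],
      calcMatrix = x@calcMatrix[, i, drop = FALSE],
      noePreconditioned = x@noePreconditioned, metadata = x@metadata)
})

setMethod("show", "ObservableSet", function(object) {
  cat("ObservableSet:", nObservables(object), "observables x",
      nConformers(object), "conformers\n")
  tab <- table(factor(object@obsClass, levels = .OBS_CLASSES))
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (any(object@obsClass == "NOE_UPPER"))
    cat("  NOE preconditioned (r^-6):", object@noePreconditioned, "\n")
  invisible(object)
})

#' @rdname RefinementResult-class
#' @param object a `RefinementResult`.
#' @export
setGeneric("kOpt", function(object) standardGeneric("kOpt"))

#' @rdname RefinementResult-class
#' @export
setMethod("kOpt", "RefinementResult", function(object) object@kOpt)

#' @rdname RefinementResult-class
#' @export
setGeneric("refinedWeights", function(object) standardGeneric("refinedWeights"))

#' @rdname RefinementResult-class
#' @export
setMethod("refinedWeights", "RefinementResult", function(object) object@weightsOpt)

#' Refinement diagnostics as a named list
#'
#' @param object a [RefinementResult-class] or [ThetaScan-class].
#' @return For a result: named list with `theta`, `chi2Init`, `chi2Opt`,
#'   `dklForward`, `dklReverse`, `cost`, `ensemblePreservation`, `converged`,
#'   `nIterations`. For a scan: the tidy per-fold score table.
#' @export
setGeneric("diagnostics", function(object) standardGeneric("diagnostics"))

#' @rdname diagnostics
#' @export
setMethod("diagnostics", "RefinementResult", function(object) {
  list(theta = object@theta, chi2Init = object@chi2Init,
       chi2Opt = object@chi2Opt, dklForward = object@dklForward,
       dklReverse = object@dklReverse, cost = object@cost,
       ensemblePreservation = object@ensemblePreservation,
       converged = object@converged, nIterations = object@nIterations,
       klDirection = object@klDirection)
})

setMethod("show", "RefinementResult", function(object) {
  cat("Umbrella refinement result (theta =", format(object@theta), ")\n")
  cat(sprintf("  chi2: %.4f -> %.4f\n", object@chi2Init, object@chi2Opt))
  cat(sprintf("  D_KL forward %.4f / reverse %.4f nats; e.p. %.1f%%\n",
              object@dklForward, object@dklReverse,
              object@ensemblePreservation))
  cat(sprintf("  k range [%.3g, %.3g]; converged: %s (%d evaluations)\n",
              min(object@kOpt), max(object@kOpt), object@converged,
              object@nIterations))
  if (any(object@kOpt < 0))
    cat("  note:", sum(object@kOpt < 0),
        "negative force constant(s) - admissible but unphysical\n")
  invisible(object)
})

#' @rdname diagnostics
#' @export
setMethod("diagnostics", "ThetaScan", function(object) object@scores)

#' @rdname ThetaScan-class
#' @param object a `ThetaScan`.
#' @export
setGeneric("thetaRecommended", function(object) standardGeneric("thetaRecommended"))

#' @rdname ThetaScan-class
#' @export
setMethod("thetaRecommended", "ThetaScan", function(object) object@thetaRecommended)

setMethod("show", "ThetaScan", function(object) {
  cat("Theta scan:", length(object@thetaGrid), "grid points in [",
      format(min(object@thetaGrid)), ",", format(max(object@thetaGrid)),
      "],", object@nFolds, "folds\n")
  i <- which.min(object@meanVal)
  cat(sprintf("  min mean validation score %.4f at theta = %.4g\n",
              object@meanVal[i], object@thetaGrid[i]))
  if (is.na(object@thetaRecommended)) {
    cat("  no theta recommendation (boundary minimum); check results carefully\n")
  } else {
    cat("  recommended theta:", format(object@thetaRecommended), "\n")
  }
  invisible(object)
})
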