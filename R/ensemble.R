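## Ensemble-averaging operators. Experimental observables are population
## averages, so back-calculated per-conformer values must be averaged under
## the ensemble weights before any comparison with experiment.

.asWeights <- function(w) {
  if (is(w, "Ensemble")) w <- w@weights
  w <- as.numeric(w)
  if (anyNA(w) || any(!is.finite(w)) || any(w < 0) || abs(sum(w) - 1) > 1e-9)
    ureInputError("weights must be normalized and non-negative")
  w
}

#' Normalize raw masses into ensemble weights
#'
#' Divides a vector of non-negative, finite masses by its sum so that the
#' weights sum to one. Zeros are preserved.
#'
#' @param raw numeric vector of non-negative masses, at least one positive.
#' @return numeric weights, proportional to `raw`, summing to 1.
#' @examples
#' normalizeWeights(c(3, 1))   # 0.75 0.25
#' @export
normalizeWeights <- function(raw) {
  raw <- as.numeric(raw)
  if (length(raw) < 1L) ureInputError("empty weight vector")
  if (anyNA(raw) || any(!is.finite(raw)))
    ureInputError("raw weights must be finite")
  if (any(raw < 0)) ureInputError("raw weights must be non-negative")
  s <- sum(raw)
  if (s <= 0) ureInputError("raw weights must contain at least one positive entry")
  raw / s
}

#' Linear ensemble average
#'
#' The weighted mean sum_t w_t O_t of a per-conformer observable: the
#' quantity compared against a measured chemical shift or J coupling.
#'
#' @param weights an [Ensemble-class] or normalized numeric weights.
#' @param values numeric per-conformer observable values.
#' @return scalar weighted average, within `[min(values), max(values)]`.
#' @examples
#' linearAverage(c(0.25, 0.75), c(0, 4))  # 3
#' @export
linearAverage <- function(weights, values) {
  w <- .asWeights(weights)
  values <- as.numeric(values)
  if (length(values) != length(w))
    ureDimensionError("weights (%d) and values (%d) differ in length",
                      length(w), length(values))
  if (anyNA(values) || any(!is.finite(values)))
    ureInputError("observable values must be finite")
  sum(w * values)
}

#' Effective NOE distance via inverse-power averaging
#'
#' NOE signal intensities fall off with the third or sixth power of the
#' interproton distance, so the ensemble-effective distance compared to an
#' NOE bound is `(sum_t w_t r_t^-p)^(-1/p)` rather than the linear mean.
#' Close conformers dominate: the result never exceeds the linear average.
#'
#' @param weights an [Ensemble-class] or normalized numeric weights.
#' @param distances numeric per-conformer distances in Angstrom, > 0.
#' @param exponent averaging power p, 3 or 6 (default 6).
#' @return scalar effective distance in Angstrom.
#' @examples
#' noeAverage(c(0.5, 0.5), c(2, 4))       # 2.239, pulled toward the close pair
#' @export
noeAverage <- function(weights, distances, exponent = 6) {
  w <- .asWeights(weights)
  distances <- as.numeric(distances)
  if (!exponent %in% c(3, 6))
    ureInputError("NOE averaging exponent must be 3 or 6")
  if (length(distances) != length(w))
    ureDimensionError("weights (%d) and distances (%d) differ in length",
                      length(w), length(distances))
  if (anyNA(distances) || any(!is.finite(distances)) || any(distances <= 0))
    ureDomainError("NOE distances must be strictly positive and finite")
  sum(w * distances^(-exponent))^(-1 / exponent)
}
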