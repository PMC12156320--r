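## Plain-text two-file input convention.
##
## Experimental file: whitespace-delimited, '#' comments, with block
## headers declaring the observable class of the following rows:
##
##   # DATA=SHIFT
##   CA_2   52.30  0.80
##   # DATA=JCOUPLING
##   J_HNHA  6.10  0.70
##   # DATA=NOE_UPPER
##   noe_1   4.00  0.50
##
## Each data row is: label, experimental value, total uncertainty sigma
## (ppm / Hz / Angstrom). sigma is mandatory; it is the combined
## experiment + back-calculation error, combined upstream.
##
## Calculated file: a header row naming the observables, then one row per
## conformer: conformer id followed by M back-calculated values.
##
##   conformer  CA_2  J_HNHA  noe_1
##   c0001      51.9  5.2     3.1

.parseLines <- function(path) {
  if (!file.exists(path)) ureInputError("input file not found: %s", path)
  readLines(path, warn = FALSE)
}

#' Read an experimental-data file
#'
#' Parses the block-structured experimental table (see the package README
#' for the dialect). Every record needs a label, a value and a strictly
#' positive total uncertainty sigma; parse errors report the offending line
#' number.
#'
#' @param path file path.
#' @return data.frame with columns `label`, `obsClass`, `value`, `sigma`,
#'   in file order.
#' @export
readExperimental <- function(path) {
  lines <- .parseLines(path)
  curClass <- NA_character_
  recs <- list()
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[ln])
    if (raw == "") next
    hdr <- regmatches(raw, regexec("^#\\s*DATA\\s*=\\s*(\\S+)\\s*$", raw))[[1]]
    if (length(hdr) == 2L) {
      curClass <- toupper(hdr[2])
      if (!curClass %in% .OBS_CLASSES)
        ureInputError("%s:%d: unknown observable class '%s' (expected %s)",
                      path, ln, hdr[2], paste(.OBS_CLASSES, collapse = "|"))
      next
    }
    if (startsWith(raw, "#")) next
    if (is.na(curClass))
      ureInputError("%s:%d: data row before any '# DATA=<CLASS>' header", path, ln)
    fields <- strsplit(raw, "\\s+")[[1]]
    if (length(fields) != 3L)
      ureInputError("%s:%d: expected 3 columns (label value sigma), found %d",
                    path, ln, length(fields))
    val <- suppressWarnings(as.numeric(fields[2]))
    sig <- suppressWarnings(as.numeric(fields[3]))
    if (is.na(val)) ureInputError("%s:%d: non-numeric value '%s'", path, ln, fields[2])
    if (is.na(sig)) ureInputError("%s:%d: non-numeric sigma '%s'", path, ln, fields[3])
    if (sig <= 0) ureInputError("%s:%d: sigma must be > 0 (got %g)", path, ln, sig)
    if (curClass == "NOE_UPPER" && val <= 0)
      ureInputError("%s:%d: NOE upper bound must be > 0 (got %g)", path, ln, val)
    recs[[length(recs) + 1L]] <- data.frame(
      label = fields[1], obsClass = curClass, value = val, sigma = sig)
  }
  if (length(recs) == 0L)
    ureInputError("%s: no observable records found", path)
  out <- do.call(rbind, recs)
  dup <- out$label[duplicated(out$label)]
  if (length(dup))
    ureInputError("%s: duplicated observable label(s): %s",
                  path, paste(unique(dup), collapse = ", "))
  out
}

#' Read a calculated-observables file
#'
#' Parses the N x M table of back-calculated values and aligns its columns
#' to the label order of the experimental records (column order in the file
#' is free, the set of labels must match exactly).
#'
#' @param path file path.
#' @param records data.frame from [readExperimental()].
#' @return list with `conformerIds` (character, length N) and `calcMatrix`
#'   (N x M numeric, columns ordered as `records$label`).
#' @export
readCalculated <- function(path, records) {
  lines <- .parseLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) < 2L)
    ureInputError("%s: expected a header row and at least one conformer row", path)
  header <- strsplit(trimws(lines[keep[1]]), "\\s+")[[1]]
  cols <- header[-1]
  if (length(cols) != nrow(records) || !setequal(cols, records$label))
    ureInputError("%s: column labels do not match the experimental records (file: %s; expected: %s)",
                  path, paste(cols, collapse = ","),
                  paste(records$label, collapse = ","))
  body <- keep[-1]
  n <- length(body)
  ids <- character(n)
  mat <- matrix(NA_real_, n, length(cols))
  for (i in seq_len(n)) {
    ln <- body[i]
    fields <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(fields) != length(cols) + 1L)
      ureInputError("%s:%d: expected %d columns, found %d",
                    path, ln, length(cols) + 1L, length(fields))
    ids[i] <- fields[1]
    vals <- suppressWarnings(as.numeric(fields[-1]))
    if (anyNA(vals))
      ureInputError("%s:%d: non-numeric calculated value", path, ln)
    mat[i, ] <- vals
  }
  if (anyDuplicated(ids))
    ureInputError("%s: duplicated conformer id(s)", path)
  mat <- mat[, match(records$label, cols), drop = FALSE]
  colnames(mat) <- records$label
  list(conformerIds = ids, calcMatrix = mat)
}

#' Read both input files into an ObservableSet
#'
#' Convenience wrapper: [readExperimental()] + [readCalculated()], then
#' optionally [preconditionNoe()].
#'
#' @param expPath experimental-data file.
#' @param calcPath calculated-observables file.
#' @param precondition apply the r^-6 NOE linearization (default TRUE).
#' @return list with `obs` (an [ObservableSet-class]) and `conformerIds`.
#' @export
readObservables <- function(expPath, calcPath, precondition = TRUE) {
  records <- readExperimental(expPath)
  calc <- readCalculated(calcPath, records)
  obs <- ObservableSet(labels = records$label, obsClass = records$obsClass,
                       expValue = records$value, sigma = records$sigma,
                       calcMatrix = calc$calcMatrix)
  if (precondition) obs <- preconditionNoe(obs)
  list(obs = obs, conformerIds = calc$conformerIds)
}

#' Linearize NOE distance bounds (r to r^-6)
#'
#' NOE-derived distances average as r^-6, not linearly. Raising calculated
#' distances and bounds to the power of minus six makes the observable
#' linear in the weights, so the refinement can treat every observable with
#' the same averaging operator. Uncertainties are mapped by first-order
#' propagation: `sigma' = 6 b^-7 sigma` for a bound b. Non-NOE observables
#' are untouched. The original Angstrom-space bounds are kept in the
#' metadata so reports can print distances.
#'
#' Applying the transform twice would silently square-compress the data, so
#' a second call is an error (the state is tracked on the object).
#'
#' @param obs an [ObservableSet-class] with NOE values in Angstrom.
#' @return the preconditioned [ObservableSet-class].
#' @examples
#' obs <- ObservableSet("noe_1", "NOE_UPPER", expValue = 4, sigma = 0.5,
#'                      calcMatrix = matrix(c(2, 5), ncol = 1))
#' preconditionNoe(obs)   # bound 4^-6, sigma 6 * 4^-7 * 0.5
#' @export
preconditionNoe <- function(obs) {
  if (isNoePreconditioned(obs))
    ureInputError("NOE observables are already preconditioned; refusing to apply r^-6 twice")
  noe <- obs@obsClass == "NOE_UPPER"
  md <- obs@metadata
  if (any(noe)) {
    b <- obs@expValue[noe]
    sig <- obs@sigma[noe]
    cm <- obs@calcMatrix[, noe, drop = FALSE]
    if (any(b <= 0) || any(cm <= 0))
      ureDomainError("NOE distances and bounds must be strictly positive")
    md$noeAngstrom <- list(labels = obs@labels[noe], bound = b, sigma = sig)
    obs@expValue[noe] <- b^(-6)
    obs@sigma[noe] <- 6 * b^(-7) * sig
    obs@calcMatrix[, noe] <- cm^(-6)
  }
  obs@metadata <- md
  obs@noePreconditioned <- TRUE
  validObject(obs)
  obs
}

#' Write refined weights with a diagnostics header
#'
#' Writes a two-column table (conformer id, weight) preceded by commented
#' header lines carrying theta, chi-squared before/after, the KL
#' divergences, the ensemble preservation and the optimized force constant
#' per observable. Weights are written in full precision so read/write
#' round-trips are lossless to 12+ significant digits.
#'
#' @param path output file path.
#' @param ensemble [Ensemble-class] to write (typically the refined weights).
#' @param result optional [RefinementResult-class] for the header.
#' @param extra optional named character vector of extra header fields
#'   (e.g. resolved config, input hashes).
#' @return invisibly, the path.
#' @export
writeWeights <- function(path, ensemble, result = NULL, extra = NULL) {
  stopifnot(is(ensemble, "Ensemble"))
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error"))
    ureInputError("cannot open '%s' for writing", path)
  on.exit(close(con))
  put <- function(x) writeLines(x, con)
  put("# umbrella refinement weights")
  if (!is.null(result)) {
    d <- diagnostics(result)
    put(sprintf("# theta = %.10g", d$theta))
    put(sprintf("# chi2_init = %.10g", d$chi2Init))
    put(sprintf("# chi2_opt = %.10g", d$chi2Opt))
    put(sprintf("# dkl_forward = %.10g", d$dklForward))
    put(sprintf("# dkl_reverse = %.10g", d$dklReverse))
    put(sprintf("# ensemble_preservation = %.10g", d$ensemblePreservation))
    put(sprintf("# converged = %s", d$converged))
    k <- kOpt(result)
    put(sprintf("# k_opt[%s] = %.10g", names(k), k))
  }
  if (!is.null(extra))
    put(sprintf("# %s = %s", names(extra), as.character(extra)))
  w <- weights(ensemble)
  put(sprintf("%s %.17e", conformerIds(ensemble), w))
  invisible(path)
}

#' Read a weights file
#'
#' Reads a two-column (conformer id, weight) table as written by
#' [writeWeights()], ignoring comment lines.
#'
#' @param path file path.
#' @return an [Ensemble-class].
#' @export
readWeights <- function(path) {
  lines <- .parseLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) ureInputError("%s: no weight rows found", path)
  ids <- character(length(keep))
  w <- numeric(length(keep))
  for (i in seq_along(keep)) {
    fields <- strsplit(trimws(lines[keep[i]]), "\\s+")[[1]]
    if (length(fields) != 2L)
      ureInputError("%s:%d: expected 2 columns (conformer weight)",
                    path, keep[i])
    ids[i] <- fields[1]
    w[i] <- suppressWarnings(as.numeric(fields[2]))
    if (is.na(w[i]))
      ureInputError("%s:%d: non-numeric weight", path, keep[i])
  }
  Ensemble(w, conformerIds = ids)
}
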