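## Spectral accuracy: extract the profile mass range window around a
## monoisotopic peak, score candidates by the RMS residual between observed
## and theoretical profiles, and produce the ranked candidate table.

#' Extract the profile mass range window around a monoisotopic peak
#'
#' Cuts the sub-spectrum on `[monoMz + window[1], monoMz + window[2]]`,
#' subtracts a robust baseline (the median of the lowest intensity decile
#' inside the window) and floors the result at zero. The default window
#' (-0.5, +3.5) Da spans the M..M+3 isotopic peaks; narrowing the upper edge
#' (e.g. to +2.5 Da) excludes interference peaks falling near M+3.
#'
#' @param calibrated a calibrated [ProfileSpectrum-class].
#' @param monoMz the monoisotopic m/z to centre on.
#' @param window numeric length-2 offsets in Da, `start < 0 < end`.
#' @return a [ProfileWindow-class].
#' @export
extractWindow <- function(calibrated, monoMz, window = c(-0.5, 3.5)) {
  stopifnot(length(window) == 2L, window[1] < 0, window[2] > 0)
  lo <- monoMz + window[1]
  hi <- monoMz + window[2]
  if (lo < min(calibrated@mz) - 1e-9 || hi > max(calibrated@mz) + 1e-9)
    stop(sprintf("window [%.4f, %.4f] outside the spectrum range", lo, hi),
         call. = FALSE)
  sel <- calibrated@mz >= lo & calibrated@mz <= hi
  mzv <- calibrated@mz[sel]
  inten <- calibrated@intensity[sel]
  if (length(inten)) {
    baseline <- median(inten[inten <= quantile(inten, 0.1)])
    inten <- pmax(inten - baseline, 0)
  }
  new("ProfileWindow", mz = mzv, intensity = inten,
      monoMz = monoMz, window = as.numeric(window))
}

#' Spectral accuracy between an observed window and a theoretical profile
#'
#' Spectral accuracy (SA) quantifies the similarity between the calibrated
#' observed isotope profile and a candidate's theoretical profile:
#' `SA = 100 * (1 - ||o - s*t|| / ||o||)` with `s >= 0` the least-squares
#' scale of the theoretical onto the observed, clipped below at 0. A perfect
#' fit gives 100%; disjoint profiles give 0%. SA is invariant to rescaling
#' either argument.
#'
#' @param observed a [ProfileWindow-class].
#' @param theoretical a [ProfileSpectrum-class] (rendered theoretical
#'   profile); it is interpolated onto the observed grid.
#' @return SA in percent, or `NA` (undefined) for an all-zero observed
#'   window.
#' @export
spectralAccuracy <- function(observed, theoretical) {
  o <- observed@intensity
  if (!length(o) || all(o == 0)) return(NA_real_)
  t <- approx(theoretical@mz, theoretical@intensity, xout = observed@mz,
              rule = 2, yleft = 0, yright = 0)$y
  tt <- sum(t * t)
  s <- if (tt > 0) max(0, sum(o * t) / tt) else 0
  sa <- 100 * (1 - sqrt(sum((o - s * t)^2)) / sqrt(sum(o * o)))
  max(sa, 0)
}

## observed monoisotopic centroid within +-0.3 Th of a candidate's mono m/z
.observedMonoCentroid <- function(spectrum, monoMz, halfwidth = 0.3) {
  sel <- which(spectrum@mz >= monoMz - halfwidth &
               spectrum@mz <= monoMz + halfwidth)
  if (length(sel) < 3L) return(NA_real_)
  apexIdx <- sel[which.max(spectrum@intensity[sel])]
  if (spectrum@intensity[apexIdx] <= 0) return(NA_real_)
  .centroidAt(spectrum@mz, spectrum@intensity, apexIdx)
}

#' Score and rank formula candidates by spectral accuracy
#'
#' For every candidate: computes its theoretical isotope pattern, renders it
#' with the fitted instrument line shape on the observed grid, extracts the
#' profile window at the candidate's own monoisotopic m/z, and computes SA
#' and the mass error from the observed monoisotopic centroid. Candidates
#' are ranked by SA (descending), ties broken by smaller absolute mass
#' error, then by the Hill string; candidates with undefined SA sink to the
#' bottom.
#'
#' @param calibrated the calibrated [ProfileSpectrum-class].
#' @param candidateSet a [CandidateSet-class] from [enumerateCandidates()].
#' @param shape the fitted [PeakShapeModel-class] (or a
#'   [CalibrationModel-class], whose shape is used).
#' @param window profile mass range window, default `c(-0.5, 3.5)` Da.
#' @param prune isotope-pattern pruning threshold.
#' @return the [CandidateSet-class] with `sa`, `rank` and observed-centroid
#'   `deltaMda` filled in, table ordered by rank.
#' @export
rankCandidates <- function(calibrated, candidateSet, shape = peakShapeModel(),
                           window = c(-0.5, 3.5), prune = 1e-8) {
  if (is(shape, "CalibrationModel")) shape <- shape@shape
  tab <- candidateSet@table
  if (!nrow(tab)) stop("empty candidate set", call. = FALSE)
  step <- median(diff(calibrated@mz))
  sa <- numeric(nrow(tab))
  dmObs <- tab$deltaMda
  for (i in seq_len(nrow(tab))) {
    f <- parseFormula(tab$formula[i])
    pat <- isotopePattern(f, prune = prune)
    mono <- pat@mz[1L]
    obs <- extractWindow(calibrated, mono, window)
    theo <- renderProfile(pat, shape, gridStep = step,
                          window = range(obs@mz) + c(-0.2, 0.2))
    ## window the theoretical through the same baseline subtraction as the
    ## observed side, so the lowest-decile estimate (which sits at the
    ## inter-peak tail level, not at zero) cancels instead of biasing the
    ## small isotope peaks
    theoWin <- extractWindow(theo, mono, window)
    sa[i] <- spectralAccuracy(obs, profileSpectrum(theoWin@mz,
                                                   theoWin@intensity))
    cen <- .observedMonoCentroid(calibrated, mono)
    if (!is.na(cen)) dmObs[i] <- massAccuracy(cen, mono)
  }
  tab$sa <- sa
  tab$deltaMda <- dmObs
  ord <- order(-ifelse(is.na(sa), -Inf, sa), abs(tab$deltaMda), tab$formula)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  new("CandidateSet", targetMz = candidateSet@targetMz,
      constraints = candidateSet@constraints, table = tab)
}

#' Rank summary string for a formula of interest
#'
#' @param candidateSet a ranked [CandidateSet-class].
#' @param formula the ion formula string of interest (any parseable
#'   spelling; normalised to Hill notation before lookup).
#' @return a string `"rank/total"` (e.g. `"5/14"`), or `"-/total"` if the
#'   formula is not in the set.
#' @export
candidateSummary <- function(candidateSet, formula) {
  tab <- candidateSet@table
  hill <- formulaString(parseFormula(formula))
  i <- match(hill, tab$formula)
  paste0(if (is.na(i)) "-" else tab$rank[i], "/", nrow(tab))
}

#' Write and read ranked candidate tables
#'
#' `writeCandidateTable()` writes TSV (or JSON with a small header carrying
#' the target m/z and tolerance); `readCandidateTable()` reads the TSV back.
#' A written table read back equals the in-memory table.
#'
#' @param candidateSet a [CandidateSet-class].
#' @param path output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly. `readCandidateTable()` returns a data.frame.
#' @export
writeCandidateTable <- function(candidateSet, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  tab <- candidateSet@table
  if (format == "tsv") {
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(list(target_mz = candidateSet@targetMz,
                              tolerance_mda = candidateSet@constraints@toleranceMda,
                              candidates = tab),
                         path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

#' @rdname writeCandidateTable
#' @export
readCandidateTable <- function(path) {
  read.csv(path, sep = "\t", stringsAsFactors = FALSE)
}
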