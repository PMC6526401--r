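## Theoretical isotope patterns by iterative fine-structure convolution, the
## M..M+3 nominal aggregation used for diagnostics, and rendering of centroid
## patterns into profile spectra under a line-shape model.

## convolve two (mass, prob) distributions, merging peaks closer than mergeTol
.convolve <- function(a, b, prune, mergeTol = 1e-6) {
  mass <- outer(a$mass, b$mass, `+`)
  prob <- outer(a$prob, b$prob, `*`)
  o <- order(mass)
  mass <- as.vector(mass)[o]
  prob <- as.vector(prob)[o]
  ## merge quasi-degenerate masses
  grp <- cumsum(c(TRUE, diff(mass) > mergeTol))
  mass <- as.vector(tapply(mass * prob, grp, sum) / tapply(prob, grp, sum))
  prob <- as.vector(tapply(prob, grp, sum))
  keep <- prob > prune * max(prob)
  list(mass = mass[keep], prob = prob[keep])
}

## distribution of n atoms of one element, by repeated squaring
.elementPower <- function(element, n, prune) {
  iso <- .ISOTOPES[[element]]
  base <- list(mass = iso$mass, prob = iso$abundance)
  out <- NULL
  p <- base
  while (n > 0L) {
    if (n %% 2L == 1L)
      out <- if (is.null(out)) p else .convolve(out, p, prune)
    n <- n %/% 2L
    if (n > 0L) p <- .convolve(p, p, prune)
  }
  out
}

#' Theoretical isotope pattern of an ion
#'
#' Computes the isotopologue distribution of a formula as the convolution of
#' per-element multinomial isotope distributions, pruning peaks below a
#' relative threshold after every convolution step. For charged formulas the
#' m/z axis includes the electron-mass correction.
#'
#' @param ion a [Formula-class] (charged or neutral).
#' @param prune relative abundance threshold in `[0, 1)`; peaks below
#'   `prune * max` are dropped (default `1e-8`).
#' @return an [IsotopePattern-class] with the base peak scaled to 100.
#' @examples
#' isotopePattern(parseFormula("C14H27NO3Na+"))
#' @export
isotopePattern <- function(ion, prune = 1e-8) {
  stopifnot(prune >= 0, prune < 1)
  validObject(ion)
  cnt <- ion@counts
  dist <- NULL
  for (e in names(cnt)) {
    pe <- .elementPower(e, cnt[[e]], prune)
    if (is.null(pe)) next
    dist <- if (is.null(dist)) pe else .convolve(dist, pe, prune)
  }
  z <- ion@charge
  mzv <- if (z == 0L) dist$mass else (dist$mass - z * .ELECTRON_MASS) / abs(z)
  ab <- dist$prob / max(dist$prob) * 100
  keep <- ab > prune * 100
  new("IsotopePattern", mz = mzv[keep], abundance = ab[keep],
      prune = prune, ion = formulaString(ion))
}

#' Aggregate an isotope pattern into nominal M..M+k clusters
#'
#' Sums fine-structure peaks lying within +-0.3 Th of `mono + k` for
#' k = 0..`kMax`, and reports cluster abundances relative to the
#' monoisotopic (M) cluster. These are the M, M+1, M+2, M+3 abundances
#' entering low-resolution isotope-pattern comparisons.
#'
#' @param pattern an [IsotopePattern-class].
#' @param kMax highest cluster index (default 3).
#' @return numeric vector named `M`, `M+1`, ..., with `M = 100`.
#' @examples
#' aggregateNominal(isotopePattern(parseFormula("C14H27NO3Na+")))
#' @export
aggregateNominal <- function(pattern, kMax = 3L) {
  stopifnot(kMax >= 0L)
  mono <- pattern@mz[1L]
  sums <- vapply(0:kMax, function(k) {
    inWin <- abs(pattern@mz - (mono + k)) <= 0.3
    sum(pattern@abundance[inWin])
  }, 0)
  if (sums[1L] <= 0)
    stop("no abundance in the monoisotopic cluster", call. = FALSE)
  setNames(sums / sums[1L] * 100,
           c("M", if (kMax >= 1L) paste0("M+", seq_len(kMax))))
}

#' Render a centroid isotope pattern as a profile spectrum
#'
#' Places a unit-area Gaussian of the model's local FWHM at every centroid,
#' scaled by its abundance, and samples the sum on a uniform grid. The
#' integral of the rendered profile equals the summed abundances (to well
#' under 0.1% at the default 0.01 Th grid).
#'
#' @param pattern an [IsotopePattern-class].
#' @param shape a [PeakShapeModel-class].
#' @param gridStep grid step in Th (default 0.01).
#' @param window numeric length-2 absolute m/z range; defaults to the pattern
#'   span padded by 5 FWHM.
#' @return a [ProfileSpectrum-class]. If the window excludes every centroid a
#'   zero spectrum is returned with `metadata$empty = TRUE` and a warning.
#' @export
renderProfile <- function(pattern, shape = peakShapeModel(),
                          gridStep = 0.01, window = NULL) {
  stopifnot(gridStep > 0)
  if (is.null(window)) {
    pad <- 5 * fwhmAt(shape, max(pattern@mz))
    window <- c(min(pattern@mz) - pad, max(pattern@mz) + pad)
  }
  grid <- seq(window[1], window[2], by = gridStep)
  inten <- numeric(length(grid))
  any_in <- FALSE
  for (i in seq_along(pattern@mz)) {
    mu <- pattern@mz[i]
    if (mu < window[1] || mu > window[2]) next
    any_in <- TRUE
    sigma <- fwhmAt(shape, mu) / (2 * sqrt(2 * log(2)))
    inten <- inten + pattern@abundance[i] *
      stats::dnorm(grid, mean = mu, sd = sigma)
  }
  md <- list(calibrated = TRUE, source = pattern@ion)
  if (!any_in) {
    warning("window excludes all pattern centroids; returning empty spectrum")
    md$empty <- TRUE
  }
  profileSpectrum(grid, inten, metadata = md)
}
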