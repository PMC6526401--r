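## Post-acquisition calibration: locate internal calibrant peaks, fit the
## mass-axis polynomial and the line-shape (FWHM vs m/z) model, and apply the
## fitted map to experimental profile spectra.

## intensity-weighted centroid over the contiguous region above 50% of the
## apex, centred at sample index `apexIdx`
.centroidAt <- function(mzv, inten, apexIdx) {
  half <- inten[apexIdx] / 2
  ## contiguous samples above the half-maximum, expanding only while
  ## descending (2% ripple allowance) so the region cannot bleed across an
  ## inter-peak valley that stays above this peak's half level
  rip <- 0.02 * inten[apexIdx]
  lo <- apexIdx
  while (lo > 1L && inten[lo - 1L] >= half &&
         inten[lo - 1L] <= inten[lo] + rip) lo <- lo - 1L
  hi <- apexIdx
  while (hi < length(inten) && inten[hi + 1L] >= half &&
         inten[hi + 1L] <= inten[hi] + rip) hi <- hi + 1L
  idx <- lo:hi
  idx <- idx[inten[idx] > 0]
  if (length(idx) < 3L) {
    w <- inten[idx]
    return(sum(mzv[idx] * w) / sum(w))
  }
  ## Gaussian vertex by weighted log-parabola: exact for a Gaussian peak
  ## independent of where the grid samples fall; weights ~ intensity^2 keep
  ## the fit anchored to the peak top
  x <- mzv[idx] - mzv[apexIdx]
  fit <- stats::lm.wfit(cbind(1, x, x^2), log(inten[idx]), inten[idx]^2)
  cf <- fit$coefficients
  if (!is.finite(cf[3]) || cf[3] >= 0) {
    w <- inten[idx] - half
    return(sum(mzv[idx] * w) / sum(w))
  }
  vertex <- -cf[2] / (2 * cf[3])
  ## a vertex outside the sampled region signals a degenerate fit
  if (vertex < min(x) || vertex > max(x)) vertex <- 0
  mzv[apexIdx] + vertex
}

#' Locate internal calibrant peaks in a profile spectrum
#'
#' For each expected calibrant m/z, finds the most intense local maximum
#' within `+-searchHalfwidth` and estimates its centroid by a Gaussian
#' vertex fit (log-parabola) over the samples above half of the apex.
#' Calibrants
#' whose apex does not rise above the signal threshold are flagged as missed
#' rather than returned with a spurious position (weak calibrant signals are
#' a known source of large calibrated-mass shifts).
#'
#' @param spectrum a [ProfileSpectrum-class].
#' @param calibrantMz numeric vector of expected calibrant ion m/z values.
#' @param searchHalfwidth half-width of the search window in Th (default 0.5,
#'   wide enough for pre-calibration errors of several hundred mDa).
#' @param signalThreshold minimum apex intensity; the default,
#'   `median + 10 * mad` of the whole spectrum, rejects apexes attributable
#'   to baseline noise.
#' @return data.frame with columns `expected`, `measured`, `apex`, `found`.
#' @export
detectCalibrantPeaks <- function(spectrum, calibrantMz,
                                 searchHalfwidth = 0.5,
                                 signalThreshold = NULL) {
  stopifnot(length(calibrantMz) >= 1L, searchHalfwidth > 0)
  mzv <- spectrum@mz
  inten <- spectrum@intensity
  if (is.null(signalThreshold))
    signalThreshold <- median(inten) + 10 * mad(inten)
  res <- lapply(calibrantMz, function(cm) {
    sel <- which(mzv >= cm - searchHalfwidth & mzv <= cm + searchHalfwidth)
    if (length(sel) < 3L)
      return(data.frame(expected = cm, measured = NA_real_,
                        apex = NA_real_, found = FALSE))
    apexLocal <- sel[which.max(inten[sel])]
    if (inten[apexLocal] < signalThreshold)
      return(data.frame(expected = cm, measured = NA_real_,
                        apex = inten[apexLocal], found = FALSE))
    data.frame(expected = cm,
               measured = .centroidAt(mzv, inten, apexLocal),
               apex = inten[apexLocal], found = TRUE)
  })
  do.call(rbind, res)
}

#' Fit a polynomial mass-axis calibration
#'
#' Least-squares fit of `true ~ measured` with polynomial order
#' `min(n_pairs - 1, 2)`: two calibrants give an affine map, three an exact
#' quadratic interpolation, four or more a least-squares quadratic. Orders
#' above 2 are never used, which avoids overfitting with the three-to-four
#' internal calibrants typical of this workflow.
#'
#' @param measured measured calibrant centroids (Th).
#' @param true corresponding exact ion m/z values (Th).
#' @return a [MassAxisModel-class]; attribute `"residualsMda"` carries the
#'   per-calibrant fit residuals (true - mapped, mDa).
#' @export
fitMassAxis <- function(measured, true) {
  stopifnot(length(measured) == length(true))
  if (length(measured) < 2L)
    stop("at least 2 calibrant pairs are required", call. = FALSE)
  if (anyDuplicated(measured))
    stop("duplicate measured calibrant m/z values", call. = FALSE)
  ord <- min(length(measured) - 1L, 2L)
  fit <- lm(true ~ poly(measured, degree = ord, raw = TRUE))
  cf <- unname(coef(fit))
  cf <- c(cf, rep(0, 3L - length(cf)))
  model <- new("MassAxisModel", coef = cf, range = range(measured))
  err <- validObject(model, test = TRUE)
  if (is.character(err))
    stop("fitted mass-axis map is not monotone over the calibrant span",
         call. = FALSE)
  attr(model, "residualsMda") <-
    (true - applyMassAxis(model, measured)) * 1000
  model
}

#' Fit the instrument line shape from calibrant peaks
#'
#' Estimates each detected calibrant peak's FWHM from the half-maximum
#' crossing points (linear interpolation on both flanks) and fits
#' `FWHM ~ m/z` as a straight line (a constant when only one peak is
#' available).
#'
#' @param spectrum the [ProfileSpectrum-class] the peaks were detected in.
#' @param calibrantPeaks data.frame from [detectCalibrantPeaks()]; only rows
#'   with `found == TRUE` are used.
#' @return a [PeakShapeModel-class]; attribute `"fwhm"` carries the
#'   per-peak estimates.
#' @export
fitLineShape <- function(spectrum, calibrantPeaks) {
  pk <- calibrantPeaks[calibrantPeaks$found, , drop = FALSE]
  if (nrow(pk) < 1L)
    stop("no detected calibrant peaks to fit a line shape on", call. = FALSE)
  mzv <- spectrum@mz
  inten <- spectrum@intensity
  fw <- vapply(pk$measured, function(cm) {
    apexIdx <- which.min(abs(mzv - cm))
    ## re-anchor to the local maximum
    win <- which(mzv >= cm - 1 & mzv <= cm + 1)
    apexIdx <- win[which.max(inten[win])]
    half <- inten[apexIdx] / 2
    rip <- 0.02 * inten[apexIdx]
    lo <- apexIdx
    while (lo > 1L && inten[lo - 1L] >= half &&
           inten[lo - 1L] <= inten[lo] + rip) lo <- lo - 1L
    hi <- apexIdx
    while (hi < length(inten) && inten[hi + 1L] >= half &&
           inten[hi + 1L] <= inten[hi] + rip) hi <- hi + 1L
    if (hi - lo + 1L < 5L)
      stop("fewer than 5 samples above half-maximum at m/z ",
           sprintf("%.3f", cm), "; use a finer grid", call. = FALSE)
    ## interpolated half-max crossings on both flanks
    left <- if (lo > 1L)
      mzv[lo - 1L] + (half - inten[lo - 1L]) / (inten[lo] - inten[lo - 1L]) *
        (mzv[lo] - mzv[lo - 1L]) else mzv[lo]
    right <- if (hi < length(inten))
      mzv[hi] + (inten[hi] - half) / (inten[hi] - inten[hi + 1L]) *
        (mzv[hi + 1L] - mzv[hi]) else mzv[hi]
    right - left
  }, 0)
  if (nrow(pk) == 1L) {
    model <- peakShapeModel(fwhmIntercept = fw, fwhmSlope = 0)
  } else {
    fit <- lm(fw ~ pk$measured)
    model <- peakShapeModel(fwhmIntercept = unname(coef(fit)[1]),
                            fwhmSlope = unname(coef(fit)[2]))
  }
  attr(model, "fwhm") <- data.frame(mz = pk$measured, fwhm = fw)
  model
}

#' Fit a full calibration model from a spectrum and a calibrant list
#'
#' Convenience wrapper: detects the calibrant peaks, fits the mass-axis
#' polynomial on the detected (measured, exact) pairs and the line shape on
#' the detected peaks, and assembles a [CalibrationModel-class].
#'
#' @param spectrum a raw [ProfileSpectrum-class].
#' @param calibrants data.frame with columns `name` and `ion_mz`
#'   (as returned by [calibrantRegistry()]), or a numeric vector of ion m/z.
#' @param searchHalfwidth,signalThreshold passed to [detectCalibrantPeaks()].
#' @return a [CalibrationModel-class].
#' @export
fitCalibration <- function(spectrum, calibrants, searchHalfwidth = 0.5,
                           signalThreshold = NULL) {
  if (is.numeric(calibrants))
    calibrants <- data.frame(name = sprintf("mz%.4f", calibrants),
                             ion_mz = calibrants)
  pk <- detectCalibrantPeaks(spectrum, calibrants$ion_mz,
                             searchHalfwidth = searchHalfwidth,
                             signalThreshold = signalThreshold)
  found <- pk$found
  if (sum(found) < 2L)
    stop("fewer than 2 calibrant peaks detected; cannot calibrate",
         call. = FALSE)
  axis <- fitMassAxis(pk$measured[found], pk$expected[found])
  shape <- fitLineShape(spectrum, pk)
  res <- setNames(as.numeric(attr(axis, "residualsMda")),
                  calibrants$name[found])
  new("CalibrationModel", axis = axis, shape = shape,
      residuals = res, calibrants = calibrants$name[found])
}

#' Apply a calibration model to a profile spectrum
#'
#' Maps the m/z axis through the calibration polynomial, divides intensities
#' by the local Jacobian of the map (so that integrated intensity is
#' conserved), and resamples onto a uniform grid whose step is the median
#' native step. Spectra extending beyond the model's calibrant span are
#' still calibrated but flagged `extrapolated` in the metadata.
#'
#' @param spectrum a raw [ProfileSpectrum-class].
#' @param model a [CalibrationModel-class] (or bare [MassAxisModel-class]).
#' @return the calibrated [ProfileSpectrum-class]
#'   (`metadata$calibrated = TRUE`).
#' @export
calibrateSpectrum <- function(spectrum, model) {
  axis <- if (is(model, "CalibrationModel")) model@axis else model
  mzRaw <- spectrum@mz
  mzCal <- applyMassAxis(axis, mzRaw)
  if (is.unsorted(mzCal, strictly = TRUE))
    stop("calibration map is not monotone over the spectrum range",
         call. = FALSE)
  jac <- axis@coef[2] + 2 * axis@coef[3] * mzRaw
  intenCal <- spectrum@intensity / jac
  step <- median(diff(mzRaw))
  grid <- seq(min(mzCal), max(mzCal), by = step)
  res <- approx(mzCal, intenCal, xout = grid, rule = 2)
  md <- spectrum@metadata
  md$calibrated <- TRUE
  md$extrapolated <- min(mzRaw) < axis@range[1] - 1e-9 ||
    max(mzRaw) > axis@range[2] + 1e-9
  if (md$extrapolated && is.finite(axis@range[1]))
    warning("spectrum extends beyond the calibrant span; ",
            "extrapolating the mass-axis map")
  profileSpectrum(res$x, pmax(res$y, 0), metadata = md)
}

#' Average repeated acquisitions onto a common grid
#'
#' Interpolates every scan onto the grid of the overlapping m/z range and
#' averages the intensities. With n independent-noise scans the noise
#' standard deviation shrinks by about sqrt(n), the reason ~100 acquisitions
#' are routinely averaged per infusion sample.
#'
#' @param spectra list of [ProfileSpectrum-class] with overlapping ranges.
#' @return the averaged [ProfileSpectrum-class].
#' @export
averageAcquisitions <- function(spectra) {
  if (!length(spectra)) stop("empty spectrum list", call. = FALSE)
  if (length(spectra) == 1L) return(spectra[[1L]])
  lo <- max(vapply(spectra, function(s) min(s@mz), 0))
  hi <- min(vapply(spectra, function(s) max(s@mz), 0))
  if (lo >= hi)
    stop("spectra do not share an overlapping m/z range", call. = FALSE)
  ref <- spectra[[1L]]
  grid <- ref@mz[ref@mz >= lo & ref@mz <= hi]
  acc <- rowMeans(vapply(spectra, function(s)
    approx(s@mz, s@intensity, xout = grid, rule = 2)$y,
    numeric(length(grid))))
  md <- ref@metadata
  md$scans <- length(spectra)
  profileSpectrum(grid, acc, metadata = md)
}
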