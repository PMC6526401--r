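#' Formula: an elemental composition with charge
#'
#' Nonnegative element counts plus an integer charge. All mass arithmetic in
#' the package (monoisotopic masses, ion m/z, RDBE, isotope patterns) operates
#' on this class. Construct with [parseFormula()] or [newFormula()].
#'
#' @slot counts named integer vector of element counts (names are element
#'   symbols present in [isotopeTable()]).
#' @slot charge integer charge state; `+1L` for all protonated/sodiated ions
#'   considered here, `0L` for neutrals.
#' @slot label optional free-text provenance label.
#' @export
setClass("Formula", representation(counts = "integer",
                                   charge = "integer",
                                   label = "character"),
         prototype(label = NA_character_))

setValidity("Formula", function(object) {
  cnt <- object@counts
  if (length(cnt) == 0L || all(cnt == 0L))
    return("at least one element count must be > 0")
  if (is.null(names(cnt)) || any(!nzchar(names(cnt))))
    return("counts must be a named vector of element symbols")
  if (any(cnt < 0L)) return("element counts must be nonnegative")
  unknown <- setdiff(names(cnt), names(.ISOTOPES))
  if (length(unknown))
    return(paste0("unknown element symbol: '", unknown[1L], "'"))
  if (length(object@charge) != 1L || is.na(object@charge))
    return("charge must be a single integer")
  TRUE
})

#' AdductSpec: an electrospray adduct definition
#'
#' Describes how a neutral molecule becomes a detected ion: the atoms added
#' and the charge acquired. The built-in registry ([adductRegistry()]) covers
#' `[M+H]+` and `[M+Na]+`, the two species observed in positive-mode ESI of
#' the compound set this package targets.
#'
#' @slot name adduct label, e.g. `"[M+H]+"`.
#' @slot delta named integer vector of atoms added to the neutral composition.
#' @slot chargeDelta integer charge added (+1 for both built-in adducts).
#' @export
setClass("AdductSpec", representation(name = "character",
                                      delta = "integer",
                                      chargeDelta = "integer"))

#' IsotopePattern: centroided theoretical isotope distribution of an ion
#'
#' @slot mz centroid m/z values (Th), strictly ascending.
#' @slot abundance relative abundances, base peak = 100.
#' @slot prune relative pruning threshold used during convolution.
#' @slot ion Hill-notation string of the ion the pattern belongs to.
#' @export
setClass("IsotopePattern", representation(mz = "numeric",
                                          abundance = "numeric",
                                          prune = "numeric",
                                          ion = "character"))

setValidity("IsotopePattern", function(object) {
  if (length(object@mz) != length(object@abundance))
    return("mz and abundance must have equal length")
  if (is.unsorted(object@mz, strictly = TRUE))
    return("centroid m/z values must be strictly ascending")
  if (abs(max(object@abundance) - 100) > 1e-9)
    return("base peak abundance must equal 100")
  if (any(object@abundance <= 0))
    return("all abundances must be positive after pruning")
  TRUE
})

#' ProfileSpectrum: a profile (continuum) mass spectrum
#'
#' An ascending m/z axis with nonnegative intensities, as acquired by a
#' scanning quadrupole in profile mode or rendered from a theoretical
#' pattern.
#'
#' @slot mz m/z axis (Th), strictly ascending, length >= 2.
#' @slot intensity nonnegative finite intensities, same length as `mz`.
#' @slot metadata list; recognised entries include `source`, `scans`,
#'   `calibrated` (logical) and `extrapolated` (logical).
#' @export
setClass("ProfileSpectrum", representation(mz = "numeric",
                                           intensity = "numeric",
                                           metadata = "list"),
         prototype(metadata = list(calibrated = FALSE)))

setValidity("ProfileSpectrum", function(object) {
  if (length(object@mz) < 2L) return("spectrum needs at least 2 samples")
  if (length(object@mz) != length(object@intensity))
    return("mz and intensity must have equal length")
  if (is.unsorted(object@mz, strictly = TRUE))
    return("m/z axis must be strictly ascending")
  if (any(!is.finite(object@intensity)) || any(object@intensity < 0))
    return("intensities must be finite and nonnegative")
  TRUE
})

#' ProfileWindow: a baseline-subtracted sub-spectrum around a monoisotopic peak
#'
#' The profile mass range window over which spectral accuracy is computed,
#' expressed relative to a monoisotopic m/z. The default span (-0.5, +3.5) Da
#' covers the M, M+1, M+2 and M+3 isotopic peaks.
#'
#' @slot mz absolute m/z grid of the extracted window.
#' @slot intensity baseline-subtracted intensities, floored at 0.
#' @slot monoMz the monoisotopic m/z the window is centred on.
#' @slot window numeric length-2, start/end offsets in Da relative to `monoMz`.
#' @export
setClass("ProfileWindow", representation(mz = "numeric",
                                         intensity = "numeric",
                                         monoMz = "numeric",
                                         window = "numeric"))

setValidity("ProfileWindow", function(object) {
  w <- object@window
  if (length(w) != 2L || !(w[1] < 0) || !(w[2] > 0))
    return("window must be c(start, end) with start < 0 < end")
  if (length(object@mz) != length(object@intensity))
    return("mz and intensity must have equal length")
  TRUE
})

#' PeakShapeModel: instrument line-shape model
#'
#' A symmetric Gaussian peak shape whose full width at half maximum varies
#' linearly with m/z: `FWHM(m/z) = a + b * m/z`. The default corresponds to a
#' resolving power of ~500 (e.g. FWHM ~0.44 Th at m/z 222), typical of a
#' triple quadrupole operated in profile mode.
#'
#' @slot shape shape family; only `"gaussian"` is implemented.
#' @slot fwhmCoef numeric length-2 `c(a, b)` of the FWHM line.
#' @export
setClass("PeakShapeModel", representation(shape = "character",
                                          fwhmCoef = "numeric"),
         prototype(shape = "gaussian", fwhmCoef = c(0, 1 / 500)))

setValidity("PeakShapeModel", function(object) {
  if (!identical(object@shape, "gaussian"))
    return("only the 'gaussian' shape family is implemented")
  if (length(object@fwhmCoef) != 2L || any(!is.finite(object@fwhmCoef)))
    return("fwhmCoef must be c(intercept, slope), finite")
  TRUE
})

#' MassAxisModel: polynomial mass-axis calibration map
#'
#' Maps raw (as-acquired) m/z to calibrated m/z through a polynomial of order
#' at most 2. The identity map has coefficients `c(0, 1, 0)`.
#'
#' @slot coef numeric length-3: calibrated = coef[1] + coef[2]*raw + coef[3]*raw^2.
#' @slot range numeric length-2 validity range (span of the calibrant peaks
#'   the model was fitted on).
#' @export
setClass("MassAxisModel", representation(coef = "numeric", range = "numeric"),
         prototype(coef = c(0, 1, 0), range = c(-Inf, Inf)))

setValidity("MassAxisModel", function(object) {
  if (length(object@coef) != 3L || any(!is.finite(object@coef)))
    return("coef must be length 3 and finite")
  if (length(object@range) != 2L || object@range[1] >= object@range[2])
    return("range must be c(lo, hi) with lo < hi")
  ## strictly increasing over the (finite) validity range
  if (all(is.finite(object@range))) {
    g <- seq(object@range[1], object@range[2], length.out = 101L)
    d <- object@coef[2] + 2 * object@coef[3] * g
    if (any(d <= 0)) return("mass-axis map must be strictly increasing over its range")
  }
  TRUE
})

#' CalibrationModel: mass-axis map plus line-shape model
#'
#' The result of fitting internal calibrant peaks: a polynomial mass-axis
#' correction, a fitted instrument line shape, and per-calibrant residuals.
#'
#' @slot axis a [MassAxisModel-class].
#' @slot shape a [PeakShapeModel-class].
#' @slot residuals named numeric, per-calibrant residual (mDa) after the fit.
#' @slot calibrants character, identities of the calibrants used.
#' @export
setClass("CalibrationModel", representation(axis = "MassAxisModel",
                                            shape = "PeakShapeModel",
                                            residuals = "numeric",
                                            calibrants = "character"))

#' SearchConstraints: the formula-search constraint box
#'
#' Element count ranges, mass tolerance, charge, RDBE window and electron
#' configuration that bound the exhaustive candidate enumeration. The
#' defaults of [searchConstraints()] are the constraint set used throughout:
#' C 2-25, H 0-50, N 0-10, O 0-10, Na 0-1, Cl 0-5, tolerance +-10 mDa,
#' charge +1, RDBE -0.5 to 20, even-electron ions only.
#'
#' @slot elements data.frame with columns `element`, `min`, `max`.
#' @slot toleranceMda mass tolerance, mDa (> 0).
#' @slot charge ion charge state.
#' @slot rdbeRange numeric length-2 RDBE window.
#' @slot electrons `"even"`, `"odd"` or `"both"`.
#' @slot maxCandidates cap on the returned set size (guards runaway searches).
#' @export
setClass("SearchConstraints", representation(elements = "data.frame",
                                             toleranceMda = "numeric",
                                             charge = "integer",
                                             rdbeRange = "numeric",
                                             electrons = "character",
                                             maxCandidates = "integer"))

setValidity("SearchConstraints", function(object) {
  el <- object@elements
  if (!all(c("element", "min", "max") %in% names(el)))
    return("elements needs columns element, min, max")
  if (nrow(el) == 0L) return("element box is empty")
  if (any(el$min > el$max)) return("element min must be <= max")
  if (any(el$min < 0)) return("element counts must be nonnegative")
  if (anyDuplicated(el$element)) return("duplicate element in box")
  unknown <- setdiff(el$element, names(.ISOTOPES))
  if (length(unknown)) return(paste0("unknown element symbol: '", unknown[1L], "'"))
  if (object@toleranceMda <= 0) return("tolerance must be > 0")
  if (length(object@rdbeRange) != 2L || object@rdbeRange[1] > object@rdbeRange[2])
    return("rdbeRange must be c(min, max)")
  if (!object@electrons %in% c("even", "odd", "both"))
    return("electrons must be 'even', 'odd' or 'both'")
  TRUE
})

#' CandidateSet: the ranked output of a formula search
#'
#' @slot targetMz the measured m/z searched around.
#' @slot constraints the [SearchConstraints-class] used.
#' @slot table data.frame with one row per candidate ion formula: `formula`,
#'   `exactMz`, `deltaMda`, `rdbe`, and after scoring also `sa` and `rank`.
#' @export
setClass("CandidateSet", representation(targetMz = "numeric",
                                        constraints = "SearchConstraints",
                                        table = "data.frame"))

setValidity("CandidateSet", function(object) {
  tab <- object@table
  need <- c("formula", "exactMz", "deltaMda", "rdbe")
  if (!all(need %in% names(tab)))
    return(paste("table needs columns", paste(need, collapse = ", ")))
  if (anyDuplicated(tab$formula)) return("duplicate candidate formulas")
  ## the tolerance bound applies to the enumeration delta-m; once scored,
  ## deltaMda is recomputed from the observed monoisotopic centroid and may
  ## drift slightly past it
  unscored <- !"sa" %in% names(tab) || all(is.na(tab$sa))
  if (nrow(tab) && unscored &&
      any(abs(tab$deltaMda) > object@constraints@toleranceMda + 1e-9))
    return("candidate outside the mass tolerance")
  TRUE
})

#' SimulationConfig: ground-truth description of a synthetic acquisition
#'
#' Everything needed to render a reproducible synthetic QqQ-like profile
#' spectrum: the species present (ion formulas or fixed-m/z interferences)
#' with relative abundances, the line shape, a polynomial mass-axis
#' distortion, noise and baseline levels, the sampling grid and a seed.
#'
#' @slot species data.frame with columns `formula` (ion formula string or
#'   `NA`), `mz` (fixed m/z for formula-free interference peaks, or `NA`)
#'   and `abundance` (base-peak-relative height).
#' @slot shape a [PeakShapeModel-class].
#' @slot distortion numeric length-3 `c(d0, d1, d2)`; a true peak at m
#'   appears at `m + d0 + d1*m + d2*m^2`. `c(0, 0, 0)` is the identity.
#' @slot noiseSigma standard deviation of additive Gaussian intensity noise.
#' @slot baseline constant baseline level.
#' @slot gridStep m/z grid step (Th).
#' @slot mzRange scan range, default 150-350 Th.
#' @slot seed integer random seed; fixed seed implies a bit-reproducible
#'   spectrum.
#' @export
setClass("SimulationConfig", representation(species = "data.frame",
                                            shape = "PeakShapeModel",
                                            distortion = "numeric",
                                            noiseSigma = "numeric",
                                            baseline = "numeric",
                                            gridStep = "numeric",
                                            mzRange = "numeric",
                                            seed = "integer"))

setValidity("SimulationConfig", function(object) {
  sp <- object@species
  if (!all(c("formula", "mz", "abundance") %in% names(sp)))
    return("species needs columns formula, mz, abundance")
  if (nrow(sp) == 0L) return("at least one species is required")
  if (any(is.na(sp$formula) & is.na(sp$mz)))
    return("each species needs a formula or a fixed m/z")
  if (any(sp$abundance <= 0)) return("species abundances must be > 0")
  if (length(object@distortion) != 3L) return("distortion must be length 3")
  if (object@gridStep <= 0) return("gridStep must be > 0")
  if (length(object@mzRange) != 2L || object@mzRange[1] >= object@mzRange[2])
    return("mzRange must be c(lo, hi)")
  TRUE
})

## ---- show methods -----------------------------------------------------------

setMethod("show", "Formula", function(object) {
  cat("Formula:", formulaString(object), "\n")
  cat("  monoisotopic mass (neutral atoms):",
      sprintf("%.4f Da", monoisotopicMass(object)), "\n")
  if (object@charge != 0L)
    cat("  ion m/z:", sprintf("%.4f Th", .ionMzOfIon(object)), "\n")
  if (!is.na(object@label)) cat("  label:", object@label, "\n")
})

setMethod("show", "IsotopePattern", function(object) {
  cat("IsotopePattern for", object@ion, "-", length(object@mz),
      "centroids (prune", format(object@prune), ")\n")
  show(head(data.frame(mz = round(object@mz, 4),
                       abundance = round(object@abundance, 3)), 8L))
})

setMethod("show", "ProfileSpectrum", function(object) {
  cal <- isTRUE(object@metadata$calibrated)
  cat(sprintf("ProfileSpectrum: %d samples, m/z %.4f-%.4f%s\n",
              length(object@mz), min(object@mz), max(object@mz),
              if (cal) " (calibrated)" else ""))
})

setMethod("show", "CalibrationModel", function(object) {
  cat("CalibrationModel\n")
  cat("  mass axis coef:", format(object@axis@coef, digits = 8), "\n")
  cat("  FWHM model: ", sprintf("%.4g + %.4g * m/z", object@shape@fwhmCoef[1],
                                object@shape@fwhmCoef[2]), "\n")
  cat("  calibrants:", paste(object@calibrants, collapse = ", "), "\n")
  cat("  residuals (mDa):",
      paste(sprintf("%.2f", object@residuals), collapse = ", "),
      sprintf(" (max |r| = %.2f)", max(abs(object@residuals))), "\n")
})

setMethod("show", "CandidateSet", function(object) {
  cat(sprintf("CandidateSet: %d candidates at m/z %.4f (tolerance +-%g mDa)\n",
              nrow(object@table), object@targetMz,
              object@constraints@toleranceMda))
  show(head(object@table, 10L))
})

## ---- accessors --------------------------------------------------------------

#' @describeIn ProfileSpectrum-class m/z axis
#' @param object a `ProfileSpectrum`
#' @export
setMethod("mz", "ProfileSpectrum", function(object) object@mz)

#' @describeIn ProfileSpectrum-class intensity vector
#' @export
setMethod("intensity", "ProfileSpectrum", function(object) object@intensity)

#' @export
setMethod("mz", "IsotopePattern", function(object) object@mz)

#' @export
setMethod("intensity", "IsotopePattern", function(object) object@abundance)

#' @export
setMethod("mz", "ProfileWindow", function(object) object@mz)

#' @export
setMethod("intensity", "ProfileWindow", function(object) object@intensity)

#' @export
setMethod("elementCounts", "Formula", function(object) object@counts)

#' @export
setMethod("ionCharge", "Formula", function(object) object@charge)

#' @export
setMethod("candidates", "CandidateSet", function(object) object@table)

#' @describeIn PeakShapeModel-class FWHM (Th) of the fitted line shape at m/z
#' @param object a `PeakShapeModel`
#' @param mz m/z value(s) at which to evaluate
#' @export
setMethod("fwhmAt", "PeakShapeModel", function(object, mz) {
  object@fwhmCoef[1] + object@fwhmCoef[2] * mz
})

#' @describeIn MassAxisModel-class evaluate the calibration polynomial
#' @param object a `MassAxisModel`
#' @param mz raw m/z value(s)
#' @export
setMethod("applyMassAxis", "MassAxisModel", function(object, mz) {
  object@coef[1] + object@coef[2] * mz + object@coef[3] * mz^2
})

#' Construct a ProfileSpectrum
#'
#' @param mz ascending m/z axis.
#' @param intensity nonnegative intensities.
#' @param metadata optional metadata list.
#' @return a [ProfileSpectrum-class].
#' @export
profileSpectrum <- function(mz, intensity, metadata = list(calibrated = FALSE)) {
  new("ProfileSpectrum", mz = as.numeric(mz), intensity = as.numeric(intensity),
      metadata = metadata)
}

#' Construct a Gaussian peak-shape model
#'
#' @param fwhmIntercept,fwhmSlope coefficients of `FWHM = a + b * m/z` (Th).
#'   The defaults give resolving power 500 at every m/z, e.g. FWHM 0.4444 Th
#'   at m/z 222.2.
#' @return a [PeakShapeModel-class].
#' @export
peakShapeModel <- function(fwhmIntercept = 0, fwhmSlope = 1 / 500) {
  new("PeakShapeModel", shape = "gaussian",
      fwhmCoef = c(fwhmIntercept, fwhmSlope))
}
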