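## Synthetic QqQ-like profile spectra with known ground truth: ion species
## rendered under a line-shape model, polynomial mass-axis distortion,
## constant baseline, seeded Gaussian noise and optional fixed-m/z
## interference peaks. Emulates positive-mode infusion acquisitions at
## resolving power ~500 over a 150-350 Th scan range.

#' Construct a simulation configuration
#'
#' @param species data.frame with columns `formula` (ion formula string, or
#'   `NA` for a formula-free interference peak), `mz` (fixed m/z for
#'   interference peaks, `NA` otherwise) and `abundance` (height of the
#'   species' base isotopologue relative to the most abundant species).
#'   A character vector of ion formulas is also accepted (equal abundances).
#' @param shape a [PeakShapeModel-class]; default resolving power 500.
#' @param distortion numeric `c(d0, d1, d2)`: a true peak at m appears at
#'   `m + d0 + d1*m + d2*m^2` in the raw spectrum. Default: no distortion.
#' @param noiseSigma additive Gaussian noise SD on the intensity axis.
#'   Peaks are rendered with unit area, so the apex height of a species'
#'   base isotopologue is about `100 * abundance * 0.3989 / sigma_peak`
#'   (e.g. ~125 per unit abundance at FWHM 0.44 Th).
#' @param baseline constant baseline level.
#' @param gridStep m/z grid step (Th), default 0.01 (>= 40 samples per FWHM
#'   at resolving power 500).
#' @param mzRange scan range, default `c(150, 350)` Th.
#' @param seed integer seed; a fixed seed makes the spectrum
#'   bit-reproducible.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(species, shape = peakShapeModel(),
                             distortion = c(0, 0, 0), noiseSigma = 0,
                             baseline = 0, gridStep = 0.01,
                             mzRange = c(150, 350), seed = 1L) {
  if (is.character(species))
    species <- data.frame(formula = species, mz = NA_real_, abundance = 1)
  if (!"mz" %in% names(species)) species$mz <- NA_real_
  if (!"abundance" %in% names(species)) species$abundance <- 1
  new("SimulationConfig", species = species, shape = shape,
      distortion = as.numeric(distortion), noiseSigma = as.numeric(noiseSigma),
      baseline = as.numeric(baseline), gridStep = as.numeric(gridStep),
      mzRange = as.numeric(mzRange), seed = as.integer(seed))
}

.distort <- function(config, m) {
  d <- config@distortion
  m + d[1] + d[2] * m + d[3] * m^2
}

#' Simulate a profile spectrum with known ground truth
#'
#' Renders every species' isotope pattern with the configured line shape at
#' mass-axis positions displaced by the distortion polynomial, then adds the
#' baseline and seeded Gaussian noise and clips at zero. With zero noise the
#' output is deterministic and equals the sum of the rendered patterns plus
#' the baseline.
#'
#' @param config a [SimulationConfig-class].
#' @return a raw (uncalibrated) [ProfileSpectrum-class]; metadata element
#'   `truth` records the species table and distortion.
#' @export
simulateSpectrum <- function(config) {
  validObject(config)
  grid <- seq(config@mzRange[1], config@mzRange[2], by = config@gridStep)
  inten <- numeric(length(grid))
  for (i in seq_len(nrow(config@species))) {
    row <- config@species[i, ]
    if (!is.na(row$formula)) {
      pat <- isotopePattern(parseFormula(row$formula))
      centers <- .distort(config, pat@mz)
      heights <- pat@abundance * row$abundance
    } else {
      centers <- .distort(config, row$mz)
      heights <- 100 * row$abundance
    }
    ## the scan range truncates like a real acquisition: losing negligible
    ## isotopologues is fine, losing significant ones is a config error
    out <- centers < config@mzRange[1] | centers > config@mzRange[2]
    if (any(out & heights > 0.005 * max(heights)))
      stop("species ", i, " falls outside the simulated m/z range",
           call. = FALSE)
    centers <- centers[!out]
    heights <- heights[!out]
    ## unit-area peaks, same convention as renderProfile(), so a zero-noise
    ## single-species simulation equals the rendered theoretical profile;
    ## each Gaussian is only evaluated within +-8 sigma of its centre
    for (j in seq_along(centers)) {
      sigma <- fwhmAt(config@shape, centers[j]) / (2 * sqrt(2 * log(2)))
      lo <- findInterval(centers[j] - 8 * sigma, grid) + 1L
      hi <- findInterval(centers[j] + 8 * sigma, grid)
      if (lo > hi) next
      idx <- lo:hi
      inten[idx] <- inten[idx] +
        heights[j] * stats::dnorm(grid[idx], centers[j], sigma)
    }
  }
  inten <- inten + config@baseline
  if (config@noiseSigma > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(config@seed)
    inten <- inten + rnorm(length(inten), sd = config@noiseSigma)
  }
  profileSpectrum(grid, pmax(inten, 0),
                  metadata = list(calibrated = FALSE,
                                  truth = list(species = config@species,
                                               distortion = config@distortion),
                                  seed = config@seed))
}

#' Simulate a series of repeated acquisitions
#'
#' Generates `nScans` independent noise realisations of the same underlying
#' spectrum; per-scan seeds are derived deterministically from the master
#' seed so the whole series is reproducible.
#'
#' @param config a [SimulationConfig-class].
#' @param nScans number of acquisitions (>= 1).
#' @return list of [ProfileSpectrum-class] of length `nScans`.
#' @export
simulateAcquisitionSeries <- function(config, nScans) {
  stopifnot(nScans >= 1L)
  lapply(seq_len(nScans), function(i) {
    cfg <- config
    cfg@seed <- as.integer((as.numeric(config@seed) + i * 9973) %% 2147483647)
    simulateSpectrum(cfg)
  })
}
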