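# single noise-free Gaussian peak spectrum on a 0.01 grid
gaussSpectrum <- function(centers, heights = 100, fwhm = NULL,
                          range = c(150, 350), step = 0.01, baseline = 0) {
  grid <- seq(range[1], range[2], by = step)
  inten <- rep(baseline, length(grid))
  heights <- rep_len(heights, length(centers))
  for (i in seq_along(centers)) {
    fw <- if (is.null(fwhm)) centers[i] / 500 else fwhm
    sigma <- fw / (2 * sqrt(2 * log(2)))
    inten <- inten + heights[i] * exp(-(grid - centers[i])^2 / (2 * sigma^2))
  }
  profileSpectrum(grid, inten)
}

test_that("calibrant peaks are located and centroided correctly", {
  s <- gaussSpectrum(215.0938)
  pk <- detectCalibrantPeaks(s, 215.0938, signalThreshold = 1)
  expect_true(pk$found)
  expect_lt(abs(pk$measured - 215.0938), 0.01)

  ## a +0.350 Th mass-axis offset shifts the centroid by the same amount
  s2 <- gaussSpectrum(215.0938 + 0.350)
  pk2 <- detectCalibrantPeaks(s2, 215.0938, signalThreshold = 1)
  expect_true(pk2$found)
  expect_lt(abs(pk2$measured - (215.0938 + 0.350)), 0.01)

  ## flat noise: every calibrant is flagged missed
  set.seed(3)
  noise <- profileSpectrum(seq(150, 350, 0.01),
                           abs(rnorm(20001, mean = 5)))
  pk3 <- detectCalibrantPeaks(noise, c(200, 250, 300))
  expect_false(any(pk3$found))
})

test_that("mass-axis fitting is exact for affine and quadratic distortions", {
  m <- fitMassAxis(c(200.350, 300.350), c(200.000, 300.000))
  expect_equal(applyMassAxis(m, 250.350), 250.000, tolerance = 1e-9)
  expect_equal(m@coef[3], 0)

  ## known quadratic: raw = true + 0.1 + 5e-4 t + 1e-6 t^2, inverted on 3 pts
  true <- c(200, 260, 320)
  raw <- true + 0.1 + 5e-4 * true + 1e-6 * true^2
  m2 <- fitMassAxis(raw, true)
  probe <- raw[2] + 10
  ## the fitted inverse agrees with numerical inversion of the distortion
  inv <- uniroot(function(t) t + 0.1 + 5e-4 * t + 1e-6 * t^2 - probe,
                 c(200, 330), tol = 1e-12)$root
  expect_equal(applyMassAxis(m2, probe), inv, tolerance = 1e-6)
  expect_lt(max(abs(attr(m2, "residualsMda"))), 1e-6)

  expect_error(fitMassAxis(200.1, 200.0), "at least 2")
  expect_error(fitMassAxis(c(200.1, 200.1), c(200, 201)), "duplicate")
})

test_that("line-shape fitting recovers FWHM and its m/z trend", {
  s <- gaussSpectrum(222, fwhm = 0.44)
  pk <- detectCalibrantPeaks(s, 222, signalThreshold = 1)
  shape <- fitLineShape(s, pk)
  expect_equal(fwhmAt(shape, 222), 0.44, tolerance = 0.02)

  s2 <- gaussSpectrum(c(200, 300), fwhm = NULL)  # FWHM = m/z / 500
  pk2 <- detectCalibrantPeaks(s2, c(200, 300), signalThreshold = 1)
  shape2 <- fitLineShape(s2, pk2)
  expect_equal(shape2@fwhmCoef[2], 0.002, tolerance = 0.05)

  ## coarse grid: too few samples across the peak
  coarse <- profileSpectrum(seq(210, 230, 0.2),
                            100 * exp(-(seq(210, 230, 0.2) - 222)^2 /
                                        (2 * 0.187^2)))
  pkc <- detectCalibrantPeaks(coarse, 222, signalThreshold = 1)
  expect_error(fitLineShape(coarse, pkc), "finer grid")
})

test_that("calibration corrects large mass-axis errors and conserves intensity", {
  ## +381 mDa offset, three calibrants, analyte at 308.2196
  truth <- c(261.0321, 268.1907, 313.1434)
  analyte <- 308.2196
  s <- gaussSpectrum(c(truth, analyte) + 0.381, heights = c(80, 80, 80, 100))
  model <- fitCalibration(s, truth, signalThreshold = 1)
  ## the scan range extends beyond the calibrant span, which is flagged
  cal <- suppressWarnings(calibrateSpectrum(s, model))
  cen <- centroidSpectrum(cal, threshold = 10)
  got <- cen$mz[which.min(abs(cen$mz - analyte))]
  expect_lt(abs(got - analyte) * 1000, 5)

  ## integrated intensity conserved through map + resampling
  expect_equal(sum(intensity(cal)) * median(diff(mz(cal))),
               sum(intensity(s)) * median(diff(mz(s))),
               tolerance = 1e-3)

  ## identity model leaves the spectrum unchanged up to resampling
  ident <- new("MassAxisModel", coef = c(0, 1, 0), range = c(150, 350))
  s0 <- gaussSpectrum(250)
  cal0 <- calibrateSpectrum(s0, ident)
  expect_equal(intensity(cal0), intensity(s0), tolerance = 1e-6)
})

test_that("fit-then-apply inverts a known quadratic distortion within 1 mDa", {
  truth <- c(216.1010, 261.0321, 268.1907, 313.1434)
  raw <- truth + (0.1 + 5e-4 * truth + 1e-6 * truth^2)
  s <- gaussSpectrum(raw, heights = 90)
  model <- fitCalibration(s, truth, signalThreshold = 1)
  ## composed map restores every calibrant across the span
  probes <- seq(min(truth), max(truth), length.out = 9)
  rawProbes <- probes + (0.1 + 5e-4 * probes + 1e-6 * probes^2)
  expect_lt(max(abs(applyMassAxis(model@axis, rawProbes) - probes)) * 1000, 1)
})

test_that("averaging improves SNR by about sqrt(n)", {
  cfg <- simulationConfig(
    data.frame(formula = "C13H20NO+", mz = NA_real_, abundance = 1),
    noiseSigma = 1, baseline = 0, mzRange = c(200, 212), seed = 9L)
  scans <- simulateAcquisitionSeries(cfg, 100)
  avg <- averageAcquisitions(scans)
  ## noise SD measured on a peak-free region
  quiet <- function(s) sd(intensity(s)[mz(s) < 204])
  singleSd <- mean(vapply(scans[1:10], quiet, 0))
  expect_equal(singleSd / quiet(avg), 10, tolerance = 0.35)

  ## identical spectra average to themselves
  s <- gaussSpectrum(250)
  expect_equal(intensity(averageAcquisitions(list(s, s, s))), intensity(s))
  ## disjoint ranges cannot be averaged
  s1 <- gaussSpectrum(200, range = c(190, 210))
  s2 <- gaussSpectrum(300, range = c(290, 310))
  expect_error(averageAcquisitions(list(s1, s2)), "overlap")
  expect_error(averageAcquisitions(list()), "empty")
})
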