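renderedWindow <- function(formula, window = c(-0.5, 3.5), step = 0.01,
                           shape = peakShapeModel()) {
  pat <- isotopePattern(parseFormula(formula))
  mono <- mz(pat)[1]
  prof <- renderProfile(pat, shape, gridStep = step,
                        window = mono + window + c(-0.6, 0.6))
  extractWindow(prof, mono, window)
}

test_that("window extraction spans the requested offsets and subtracts baseline", {
  grid <- seq(275, 290, 0.01)
  inten <- rep(5, length(grid))   # constant background
  inten <- inten + 100 * exp(-(grid - 280.1883)^2 / (2 * 0.24^2)) +
    40 * exp(-(grid - 283.0140)^2 / (2 * 0.24^2))
  s <- profileSpectrum(grid, inten)
  wide <- extractWindow(s, 280.1883, c(-0.5, 3.5))
  expect_equal(range(mz(wide)), c(279.6883, 283.6883), tolerance = 0.011)
  ## the interference apex is inside the wide window ...
  expect_gt(max(intensity(wide)[abs(mz(wide) - 283.0140) < 0.05]), 30)
  ## ... and excluded by the narrow one
  narrow <- extractWindow(s, 280.1883, c(-0.5, 2.5))
  expect_lt(max(mz(narrow)), 282.70)
  ## constant background is removed
  expect_lt(min(intensity(wide)), 0.5)
  ## fully flat region extracts to an all-zero window
  flat <- extractWindow(s, 289, c(-0.5, 0.6))
  expect_true(all(intensity(flat) == 0))
  expect_error(extractWindow(s, 275.2, c(-0.5, 3.5)), "outside")
})

test_that("spectral accuracy anchors: identity 100, disjoint 0, undefined NA", {
  w <- renderedWindow("C13H20NO+")
  self <- profileSpectrum(mz(w), pmax(intensity(w), 0) + 1e-12)
  expect_equal(spectralAccuracy(w, self), 100, tolerance = 1e-6)

  ## disjoint support: optimal scale is 0, SA collapses to 0
  shifted <- profileSpectrum(mz(w) + 50, intensity(w))
  expect_equal(spectralAccuracy(w, shifted), 0)

  empty <- new("ProfileWindow", mz = mz(w), intensity = rep(0, length(mz(w))),
               monoMz = 206.15, window = c(-0.5, 3.5))
  expect_true(is.na(spectralAccuracy(empty, self)))
})

test_that("spectral accuracy is scale invariant in both arguments", {
  w <- renderedWindow("C14H27NO3Na+")
  theo <- profileSpectrum(mz(w), intensity(w) * 0.73 + 0)
  base <- spectralAccuracy(w, theo)
  wScaled <- new("ProfileWindow", mz = mz(w), intensity = intensity(w) * 37,
                 monoMz = w@monoMz, window = w@window)
  expect_equal(spectralAccuracy(wScaled, theo), base, tolerance = 1e-9)
  theoScaled <- profileSpectrum(mz(theo), intensity(theo) * 0.001)
  expect_equal(spectralAccuracy(w, theoScaled), base, tolerance = 1e-9)
})

test_that("zero-intensity padding does not change spectral accuracy", {
  w <- renderedWindow("C13H20NO+")
  theo <- profileSpectrum(mz(w), intensity(w))
  base <- spectralAccuracy(w, theo)
  padded <- new("ProfileWindow",
                mz = c(mz(w), max(mz(w)) + 1:5),
                intensity = c(intensity(w), rep(0, 5)),
                monoMz = w@monoMz, window = w@window)
  expect_equal(spectralAccuracy(padded, theo), base, tolerance = 1e-9)
})

test_that("an added disjoint interference strictly lowers spectral accuracy", {
  w <- renderedWindow("C14H27NO3Na+")
  theo <- profileSpectrum(mz(w), intensity(w))
  clean <- spectralAccuracy(w, theo)
  bump <- 20 * exp(-(mz(w) - 283.0140)^2 / (2 * 0.24^2))
  dirty <- new("ProfileWindow", mz = mz(w), intensity = intensity(w) + bump,
               monoMz = w@monoMz, window = w@window)
  expect_lt(spectralAccuracy(dirty, theo), clean)
})

test_that("SA degrades monotonically with noise amplitude", {
  w <- renderedWindow("C13H20NO+")
  theo <- profileSpectrum(mz(w), intensity(w))
  set.seed(17)
  noise <- rnorm(length(mz(w)))
  sas <- vapply(c(0, 1, 3, 8, 20), function(amp) {
    noisy <- new("ProfileWindow", mz = mz(w),
                 intensity = pmax(intensity(w) + amp * noise, 0),
                 monoMz = w@monoMz, window = w@window)
    spectralAccuracy(noisy, theo)
  }, 0)
  expect_false(is.unsorted(rev(sas), strictly = TRUE))
})

test_that("on noise-free synthetic data the generating formula attains maximal SA", {
  shape <- peakShapeModel()
  for (f in compoundIons[c("B", "C", "F")]) {
    hill <- formulaString(parseFormula(f))
    cfg <- simulationConfig(
      data.frame(formula = f, mz = NA_real_, abundance = 1),
      noiseSigma = 0, baseline = 0, seed = 1L)
    spec <- simulateSpectrum(cfg)
    spec@metadata$calibrated <- TRUE
    cs <- enumerateCandidates(ionMz(parseFormula(f)))
    rk <- candidates(rankCandidates(spec, cs, shape))
    expect_identical(rk$formula[1], hill)
    expect_identical(rk$rank[rk$formula == hill], 1L)
    expect_gt(rk$sa[1], 99)
  }
})

test_that("single-candidate sets rank first regardless of SA", {
  f <- "C13H20NO+"
  cfg <- simulationConfig(data.frame(formula = f, mz = NA_real_,
                                     abundance = 1),
                          noiseSigma = 0, baseline = 0, seed = 1L)
  spec <- simulateSpectrum(cfg)
  spec@metadata$calibrated <- TRUE
  box <- data.frame(element = c("C", "H", "N", "O"),
                    min = c(13L, 20L, 1L, 1L), max = c(13L, 20L, 1L, 1L))
  cs <- enumerateCandidates(ionMz(parseFormula(f)),
                            searchConstraints(elements = box,
                                              toleranceMda = 0.5))
  rk <- candidates(rankCandidates(spec, cs))
  expect_identical(nrow(rk), 1L)
  expect_identical(rk$rank, 1L)
})

test_that("candidate reports round-trip and summarise ranks", {
  cs <- enumerateCandidates(206.1538)
  cfg <- simulationConfig(data.frame(formula = "C13H20NO+", mz = NA_real_,
                                     abundance = 1),
                          noiseSigma = 0, baseline = 0, seed = 1L)
  spec <- simulateSpectrum(cfg)
  spec@metadata$calibrated <- TRUE
  rk <- rankCandidates(spec, cs)
  expect_identical(candidateSummary(rk, "C13H20NO+"), "1/6")
  expect_identical(candidateSummary(rk, "C99H2+"), "-/6")

  path <- tempfile(fileext = ".tsv")
  writeCandidateTable(rk, path)
  back <- readCandidateTable(path)
  expect_equal(back$formula, candidates(rk)$formula)
  expect_equal(back$sa, candidates(rk)$sa, tolerance = 1e-9)

  jpath <- tempfile(fileext = ".json")
  writeCandidateTable(rk, jpath, format = "json")
  j <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  expect_equal(j$target_mz, 206.1538)
  expect_identical(nrow(j$candidates), 6L)
})
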