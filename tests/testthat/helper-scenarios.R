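# Shared builders for synthetic acquisition scenarios used across tests.

# ion formula strings for the rows of a calibrant registry data.frame
calibrantIonFormulas <- function(reg) {
  vapply(seq_len(nrow(reg)), function(i)
    formulaString(applyAdduct(parseFormula(reg$neutral_formula[i]),
                              reg$adduct[i])), "")
}

# the six compound ions of the validation set (adduct composition included)
compoundIons <- c(A = "C15H23NO3Na+", B = "C13H20NO+", C = "C14H27NO3Na+",
                  D = "C14H24NO+", E = "C16H31NO3Na+", F = "C7H11ClO3Na+")

# pick the 4 calibrants nearest the analyte whose peaks stay clear of the
# analyte's profile mass range window
pickCalibrants <- function(analyteMz, registry = calibrantRegistry(),
                           clearance = 4.5, n = 4L) {
  ok <- registry[abs(registry$ion_mz - analyteMz) > clearance, ]
  ok[order(abs(ok$ion_mz - analyteMz))[seq_len(min(n, nrow(ok)))], ]
}

# simulate an infusion acquisition (analyte + spiked calibrants [+ extras]),
# average nScans noisy scans, fit the calibration and apply it
runScenario <- function(analyte, seed, abundance = 1, extras = NULL,
                        nScans = 50L, distortion = c(0.1, 5e-4, 1e-6),
                        noiseSigma = 0.5, baseline = 2,
                        registry = calibrantRegistry()) {
  exact <- ionMz(parseFormula(analyte))
  calSub <- pickCalibrants(exact, registry)
  species <- rbind(
    data.frame(formula = analyte, mz = NA_real_, abundance = abundance),
    data.frame(formula = calibrantIonFormulas(calSub), mz = NA_real_,
               abundance = 0.8))
  if (!is.null(extras)) species <- rbind(species, extras)
  cfg <- simulationConfig(species, distortion = distortion,
                          noiseSigma = noiseSigma, baseline = baseline,
                          seed = seed)
  avg <- averageAcquisitions(simulateAcquisitionSeries(cfg, nScans))
  model <- fitCalibration(avg, calSub)
  calibrated <- suppressWarnings(calibrateSpectrum(avg, model))
  list(exact = exact, calibrants = calSub, averaged = avg,
       model = model, calibrated = calibrated)
}

# observed centroid closest to an expected m/z
observedCentroidNear <- function(spectrum, expectMz, threshold = 30) {
  cen <- centroidSpectrum(spectrum, threshold = threshold)
  cen$mz[which.min(abs(cen$mz - expectMz))]
}
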