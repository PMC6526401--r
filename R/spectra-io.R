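## Profile-spectrum I/O: two-column CSV (the package's plain-text exchange
## format), mzML reading through mzR, a minimal fixture-grade mzML writer,
## and profile centroiding.

#' Read profile spectra from CSV or mzML
#'
#' CSV files must have the header `mz,intensity` with '.' as the decimal
#' mark. mzML files are read through the `mzR` package; only profile-mode
#' spectra are accepted. Axes that are unsorted or contain duplicate m/z
#' values are repaired (sorted, duplicates averaged) with a warning.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"csv"` or `"mzML"`.
#' @param scans scan selector for multi-scan mzML files: `"all"` or an
#'   integer vector of scan numbers.
#' @return a list of [ProfileSpectrum-class] objects (length 1 for CSV).
#' @export
readSpectrum <- function(path, format = c("auto", "csv", "mzML"),
                         scans = "all") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzML" else "csv"
  if (format == "csv") list(.readSpectrumCsv(path)) else
    .readSpectrumMzml(path, scans)
}

.readSpectrumCsv <- function(path) {
  if (file.size(path) == 0L) stop("empty file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("empty spectrum file: ", path, call. = FALSE)
  hdr <- strsplit(trimws(lines[1L]), ",")[[1]]
  if (!identical(tolower(hdr[1:2]), c("mz", "intensity")))
    stop("CSV header must be 'mz,intensity' in ", path, call. = FALSE)
  body <- strsplit(lines[-1L], ",")
  bad <- which(vapply(body, length, 0L) < 2L)
  if (length(bad))
    stop("malformed CSV row at line ", bad[1L] + 1L, " of ", path,
         call. = FALSE)
  mzv <- suppressWarnings(as.numeric(vapply(body, `[[`, "", 1L)))
  inten <- suppressWarnings(as.numeric(vapply(body, `[[`, "", 2L)))
  if (anyNA(mzv) || anyNA(inten)) {
    bad <- which(is.na(mzv) | is.na(inten))[1L]
    stop("non-numeric value at line ", bad + 1L, " of ", path, call. = FALSE)
  }
  .repairedSpectrum(mzv, inten, source = path)
}

.repairedSpectrum <- function(mzv, inten, source) {
  if (is.unsorted(mzv)) {
    warning("m/z axis not sorted in ", source, "; sorting")
    o <- order(mzv)
    mzv <- mzv[o]; inten <- inten[o]
  }
  if (anyDuplicated(mzv)) {
    warning("duplicate m/z values in ", source, "; averaging")
    inten <- as.vector(tapply(inten, factor(mzv, levels = unique(mzv)), mean))
    mzv <- unique(mzv)
  }
  profileSpectrum(mzv, inten, metadata = list(calibrated = FALSE,
                                              source = source))
}

.readSpectrumMzml <- function(path, scans) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the 'mzR' package", call. = FALSE)
  h <- mzR::openMSfile(path)
  on.exit(mzR::close(h))
  hd <- suppressWarnings(mzR::header(h))
  idx <- if (identical(scans, "all")) seq_len(nrow(hd)) else as.integer(scans)
  if (any(idx < 1L | idx > nrow(hd)))
    stop("scan selector outside 1..", nrow(hd), call. = FALSE)
  if ("centroided" %in% names(hd) &&
      any(isTRUE(hd$centroided[idx])))
    stop("mzML contains centroided scans; profile spectra are required",
         call. = FALSE)
  lapply(idx, function(i) {
    p <- mzR::peaks(h, i)
    .repairedSpectrum(p[, 1L], p[, 2L],
                      source = paste0(path, "#scan", i))
  })
}

#' Write a profile spectrum as CSV
#'
#' Writes the two-column `mz,intensity` format at full double precision, so
#' a written spectrum reads back bit-identically.
#'
#' @param spectrum a [ProfileSpectrum-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSpectrumCsv <- function(spectrum, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("mz,intensity", con)
  writeLines(sprintf("%.17g,%.17g", spectrum@mz, spectrum@intensity), con)
  invisible(path)
}

#' Centroid a profile spectrum
#'
#' Finds local intensity maxima above a threshold and reports each peak's
#' centroid and apex intensity. Centroids come from a Gaussian vertex fit
#' over the samples above half-maximum, refined by subtracting the fitted
#' Gaussians of neighbouring peaks (so small isotopologue peaks are not
#' biased by the pedestal of the base peak).
#'
#' @param spectrum a [ProfileSpectrum-class].
#' @param threshold minimum apex intensity (default 0 keeps all maxima).
#' @return data.frame with columns `mz` (centroid) and `intensity` (apex).
#' @export
centroidSpectrum <- function(spectrum, threshold = 0) {
  stopifnot(threshold >= 0)
  mzv <- spectrum@mz
  inten <- spectrum@intensity
  n <- length(inten)
  isMax <- c(FALSE, inten[2:(n - 1)] > inten[1:(n - 2)] &
               inten[2:(n - 1)] >= inten[3:n], FALSE)
  apex <- which(isMax & inten > threshold)
  if (!length(apex))
    return(data.frame(mz = numeric(0), intensity = numeric(0)))
  ## first pass: per-peak Gaussian estimates (centroid, apex, sigma)
  est <- lapply(apex, function(i) {
    list(c = .centroidAt(mzv, inten, i), a = inten[i],
         s = .halfWidthAt(mzv, inten, i) / (2 * sqrt(2 * log(2))))
  })
  ## refinement: re-centroid each peak after subtracting the fitted
  ## Gaussians of all other peaks, which removes the sloped pedestal a
  ## neighbouring (possibly much larger) peak lays under this one
  cen <- vapply(seq_along(apex), function(k) {
    i <- apex[k]
    lo <- max(1L, i - 200L)
    hi <- min(n, i + 200L)
    res <- inten[lo:hi]
    for (j in seq_along(apex)) {
      if (j == k || !is.finite(est[[j]]$s)) next
      res <- res - est[[j]]$a *
        exp(-(mzv[lo:hi] - est[[j]]$c)^2 / (2 * est[[j]]$s^2))
    }
    res <- pmax(res, 0)
    apexLocal <- which.max(res[seq(max(1L, i - lo - 1L), i - lo + 3L)]) +
      max(1L, i - lo - 1L) - 1L
    .centroidAt(mzv[lo:hi], res, apexLocal)
  }, 0)
  data.frame(mz = cen, intensity = inten[apex])
}

## interpolated full width at half maximum of the local peak at apexIdx
.halfWidthAt <- function(mzv, inten, apexIdx) {
  half <- inten[apexIdx] / 2
  rip <- 0.02 * inten[apexIdx]
  lo <- apexIdx
  while (lo > 1L && inten[lo - 1L] >= half &&
         inten[lo - 1L] <= inten[lo] + rip) lo <- lo - 1L
  hi <- apexIdx
  while (hi < length(inten) && inten[hi + 1L] >= half &&
         inten[hi + 1L] <= inten[hi] + rip) hi <- hi + 1L
  left <- if (lo > 1L && inten[lo - 1L] < inten[lo])
    mzv[lo - 1L] + (half - inten[lo - 1L]) / (inten[lo] - inten[lo - 1L]) *
      (mzv[lo] - mzv[lo - 1L]) else mzv[lo]
  right <- if (hi < length(inten) && inten[hi + 1L] < inten[hi])
    mzv[hi] + (inten[hi] - half) / (inten[hi] - inten[hi + 1L]) *
      (mzv[hi + 1L] - mzv[hi]) else mzv[hi]
  right - left
}

## ---- minimal mzML writer ----------------------------------------------------

.b64 <- function(x) {
  gsub("[\r\n]", "",
       jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8L,
                                     endian = "little")))
}

.mzmlBinaryArray <- function(values, cvAccession, cvName, unitXml) {
  b <- .b64(values)
  paste0('<binaryDataArray encodedLength="', nchar(b), '">\n',
         '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>\n',
         '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>\n',
         '<cvParam cvRef="MS" accession="', cvAccession, '" name="', cvName,
         '" value=""', unitXml, '/>\n',
         '<binary>', b, '</binary>\n</binaryDataArray>')
}

.mzmlSpectrum <- function(spectrum, index) {
  mzArr <- .mzmlBinaryArray(spectrum@mz, "MS:1000514", "m/z array",
                            ' unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"')
  intArr <- .mzmlBinaryArray(spectrum@intensity, "MS:1000515",
                             "intensity array",
                             ' unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"')
  paste0('<spectrum index="', index, '" id="scan=', index + 1L,
         '" defaultArrayLength="', length(spectrum@mz), '">\n',
         '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>\n',
         '<cvParam cvRef="MS" accession="MS:1000128" name="profile spectrum" value=""/>\n',
         '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>\n',
         '<binaryDataArrayList count="2">\n', mzArr, '\n', intArr,
         '\n</binaryDataArrayList>\n</spectrum>')
}

#' Write spectra to a minimal mzML file
#'
#' A fixture-grade mzML 1.1.0 writer (uncompressed 64-bit arrays, MS1
#' profile spectra only) intended for producing synthetic multi-scan inputs
#' that standard mzML readers can open. It is not a general-purpose mzML
#' exporter.
#'
#' @param spectra a [ProfileSpectrum-class] or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMzML <- function(spectra, path) {
  if (is(spectra, "ProfileSpectrum")) spectra <- list(spectra)
  specs <- paste(vapply(seq_along(spectra), function(i)
    .mzmlSpectrum(spectra[[i]], i - 1L), ""), collapse = "\n")
  doc <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '<cvList count="2">\n',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>\n',
    '<cv id="UO" fullName="Unit Ontology" URI="http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo"/>\n',
    '</cvList>\n',
    '<fileDescription><fileContent>\n',
    '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>\n',
    '<cvParam cvRef="MS" accession="MS:1000128" name="profile spectrum" value=""/>\n',
    '</fileContent></fileDescription>\n',
    '<softwareList count="1"><software id="SpectralAccuracy" version="0.1.0">',
    '<cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="SpectralAccuracy"/>',
    '</software></softwareList>\n',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1">\n',
    '<cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/>\n',
    '</instrumentConfiguration></instrumentConfigurationList>\n',
    '<dataProcessingList count="1"><dataProcessing id="DP1">',
    '<processingMethod order="1" softwareRef="SpectralAccuracy">\n',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>\n',
    '</processingMethod></dataProcessing></dataProcessingList>\n',
    '<run id="run1" defaultInstrumentConfigurationRef="IC1">\n',
    '<spectrumList count="', length(spectra),
    '" defaultDataProcessingRef="DP1">\n',
    specs, '\n</spectrumList>\n</run>\n</mzML>\n')
  writeLines(doc, path)
  invisible(path)
}
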