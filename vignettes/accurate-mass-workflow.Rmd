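---
title: "Accurate masses and spectral accuracy from a triple quadrupole: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accurate masses and spectral accuracy from a triple quadrupole}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpectralAccuracy)
```

# The problem

Assigning a molecular formula to a synthesis product normally requires a
high-resolution mass spectrometer. A triple quadrupole (QqQ) resolves only
about one thousandth of the mass scale (resolving power R<sub>FWHM</sub> ≈
500), but its mass *axis* error is dominated by slowly varying calibration
drift, not by peak width. If internal calibrants of known formula are spiked
into the infused sample, the axis can be corrected post-acquisition to a few
mDa — good enough for ±10 mDa formula searches — and the *shape* of the
isotope pattern in the calibrated profile can arbitrate between formulas
that are indistinguishable by mass alone. That arbitration score is called
spectral accuracy (SA).

This vignette documents the models, parameters and numerical choices behind
each stage, what the synthetic-data generator does and does not emulate, and
the known limitations.

# Exact-mass arithmetic

All masses derive from a vendored isotope table
(`isotopeTable()`, AME2020 masses / CIAAW2021 abundances) so results do not
depend on external databases. The monoisotopic mass of a formula is the sum
of most-abundant-isotope masses; an ion's m/z subtracts one electron mass
(0.000549 Da) per positive charge:

$$ m/z \;=\; \frac{\sum_i n_i M_i - z\,m_e}{|z|}. $$

Omitting the electron term shifts every ion by +0.5 mDa and visibly breaks
agreement with 4-decimal reference masses, so it is never optional.
Rings-plus-double-bonds uses the fixed valence model C 4; N, P 3; O, S 2;
H, Cl, Na 1:

$$ \mathrm{RDBE} = 1 + \tfrac12\sum_i n_i (v_i - 2) $$

which makes every even-electron singly charged cation (protonated molecule
or sodium adduct) score a half-integer, and places fully saturated species
like NH4+ at the search window's lower edge of −0.5. The parity rule "even-
electron ⇔ half-integer RDBE at odd |z|" is exactly the electron-
configuration filter of the search.

Formulas render in Hill notation (C, H, then alphabetical, so sodium sorts
as "Na" between N and O — `C14H27NNaO3+`); the parser also accepts
adduct-style spellings such as `C14H27NO3Na+` and typeset sub/superscripts,
and normalises them to the same composition.

# Candidate enumeration

`enumerateCandidates()` is exhaustive by construction: it scans the full
grid of non-hydrogen element counts (~35 000 combinations for the default
box) and solves for the hydrogen counts that land inside the mass tolerance
— hydrogen is the lightest element, so at ±10 mDa at most one H count per
grid point can qualify. Candidates are enumerated directly as *ion*
compositions (adduct atoms included), which is how a search against a
measured adduct mass is naturally reported. The defaults — C 2–25, H 0–50,
N 0–10, O 0–10, Na 0–1, Cl 0–5, ±10 mDa, charge +1, RDBE −0.5 to 20,
even-electron — are the standard box for ESI+ small-molecule work where Na
enters only as an adduct contaminant; they are deliberately free of
heuristic plausibility filters (no element-ratio rules, no database
lookups). Output order is deterministic: ascending |Δm|, ties broken by the
Hill string. A naive full-Cartesian oracle over small boxes verifies
exhaustiveness in the test suite.

# Isotope patterns

Patterns are computed by iterative fine-structure convolution: per-element
distributions are raised to their atom count by repeated squaring, peaks
closer than 10⁻⁶ Da are merged (weighted mean), and peaks below a relative
threshold (default 10⁻⁸) are pruned after every step. At ≤ 50 atoms this is
exact for all practical purposes — the test suite checks it against a
brute-force polynomial expansion — and pruning at 10⁻⁶ instead changes the
M…M+3 cluster abundances by under 0.01 percentage points. For diagnostics,
`aggregateNominal()` sums fine structure within ±0.3 Th of mono + k
(unambiguous for CHNONaCl chemistry below m/z 1000) into the familiar M,
M+1, M+2, M+3 abundances.

Profile rendering (`renderProfile()`) places a unit-area Gaussian of the
local model FWHM at every centroid, scaled by abundance, on a 0.01 Th grid
(≥ 40 samples per FWHM at R ≈ 500), conserving integrated abundance to well
under 0.1 %.

# Calibration

**Peak location.** Calibrant peaks are searched within ±0.5 Th of their
expected position — wide enough for the several-hundred-mDa errors an
uncalibrated quadrupole can show. Apexes that fail a signal threshold
(default median + 10·MAD of the spectrum) are flagged missed rather than
used: weak calibrant signals are a documented cause of >10 mDa calibrated
shifts, and silence here would propagate them.

**Centroids.** The centroid estimator is a weighted log-parabola (Gaussian
vertex) fit over the contiguous samples above half maximum, with two
safeguards: region growth stops when intensity starts rising again (2 %
ripple allowance), so a small peak's region cannot bleed across a valley
into a larger neighbour; and `centroidSpectrum()` runs a second pass that
subtracts the fitted Gaussians of neighbouring peaks before re-centroiding,
which removes the sloped pedestal a base peak lays under its M+1/M+2
satellites. A plain intensity-weighted mean over the half-max region was
tried first and found to jitter by up to ~3 mDa with grid phase and to be
biased by ~8 mDa on pedestal-seated peaks — both visible at the accuracy
this workflow targets, hence the vertex fit.

**Mass axis.** `fitMassAxis()` fits true ~ measured by least squares with
polynomial order min(n−1, 2). The order cap matches the three-to-four
calibrants the workflow uses; a cubic through four noisy centroids would
chase centroid error. The fitted map must be strictly increasing over the
calibrant span; spectra extending beyond that span are still calibrated but
flagged `extrapolated`.

**Line shape.** Per-peak FWHM comes from interpolated half-maximum
crossings, then FWHM ~ m/z is fitted as a line (constant for a single
peak). The default shape anchor is R = 500, i.e. FWHM ≈ 0.444 Th at
m/z 222.2.

**Application.** `calibrateSpectrum()` maps the axis, divides intensities
by the local Jacobian of the map (without this, any non-unit slope changes
the integral), and resamples by linear interpolation onto a uniform grid at
the native median step. Total intensity is conserved to 0.1 %.

A deliberate design choice: the proprietary reference implementation of
this workflow *reshapes the measured data* toward a target line-shape
function. Here the comparison happens in the instrument's own shape space
instead — theoretical patterns are rendered with the *fitted* shape. The SA
semantics are identical (both compare like with like), but no deconvolution
step is needed, which avoids its noise amplification.

# Spectral accuracy and ranking

The profile window extends from −0.5 to +3.5 Da around the monoisotopic
peak (covering M…M+3); a robust baseline — the median of the lowest
intensity decile inside the window — is subtracted and the result floored
at zero. SA is computed on the profile samples:

$$ \mathrm{SA} = 100\,\Bigl(1 - \frac{\lVert o - s\,t\rVert_2}{\lVert o \rVert_2}\Bigr),
   \qquad s = \max\!\Bigl(0, \tfrac{\langle o, t\rangle}{\langle t, t\rangle}\Bigr), $$

clipped at 0, undefined (NA) for an all-zero window. This normalisation
reproduces the anchors that define the score: identical patterns give
exactly 100 %, disjoint patterns 0 %, and it is invariant to rescaling
either side. Whether the reference implementation scores profile samples or
nominal clusters is unpublished; this package scores profiles and exposes
`aggregateNominal()` for cluster-level diagnostics.

One subtlety matters numerically: the theoretical profile is passed through
the *same* window extraction (including baseline subtraction) as the
observed one. The lowest-decile baseline estimate sits at the inter-peak
Gaussian tail level, not at zero; subtracting it from only one side
systematically guts the small M+2/M+3 peaks of the observed window and is
enough to flip ranks between near-degenerate formulas.

`rankCandidates()` centres each candidate's window at its own theoretical
monoisotopic m/z (post-calibration residuals are orders of magnitude
smaller than the window), computes Δm from the observed monoisotopic
centroid within ±0.3 Th, and sorts by SA, breaking ties by smaller |Δm|
and then the Hill string. Candidates with undefined SA sink to the bottom,
flagged.

Narrowing the window (e.g. to +2.5 Da) is the documented remedy when an
interference peak falls near M+3: it excludes the interference from the
residual for *every* candidate and restores the clean ranking. The window
is a parameter of `extractWindow()`/`rankCandidates()` for exactly this
use.

# The synthetic-data generator

`simulateSpectrum()` emulates what the calibration and scoring stages
actually consume: ESI+ profile spectra over m/z 150–350 at R ≈ 500,
rendered isotope patterns of the configured ion species, a polynomial
mass-axis distortion (the generator displaces true positions by
d0 + d1·m + d2·m², mirroring drifted-quadrupole behaviour of up to several
hundred mDa), a constant baseline, additive Gaussian intensity noise with a
fixed seed, and optional fixed-m/z interference peaks. Species whose
significant isotopologues (> 0.5 % of the species base) fall outside the
scan range are an error; negligible ones are truncated like a real scan
range does. `simulateAcquisitionSeries()` derives per-scan seeds
deterministically from the master seed, and averaging n scans improves SNR
by ≈ √n, which the tests verify.

What it does *not* model: ionisation efficiency and matrix suppression,
detector saturation, peak asymmetry, resolution drift within a scan, and
chromatography. Consequently, green tests demonstrate that the *algorithms*
are correct under their stated assumptions (Gaussian shape, polynomial
distortion, additive noise) — they do not certify performance on matrices
where suppression or non-Gaussian tailing dominates, and published SA
percentages from real instruments are reproduced qualitatively, not
numerically.

Default study conditions used across the test scenarios: four calibrants at
0.8 relative abundance bracketing the analyte (chosen ≥ 4.5 Th away so no
calibrant falls inside the analyte's profile window — with a +3.5 Da window
a calibrant 3 Th above the analyte is an interference), quadratic
distortion up to ~0.4 Th, noise σ = 0.5 (apex SNR ≈ 300 for a unit-
abundance species), baseline 2, and 50–100 averaged scans, matching the
~100 acquisitions per infusion sample that the workflow averages in
practice.

# Numerical choices and degenerate inputs

* Grid step 0.01 Th everywhere (rendering error ≪ SA sensitivity).
* Convolution merge tolerance 10⁻⁶ Da; pruning 10⁻⁸ relative.
* Mass-tolerance comparisons carry a 10⁻¹² Da epsilon so boundary
  candidates are kept deterministically.
* Ties in ranking are broken by |Δm|, then lexicographic Hill string, so
  output is reproducible byte for byte.
* Degenerate inputs fail loudly: empty element boxes, candidate sets
  exceeding the configurable cap, single calibrant pairs, duplicate
  measured centroids, non-monotone fitted maps, windows outside the
  spectrum, centroid-mode mzML where profile data is required.
* `massAccuracy()` rounds to 0.1 mDa — the precision at which Δm values
  are conventionally reported.

# Known limitations

* Only Gaussian line shapes are implemented; an asymmetric peak is fitted
  by the symmetric family with a documented residual rather than an error.
* The mass-axis polynomial is capped at order 2; wilder axis distortions
  would need more calibrants and a higher order than this workflow uses.
* Negative-mode adducts are implemented by symmetry but exercised only
  lightly by tests, since the target workflow is ESI+.
* SA discrimination between formulas whose patterns differ by < 0.1 % (the
  chlorine-free near-degenerate pairs at nominal mass 280, for instance)
  is genuinely fragile at QqQ resolution; rank inversions among the top
  few candidates under noise are expected behaviour, which is why the
  workflow reports the full ranked table rather than a single answer.

# Problem sizes

The shipped tests simulate 12–100 scans of 20 001-sample spectra per
scenario and rank candidate sets of 5–30 formulas; the whole suite runs in
under two minutes on one CPU. These sizes were chosen as the smallest at
which the √n-averaging, calibration-recovery and ranking properties are
comfortably away from their thresholds; nothing in the method depends on
them.
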