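## Exhaustive candidate-formula enumeration within a mass tolerance under
## element-range, RDBE and electron-configuration constraints.

#' Construct formula-search constraints
#'
#' The defaults are the constraint set applied to every compound in the
#' target workflow: elements C 2-25, H 0-50, N 0-10, O 0-10, Na 0-1,
#' Cl 0-5; mass tolerance +-10 mDa; charge +1; RDBE from -0.5 to 20;
#' even-electron ions only. Sodium is capped at one atom because it enters
#' as a ubiquitous adduct-forming contaminant rather than a structural
#' element.
#'
#' @param elements data.frame with columns `element`, `min`, `max`.
#' @param toleranceMda mass tolerance in mDa (> 0).
#' @param charge ion charge state (default +1).
#' @param rdbeRange numeric length-2 window for rings plus double bonds.
#' @param electrons electron configuration filter: `"even"`, `"odd"` or
#'   `"both"`.
#' @param maxCandidates cap on the candidate set size; exceeding it is an
#'   error advising a narrower search.
#' @return a [SearchConstraints-class].
#' @examples
#' searchConstraints()
#' @export
searchConstraints <- function(elements = data.frame(
                                element = c("C", "H", "N", "O", "Na", "Cl"),
                                min = c(2L, 0L, 0L, 0L, 0L, 0L),
                                max = c(25L, 50L, 10L, 10L, 1L, 5L)),
                              toleranceMda = 10,
                              charge = 1L,
                              rdbeRange = c(-0.5, 20),
                              electrons = "even",
                              maxCandidates = 100000L) {
  new("SearchConstraints", elements = elements,
      toleranceMda = as.numeric(toleranceMda), charge = as.integer(charge),
      rdbeRange = as.numeric(rdbeRange), electrons = electrons,
      maxCandidates = as.integer(maxCandidates))
}

#' Electron-configuration parity of an ion
#'
#' For singly charged cations under the package's valence model, an
#' even-electron ion (all electrons paired, e.g. a protonated molecule or a
#' sodium adduct) has a half-integer RDBE, while an odd-electron radical
#' cation has an integer RDBE. Neutrals are classified `"even"` by
#' convention.
#'
#' @param object a [Formula-class].
#' @return `"even"` or `"odd"`.
#' @examples
#' electronParity(parseFormula("C13H20NO+")) # even
#' electronParity(parseFormula("C6H6+"))     # odd (radical cation)
#' @export
setMethod("electronParity", "Formula", function(object) {
  z <- object@charge
  if (z == 0L) return("even")
  r <- rdbe(object)
  halfInteger <- abs(r %% 1 - 0.5) < 1e-9
  if (abs(z) %% 2L == 1L) {
    if (halfInteger) "even" else "odd"
  } else {
    if (halfInteger) "odd" else "even"
  }
})

## RDBE of an ion composition, vectorised over a count matrix (columns =
## elements of the box); relies on the same valence model as rdbe().
.rdbeVec <- function(countMat) {
  v <- .VALENCE[colnames(countMat)]
  if (anyNA(v))
    stop("no valence assigned for element: '",
         colnames(countMat)[which(is.na(v))[1L]], "'", call. = FALSE)
  1 + as.vector(countMat %*% (v - 2L)) / 2
}

#' Enumerate candidate ion formulas for a measured m/z
#'
#' Exhaustively enumerates every ion composition inside the element box
#' whose exact m/z (with electron-mass correction) lies within the mass
#' tolerance of the target, then filters on the RDBE window and the
#' electron-configuration rule. Candidates are ion compositions: adduct
#' atoms (H or Na) are part of the formula, as in `"C14H27NO3Na+"`.
#'
#' The scan iterates the grid of all non-hydrogen element counts and solves
#' directly for the admissible hydrogen counts, which makes the enumeration
#' exact and fast at the scale of small-molecule searches.
#'
#' @param targetMz measured m/z (Th), > 0.
#' @param constraints a [SearchConstraints-class].
#' @return a [CandidateSet-class] whose table is ordered by ascending
#'   absolute mass error, ties broken by the Hill formula string.
#' @examples
#' cs <- enumerateCandidates(206.1538, searchConstraints())
#' nrow(candidates(cs)) # 6
#' @export
enumerateCandidates <- function(targetMz, constraints = searchConstraints()) {
  stopifnot(is.numeric(targetMz), length(targetMz) == 1L, targetMz > 0)
  validObject(constraints)
  el <- constraints@elements
  tol <- constraints@toleranceMda / 1000
  z <- constraints@charge
  if (z == 0L) stop("charge must be nonzero for an ion search", call. = FALSE)

  masses <- vapply(el$element, .monoMass, 0)
  hasH <- "H" %in% el$element
  grid_el <- el[el$element != "H", , drop = FALSE]
  gridSize <- prod(grid_el$max - grid_el$min + 1)
  if (gridSize > 5e6)
    stop("element box too large (", format(gridSize),
         " combinations); narrow the search", call. = FALSE)

  ranges <- lapply(seq_len(nrow(grid_el)),
                   function(i) grid_el$min[i]:grid_el$max[i])
  names(ranges) <- grid_el$element
  g <- as.matrix(expand.grid(ranges, KEEP.OUT.ATTRS = FALSE))
  restMass <- as.vector(g %*% masses[grid_el$element]) - z * .ELECTRON_MASS
  ## target m/z corresponds to total ion mass target*|z| + z*me already
  ## folded in via restMass; remaining mass must be made of H atoms
  targetMass <- targetMz * abs(z)

  mH <- .monoMass("H")
  hMin <- if (hasH) el$min[el$element == "H"] else 0L
  hMax <- if (hasH) el$max[el$element == "H"] else 0L

  rows <- vector("list", 0L)
  for (nH in hMin:hMax) {
    dev <- restMass + nH * mH - targetMass
    ok <- abs(dev) <= tol + 1e-12
    if (!any(ok)) next
    sub <- g[ok, , drop = FALSE]
    cm <- cbind(sub, H = rep.int(nH, nrow(sub)))
    rows[[length(rows) + 1L]] <-
      list(counts = cm, mzDev = dev[ok])
  }
  if (length(rows)) {
    countMat <- do.call(rbind, lapply(rows, `[[`, "counts"))
    mzDev <- unlist(lapply(rows, `[[`, "mzDev"), use.names = FALSE)
  } else {
    countMat <- matrix(0L, 0L, nrow(grid_el) + 1L,
                       dimnames = list(NULL, c(grid_el$element, "H")))
    mzDev <- numeric(0)
  }

  if (nrow(countMat)) {
    r <- .rdbeVec(countMat)
    keep <- r >= constraints@rdbeRange[1] - 1e-9 &
            r <= constraints@rdbeRange[2] + 1e-9
    if (constraints@electrons != "both") {
      halfInt <- abs(r %% 1 - 0.5) < 1e-9
      isEven <- if (abs(z) %% 2L == 1L) halfInt else !halfInt
      keep <- keep & (if (constraints@electrons == "even") isEven else !isEven)
    }
    ## drop the all-zero composition if the box allows it
    keep <- keep & rowSums(countMat) > 0L
    countMat <- countMat[keep, , drop = FALSE]
    mzDev <- mzDev[keep]
    r <- r[keep]
  } else r <- numeric(0)

  if (nrow(countMat) > constraints@maxCandidates)
    stop(nrow(countMat), " candidates exceed the cap (",
         constraints@maxCandidates, "); narrow the tolerance or element box",
         call. = FALSE)

  formulas <- vapply(seq_len(nrow(countMat)), function(i) {
    formulaString(newFormula(countMat[i, ], charge = z))
  }, "")
  tab <- data.frame(formula = formulas,
                    exactMz = targetMz + mzDev / abs(z),
                    deltaMda = -mzDev / abs(z) * 1000,
                    rdbe = r,
                    sa = NA_real_,
                    rank = NA_integer_,
                    stringsAsFactors = FALSE)
  ## deterministic order: ascending |delta m|, ties by Hill string
  tab <- tab[order(abs(tab$deltaMda), tab$formula), , drop = FALSE]
  rownames(tab) <- NULL
  new("CandidateSet", targetMz = targetMz, constraints = constraints,
      table = tab)
}
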