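## Formula arithmetic: parsing/printing, monoisotopic masses, adducts,
## ion m/z with electron-mass correction, RDBE, mass accuracy.

#' Construct a Formula from element counts
#'
#' @param counts named integer vector of element counts, e.g.
#'   `c(C = 13, H = 20, N = 1, O = 1)`.
#' @param charge integer charge state (default 0, a neutral).
#' @param label optional provenance label.
#' @return a [Formula-class].
#' @examples
#' newFormula(c(C = 8, H = 10, N = 4, O = 2))
#' @export
newFormula <- function(counts, charge = 0L, label = NA_character_) {
  counts <- counts[counts != 0]
  stor <- setNames(as.integer(counts), names(counts))
  new("Formula", counts = stor, charge = as.integer(charge), label = label)
}

#' Parse a molecular formula string
#'
#' Accepts Hill-notation strings with an optional trailing charge, e.g.
#' `"C13H20NO+"`, `"C14H27NO3Na+"`, `"C6H6"`, `"CHCl3"` or `"H2O2-"`.
#' Multiple charges are written as repeated signs (`"++"`) or sign-then-count
#' (`"+2"`); digits before a sign always belong to the last element count.
#' Unicode sub/superscripts are normalised before parsing.
#'
#' @param text the formula string.
#' @return a [Formula-class].
#' @examples
#' parseFormula("C13H20NO+")
#' @export
parseFormula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- .normalizeFormulaText(text)
  ## trailing charge: "+", "-", repeated signs ("++") or sign-then-digits
  ## ("+2"); digits BEFORE a sign are element counts, never a charge
  charge <- 0L
  chg <- regmatches(s, regexpr("([+-][0-9]+|[+-]+)$", s))
  if (length(chg) && nzchar(chg)) {
    s <- substr(s, 1L, nchar(s) - nchar(chg))
    sign <- if (substr(chg, 1L, 1L) == "-") -1L else 1L
    digits <- gsub("[+-]", "", chg)
    mult <- if (nzchar(digits)) as.integer(digits)
            else nchar(chg)
    charge <- sign * mult
  }
  parts <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1]]
  if (!length(parts) || sum(nchar(parts)) != nchar(s))
    stop("cannot parse formula: '", text, "'", call. = FALSE)
  els <- sub("[0-9]*$", "", parts)
  ns <- sub("^[A-Za-z]+", "", parts)
  cnt <- ifelse(nzchar(ns), suppressWarnings(as.integer(ns)), 1L)
  counts <- tapply(cnt, els, sum)
  bad <- setdiff(names(counts), names(.ISOTOPES))
  if (length(bad))
    stop("unknown element symbol: '", bad[1L], "'", call. = FALSE)
  newFormula(setNames(as.integer(counts), names(counts)), charge = charge)
}

## strip unicode sub/superscripts and brackets that appear in typeset formulas
.normalizeFormulaText <- function(s) {
  sub_digits <- c("₀","₁","₂","₃","₄",
                  "₅","₆","₇","₈","₉")
  sup_digits <- c("⁰","¹","²","³","⁴",
                  "⁵","⁶","⁷","⁸","⁹")
  for (i in seq_along(sub_digits)) {
    s <- gsub(sub_digits[i], as.character(i - 1L), s, fixed = TRUE)
    s <- gsub(sup_digits[i], as.character(i - 1L), s, fixed = TRUE)
  }
  s <- gsub("⁺", "+", s, fixed = TRUE)
  s <- gsub("⁻", "-", s, fixed = TRUE)
  s <- gsub("[_^{}\\[\\]\\s]", "", s, perl = TRUE)
  s
}

.hillOrder <- function(els) {
  if ("C" %in% els) {
    rest <- sort(setdiff(els, c("C", "H")))
    c("C", intersect("H", els), rest)
  } else sort(els)
}

#' @describeIn Formula-class canonical Hill-notation string
#'   (C first, then H, remaining elements alphabetically; trailing charge).
#' @param object a `Formula`
#' @export
setMethod("formulaString", "Formula", function(object, ...) {
  cnt <- object@counts
  els <- .hillOrder(names(cnt))
  body <- paste0(vapply(els, function(e)
    paste0(e, if (cnt[[e]] > 1L) cnt[[e]] else ""), ""), collapse = "")
  z <- object@charge
  suffix <- if (z == 0L) "" else
    paste0(if (abs(z) > 1L) abs(z) else "", if (z > 0L) "+" else "-")
  paste0(body, suffix)
})

#' @describeIn Formula-class neutral-atom monoisotopic mass (Da): the sum of
#'   most-abundant-isotope masses; the charge is ignored (no electron-mass
#'   correction at this level).
#' @export
setMethod("monoisotopicMass", "Formula", function(object) {
  cnt <- object@counts
  sum(vapply(names(cnt), .monoMass, 0) * cnt)
})

## ---- adducts ----------------------------------------------------------------

#' Built-in electrospray adduct registry
#'
#' @return named list of [AdductSpec-class] objects; includes `[M+H]+` and
#'   `[M+Na]+`, the two positive-mode species relevant here.
#' @examples
#' names(adductRegistry())
#' @export
adductRegistry <- function() {
  list(
    "[M+H]+" = new("AdductSpec", name = "[M+H]+",
                   delta = c(H = 1L), chargeDelta = 1L),
    "[M+Na]+" = new("AdductSpec", name = "[M+Na]+",
                    delta = c(Na = 1L), chargeDelta = 1L),
    "[M-H]-" = new("AdductSpec", name = "[M-H]-",
                   delta = c(H = -1L), chargeDelta = -1L)
  )
}

.resolveAdduct <- function(adduct) {
  if (is(adduct, "AdductSpec")) return(adduct)
  reg <- adductRegistry()
  if (is.character(adduct) && adduct %in% names(reg)) return(reg[[adduct]])
  stop("unknown adduct: ", adduct, call. = FALSE)
}

#' Apply an adduct to a neutral formula
#'
#' @param neutral a neutral [Formula-class].
#' @param adduct an [AdductSpec-class] or registry name such as `"[M+H]+"`.
#' @return the ion [Formula-class] (composition plus adduct atoms, charge
#'   plus adduct charge). `removeAdduct()` inverts the operation exactly.
#' @examples
#' applyAdduct(parseFormula("C13H19NO"), "[M+H]+")
#' @export
applyAdduct <- function(neutral, adduct) {
  a <- .resolveAdduct(adduct)
  cnt <- neutral@counts
  for (e in names(a@delta)) {
    cnt[e] <- (if (e %in% names(cnt)) cnt[[e]] else 0L) + a@delta[[e]]
    if (cnt[e] < 0L)
      stop("adduct removes more ", e, " than present", call. = FALSE)
  }
  newFormula(cnt, charge = neutral@charge + a@chargeDelta,
             label = neutral@label)
}

#' @rdname applyAdduct
#' @param ion the ion [Formula-class] to strip.
#' @export
removeAdduct <- function(ion, adduct) {
  a <- .resolveAdduct(adduct)
  inv <- new("AdductSpec", name = paste0("inverse:", a@name),
             delta = -a@delta, chargeDelta = -a@chargeDelta)
  applyAdduct(ion, inv)
}

## ---- ion m/z ----------------------------------------------------------------

## m/z of an already-charged ion composition
.ionMzOfIon <- function(ion) {
  z <- ion@charge
  if (z == 0L) stop("ion m/z requires a nonzero charge", call. = FALSE)
  (monoisotopicMass(ion) - z * .ELECTRON_MASS) / abs(z)
}

#' Exact ion m/z of a neutral molecule under an adduct
#'
#' Computes `(monoisotopic mass of neutral + adduct atoms - z * m_e) / |z|`:
#' the electron mass is subtracted once per positive charge (added per
#' negative charge), which is required to match 4-decimal exact masses.
#'
#' @param neutral a neutral [Formula-class] (or an already-charged ion if
#'   `adduct` is `NULL`).
#' @param adduct an [AdductSpec-class], a registry name, or `NULL`.
#' @return the exact m/z (Th).
#' @examples
#' ionMz(parseFormula("C13H19NO"), "[M+H]+")   # 206.1539
#' ionMz(parseFormula("C14H27NO3"), "[M+Na]+") # 280.1883
#' @export
ionMz <- function(neutral, adduct = NULL) {
  ion <- if (is.null(adduct)) neutral else applyAdduct(neutral, adduct)
  .ionMzOfIon(ion)
}

## ---- RDBE -------------------------------------------------------------------

#' @describeIn Formula-class rings plus double bonds equivalent:
#'   `nC + 1 + (nN + nP - nH - nCl - nNa)/2` under the valence model
#'   C,4; N,P,3; O,S,2 (zero contribution); H, Cl, Na monovalent. Errors if
#'   an element has no assigned valence.
#' @export
setMethod("rdbe", "Formula", function(object) {
  cnt <- object@counts
  noval <- setdiff(names(cnt), names(.VALENCE))
  if (length(noval))
    stop("no valence assigned for element: '", noval[1L], "'", call. = FALSE)
  v <- .VALENCE[names(cnt)]
  1 + sum(cnt * (v - 2L)) / 2
})

## ---- mass accuracy ----------------------------------------------------------

#' Mass accuracy (delta-m) in millidaltons
#'
#' @param measuredMz measured m/z (Th).
#' @param exactMz theoretical exact m/z (Th).
#' @return `(measured - exact) * 1000`, rounded to 0.1 mDa, the convention
#'   used for reporting accurate-mass errors.
#' @examples
#' massAccuracy(206.1538, 206.1539) # -0.1
#' @export
massAccuracy <- function(measuredMz, exactMz) {
  stopifnot(is.finite(measuredMz), is.finite(exactMz))
  round((measuredMz - exactMz) * 1000, 1)
}

## ---- calibrant registry -----------------------------------------------------

#' Internal mass calibrant registry
#'
#' Reads a calibrant list (CSV columns `name`, `neutral_formula`, `adduct`)
#' and computes each calibrant's exact ion m/z. The packaged default lists
#' the six small-molecule calibrants used for post-acquisition calibration of
#' positive-mode infusion spectra: caffeine, atrazine, cyclophosphamide,
#' metoprolol, avobenzone and benzylbutyl phthalate.
#'
#' @param path path to a calibrant CSV; `NULL` loads the packaged registry.
#' @return data.frame with columns `name`, `neutral_formula`, `adduct`,
#'   `neutral_mass` and `ion_mz`.
#' @examples
#' calibrantRegistry()
#' @export
calibrantRegistry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "calibrants.csv",
                        package = "SpectralAccuracy", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "neutral_formula", "adduct")
  if (!all(need %in% names(df)))
    stop("calibrant file needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df$neutral_mass <- vapply(df$neutral_formula,
                            function(f) monoisotopicMass(parseFormula(f)), 0)
  df$ion_mz <- mapply(function(f, a) ionMz(parseFormula(f), a),
                      df$neutral_formula, df$adduct)
  rownames(df) <- NULL
  df
}
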