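test_that("monoisotopic masses of the calibrant set reproduce to 4 decimals", {
  known <- c(C8H10N4O2 = 194.0804,    # caffeine
             C8H14ClN5 = 215.0938,    # atrazine
             C7H15Cl2N2O2P = 260.0248, # cyclophosphamide
             C15H25NO3 = 267.1834,    # metoprolol
             C20H22O3 = 310.1569,     # avobenzone
             C19H20O4 = 312.1362)     # benzylbutyl phthalate
  for (f in names(known))
    expect_equal(round(monoisotopicMass(parseFormula(f)), 4), known[[f]])
  ## single-atom identity: H1 is the 1H isotope mass exactly
  tab <- isotopeTable()
  h1 <- tab$mass[tab$element == "H"][1]
  expect_identical(monoisotopicMass(parseFormula("H1")), h1)
})

test_that("ion m/z includes the electron-mass correction", {
  expect_equal(round(ionMz(parseFormula("C13H19NO"), "[M+H]+"), 4), 206.1539)
  expect_equal(round(ionMz(parseFormula("C14H27NO3"), "[M+Na]+"), 4), 280.1883)
  expect_equal(round(ionMz(parseFormula("C15H23NO3"), "[M+Na]+"), 4), 288.1570)
  ## protonation adds exactly mass(H) - m_e to the neutral mass at z = 1
  n <- parseFormula("C13H19NO")
  expect_equal(ionMz(n, "[M+H]+") - monoisotopicMass(n),
               monoisotopicMass(parseFormula("H1")) - electronMass(),
               tolerance = 1e-12)
  expect_error(ionMz(parseFormula("C6H6")), "charge")
})

test_that("formula parsing, Hill rendering and adducts round-trip", {
  for (txt in c("C13H20NO+", "C14H27NO3Na+", "C6H6", "CHCl3", "NH4+",
                "C12H27N7ONa+", "H2O2-", "C7H11ClO3Na+")) {
    f <- parseFormula(txt)
    expect_identical(formulaString(parseFormula(formulaString(f))),
                     formulaString(f))
  }
  ## typeset spellings normalise to the same composition
  expect_identical(formulaString(parseFormula("C_13_H_20_NO^+^")),
                   formulaString(parseFormula("C13H20NO+")))
  expect_identical(formulaString(parseFormula("C₁₃H₂₀NO⁺")),
                   formulaString(parseFormula("C13H20NO+")))
  ## digits before a sign are counts, not charges
  expect_identical(ionCharge(parseFormula("NH4+")), 1L)
  expect_identical(unname(elementCounts(parseFormula("NH4+"))["H"]), 4L)
  ## apply-then-remove an adduct is the identity
  n <- parseFormula("C13H19NO")
  for (a in c("[M+H]+", "[M+Na]+")) {
    back <- removeAdduct(applyAdduct(n, a), a)
    expect_identical(formulaString(back), formulaString(n))
    expect_identical(ionCharge(back), 0L)
  }
  expect_error(parseFormula("C3Xx2"), "Xx")
})

test_that("monoisotopic mass is additive over disjoint compositions", {
  set.seed(101)
  els <- c("C", "H", "N", "O", "Na", "Cl", "P", "S")
  for (i in 1:20) {
    ca <- setNames(sample(0:9, 4, replace = TRUE), sample(els, 4))
    cb <- setNames(sample(0:9, 4, replace = TRUE), sample(els, 4))
    if (all(ca == 0) || all(cb == 0)) next
    merged <- tapply(c(ca, cb), names(c(ca, cb)), sum)
    expect_equal(monoisotopicMass(newFormula(merged)),
                 monoisotopicMass(newFormula(ca[ca > 0])) +
                   monoisotopicMass(newFormula(cb[cb > 0])),
                 tolerance = 1e-10)
  }
})

test_that("RDBE follows the valence model", {
  expect_equal(rdbe(parseFormula("C13H20NO+")), 4.5)
  expect_equal(rdbe(parseFormula("NH4+")), -0.5)
  expect_equal(rdbe(parseFormula("C6H6")), 4)
  ## half-integer for even-electron singly charged CHNONaCl cations,
  ## integer for neutrals
  set.seed(7)
  for (i in 1:25) {
    cnt <- c(C = sample(1:20, 1), H = sample(0:30, 1), N = sample(0:5, 1),
             O = sample(0:5, 1), Na = sample(0:1, 1), Cl = sample(0:2, 1))
    r_ion <- rdbe(newFormula(cnt, charge = 1L))
    r_neutral <- rdbe(newFormula(cnt))
    expect_identical(r_ion, r_neutral)   # charge does not enter the formula
    expect_true(r_neutral %% 0.5 == 0)
    even_h <- (cnt[["H"]] + cnt[["Cl"]] + cnt[["Na"]] + cnt[["N"]]) %% 2 == 0
    expect_identical(r_neutral %% 1 == 0, even_h)
  }
})

test_that("mass accuracy reports measured minus exact in mDa at 0.1 precision", {
  expect_identical(massAccuracy(206.1538, 206.1539), -0.1)
  expect_identical(massAccuracy(308.2242, 308.2196), 4.6)
  expect_identical(massAccuracy(200.1234, 200.1234), 0)
})

test_that("isotope table is internally consistent", {
  tab <- isotopeTable()
  for (el in unique(tab$element)) {
    sub <- tab[tab$element == el, ]
    expect_equal(sum(sub$abundance), 1, tolerance = 1e-6)
    expect_false(is.unsorted(sub$mass, strictly = TRUE))
  }
  expect_true(all(c("C", "H", "N", "O", "Na", "Cl", "P", "S") %in%
                    tab$element))
})

test_that("the packaged calibrant registry resolves to the expected ion masses", {
  reg <- calibrantRegistry()
  expect_setequal(reg$name, c("caffeine", "atrazine", "cyclophosphamide",
                              "metoprolol", "avobenzone",
                              "benzylbutyl_phthalate"))
  expect_equal(round(reg$neutral_mass[reg$name == "caffeine"], 4), 194.0804)
  expect_equal(round(reg$ion_mz[reg$name == "caffeine"], 4),
               round(194.0804 + 1.00782503207 - 0.000548579909, 4))
})
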