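# brute-force oracle: full Cartesian scan over the element box, validated
# formula by formula through the public chem API
naiveEnumerate <- function(targetMz, constraints) {
  el <- constraints@elements
  grid <- expand.grid(lapply(seq_len(nrow(el)),
                             function(i) el$min[i]:el$max[i]))
  names(grid) <- el$element
  tol <- constraints@toleranceMda / 1000
  hits <- character(0)
  for (i in seq_len(nrow(grid))) {
    cnt <- unlist(grid[i, , drop = TRUE])
    if (all(cnt == 0)) next
    f <- newFormula(cnt, charge = constraints@charge)
    if (abs(ionMz(f) - targetMz) > tol + 1e-12) next
    r <- rdbe(f)
    if (r < constraints@rdbeRange[1] - 1e-9 ||
        r > constraints@rdbeRange[2] + 1e-9) next
    if (constraints@electrons != "both" &&
        electronParity(f) != constraints@electrons) next
    hits <- c(hits, formulaString(f))
  }
  sort(hits)
}


# brute-force oracle: expand the isotopologue polynomial atom by atom
# (exhaustive product over per-atom isotope choices), for formulas of at
# most ~15 atoms
bruteForcePattern <- function(counts, charge = 0L, prune = 1e-10) {
  tab <- isotopeTable()
  dist <- data.frame(mass = 0, prob = 1)
  for (el in names(counts)) {
    iso <- tab[tab$element == el, ]
    for (k in seq_len(counts[[el]])) {
      dist <- do.call(rbind, lapply(seq_len(nrow(iso)), function(j)
        data.frame(mass = dist$mass + iso$mass[j],
                   prob = dist$prob * iso$abundance[j])))
    }
  }
  dist$mass <- round(dist$mass, 6)   # collapse identical isotopologues
  agg <- aggregate(prob ~ mass, dist, sum)
  agg <- agg[order(agg$mass), ]
  agg <- agg[agg$prob > prune * max(agg$prob), ]
  if (charge != 0L)
    agg$mass <- (agg$mass - charge * electronMass()) / abs(charge)
  agg$ab <- agg$prob / max(agg$prob) * 100
  agg
}

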