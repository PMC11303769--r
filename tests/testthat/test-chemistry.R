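test_that("monoisotopic masses match a published residue-mass table", {
  expect_equal(monoisotopicMass(modifiedPeptide("G")), 75.03203, tolerance = 1e-5)
  for (seq in c("LRYPYP", "LRYPYPSY", "SMIRHPYP", "IRHPYPSY", "ACDEFGHIKLMNPQRSTVWY"))
    expect_equal(monoisotopicMass(modifiedPeptide(seq)), refPeptideMass(seq),
                 tolerance = 2e-4, label = seq)
  expect_equal(monoisotopicMass(modifiedPeptide("LRYPYP")), 807.4279,
               tolerance = 1e-4)
})

test_that("mass is additive under concatenation (condensation removes water)", {
  set.seed(11)
  aas <- names(REF_RESIDUE_MASS)
  for (i in 1:20) {
    a <- paste(sample(aas, sample(2:8, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(2:8, 1), replace = TRUE), collapse = "")
    expect_equal(monoisotopicMass(modifiedPeptide(paste0(a, b))),
                 monoisotopicMass(modifiedPeptide(a)) +
                   monoisotopicMass(modifiedPeptide(b)) - 18.010565,
                 tolerance = 1e-9)
  }
})

test_that("modification deltas and residue constraints are enforced", {
  reg <- defaultModifications()
  # mass deltas consistent with composition deltas
  for (i in seq_len(nrow(reg))) {
    d <- unlist(reg[i, c("dC", "dH", "dN", "dO", "dS", "dP")])
    m <- sum(d * c(12, 1.0078250319, 14.0030740052, 15.9949146221,
                   31.97207069, 30.97376151))
    expect_lt(abs(m - reg$deltaMass[i]), 1e-4)
  }
  # deamidation delta on any eligible residue
  base <- monoisotopicMass(modifiedPeptide("GNGG"))
  deam <- monoisotopicMass(modifiedPeptide("GNGG",
    list(list(position = 2, name = "Deamidation"))))
  expect_equal(deam - base, 0.984016, tolerance = 1e-5)
  # disallowed residues error
  expect_error(modifiedPeptide("LRYPYP",
    list(list(position = 1, name = "Deamidation"))), "not allowed")
  expect_error(modifiedPeptide("GGG",
    list(list(position = 2, name = "Gln->pyro-Glu"))), "N-termin")
  expect_error(modifiedPeptide("AB"), "unknown residue")
  expect_error(modifiedPeptide("GG",
    list(list(position = 5, name = "Oxidation"))))
})

test_that("modification registry file round-trips and validates masses", {
  f <- tempfile(fileext = ".tsv")
  writeModifications(defaultModifications(), f)
  back <- loadModifications(f)
  expect_equal(back$name, defaultModifications()$name)
  expect_equal(back$deltaMass, defaultModifications()$deltaMass, tolerance = 1e-6)
  # a stated mass inconsistent with the composition is rejected
  lines <- readLines(f)
  lines[2] <- sub("15\\.994915", "15.99", lines[2])
  writeLines(lines, f)
  expect_error(loadModifications(f), "inconsistent")
  # shipped registry file loads
  shipped <- loadModifications(system.file("extdata", "modifications.tsv",
                                           package = "enamelLFQ"))
  expect_setequal(shipped$name, defaultModifications()$name)
})

test_that("ionMz reproduces printed marker values and inverts exactly", {
  expect_equal(ionMz(monoisotopicMass(modifiedPeptide("LRYPYP")), 2),
               404.7212, tolerance = 5e-5)
  expect_equal(ionMz(monoisotopicMass(modifiedPeptide("LRYPYPSY")), 2),
               529.7689, tolerance = 5e-5)
  expect_equal(ionMz(100, 1), 100 + 1.007276, tolerance = 1e-6)
  for (z in 1:8) {
    m <- 1234.5678
    expect_equal(neutralMass(ionMz(m, z), z), m, tolerance = 1e-9)
  }
  expect_error(ionMz(100, 0), "positive")
})

test_that("elemental composition agrees with mass and handles glycine cases", {
  g <- elementalComposition("G")
  expect_equal(as.integer(g[c("C", "H", "N", "O")]), c(2L, 5L, 1L, 2L))
  gg <- elementalComposition("GG")
  expect_equal(as.integer(gg[c("C", "H", "N", "O")]), c(4L, 8L, 2L, 3L))
  for (seq in c("LRYPYP", "IRHPYPSY", "WCMST")) {
    expect_equal(compositionMass(elementalComposition(seq)),
                 monoisotopicMass(modifiedPeptide(seq)), tolerance = 1e-9)
    expect_equal(compositionMass(elementalComposition(seq)),
                 refPeptideMass(seq), tolerance = 2e-4)
  }
  # composition tracks modification deltas (oxidation adds one O)
  cx <- elementalComposition(modifiedPeptide("SMIRHPYP",
    list(list(position = 2, name = "Oxidation"))))
  c0 <- elementalComposition("SMIRHPYP")
  expect_equal(as.integer(cx["O"]) - as.integer(c0["O"]), 1L)
})

test_that("single-carbon envelope equals the natural 13C/12C ratio", {
  cc <- new("ElementalComposition", c(C = 1L))
  e <- isotopeEnvelope(cc, z = 1, nPeaks = 2, normalize = FALSE)
  expect_equal(e$abundance[2] / e$abundance[1], 0.0107 / 0.9893,
               tolerance = 1e-12)
  expect_equal(sum(e$abundance), 1, tolerance = 1e-9)
})

test_that("envelope abundances sum to one and m/z spacing is 1.00335/z", {
  for (seq in c("LRYPYP", "QQHPPQHTLQPHH")) {
    for (z in c(1L, 2L)) {
      e <- isotopeEnvelope(seq, z = z, nPeaks = 30, normalize = FALSE)
      expect_equal(sum(e$abundance), 1, tolerance = 1e-9)
      expect_equal(unique(round(diff(e$mz), 7)), round(1.0033548378 / z, 7))
      e4 <- isotopeEnvelope(seq, z = z, nPeaks = 4)
      expect_equal(sum(e4$abundance), 1, tolerance = 1e-12)
      expect_equal(e4$mz[1], ionMz(monoisotopicMass(modifiedPeptide(seq)), z),
                   tolerance = 1e-9)
    }
  }
})

test_that("convolution envelope matches exhaustive enumeration oracle", {
  set.seed(42)
  for (i in 1:25) {
    counts <- c(C = sample(0:8, 1), H = sample(0:8, 1), N = sample(0:3, 1),
                O = sample(0:3, 1), S = sample(0:2, 1), P = sample(0:1, 1))
    if (sum(counts) == 0 || sum(counts) > 20) next
    comp <- new("ElementalComposition", stats::setNames(as.integer(counts),
                                                        names(counts)))
    got <- isotopeEnvelope(comp, nPeaks = 40, normalize = FALSE)$abundance
    want <- enumEnvelopeOracle(counts)
    n <- max(length(got), length(want))
    got <- c(got, numeric(n - length(got)))
    want <- c(want, numeric(n - length(want)))
    expect_lt(max(abs(got - want)), 1e-10)
  }
  expect_error(isotopeEnvelope(new("ElementalComposition",
                                   c(C = 0L)), nPeaks = 2), "empty")
})

test_that("b/y fragment ions match residue arithmetic and complement to M+2H", {
  fr <- fragmentIons("LR")
  b2 <- fr$mz[fr$label == "b2^1"]
  expect_equal(b2, 270.1925, tolerance = 1e-3)
  y1 <- fragmentIons("PY")$mz
  expect_equal(fragmentIons("PY")$mz[fragmentIons("PY")$label == "y1^1"],
               182.0812, tolerance = 1e-3)
  set.seed(5)
  aas <- names(REF_RESIDUE_MASS)
  for (rep in 1:10) {
    seq <- paste(sample(aas, sample(3:10, 1), replace = TRUE), collapse = "")
    fr <- fragmentIons(seq)
    n <- nchar(seq)
    M <- monoisotopicMass(modifiedPeptide(seq))
    for (i in seq_len(n - 1)) {
      b <- fr$mz[fr$label == sprintf("b%d^1", i)]
      y <- fr$mz[fr$label == sprintf("y%d^1", n - i)]
      expect_equal(b + y, M + 2 * 1.00727646688, tolerance = 1e-6)
    }
  }
  # positioned modification lands only in containing fragments
  pep <- modifiedPeptide("SMIRHPYP", list(list(position = 2, name = "Oxidation")))
  fr0 <- fragmentIons("SMIRHPYP")
  frx <- fragmentIons(pep)
  expect_equal(frx$mz[frx$label == "b1^1"], fr0$mz[fr0$label == "b1^1"])
  expect_equal(frx$mz[frx$label == "b2^1"] - fr0$mz[fr0$label == "b2^1"],
               15.994915, tolerance = 1e-5)
  expect_equal(frx$mz[frx$label == "y6^1"], fr0$mz[fr0$label == "y6^1"])
  expect_equal(frx$mz[frx$label == "y7^1"] - fr0$mz[fr0$label == "y7^1"],
               15.994915, tolerance = 1e-5)
  expect_error(fragmentIons("G"), "length")
})
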