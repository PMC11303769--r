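# Independent oracles used by the tests. These deliberately avoid the
# package's computational paths (convolution, Biostrings matching) so that
# agreement is evidence, not tautology.

# Published monoisotopic residue masses (5 d.p.), typed in independently of
# the package's formula-derived table.
REF_RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

refPeptideMass <- function(seq) {
  sum(REF_RESIDUE_MASS[strsplit(seq, "")[[1]]]) + 18.010565
}

# Exhaustive isotopologue enumeration oracle: per element, enumerate every
# isotope composition of its n atoms with multinomial probabilities, then
# combine elements by full cross-product aggregation over nominal-mass
# offsets. Feasible for compositions of <= ~20 atoms.
ISO_TABLE <- list(
  C = list(off = c(0, 1), p = c(0.9893, 0.0107)),
  H = list(off = c(0, 1), p = c(0.999885, 0.000115)),
  N = list(off = c(0, 1), p = c(0.99636, 0.00364)),
  O = list(off = c(0, 1, 2), p = c(0.99757, 0.00038, 0.00205)),
  S = list(off = c(0, 1, 2, 4), p = c(0.9499, 0.0075, 0.0425, 0.0001)),
  P = list(off = 0, p = 1))

.compositionsOf <- function(n, k) {
  # all non-negative integer k-tuples summing to n
  if (k == 1L) return(matrix(n, ncol = 1))
  out <- list()
  for (i in 0:n) {
    rest <- .compositionsOf(n - i, k - 1L)
    out[[length(out) + 1L]] <- cbind(i, rest)
  }
  do.call(rbind, out)
}

enumEnvelopeOracle <- function(counts) {
  # counts: named vector over elements; returns abundance vector by offset
  agg <- c(`0` = 1.0)
  for (el in names(counts)) {
    n <- counts[[el]]
    if (n == 0) next
    tab <- ISO_TABLE[[el]]
    combos <- .compositionsOf(n, length(tab$p))
    offs <- drop(combos %*% tab$off)
    probs <- apply(combos, 1, function(x) stats::dmultinom(x, prob = tab$p))
    eltab <- tapply(probs, offs, sum)
    # cross-product aggregation
    newOff <- as.numeric(outer(as.numeric(names(agg)),
                               as.numeric(names(eltab)), `+`))
    newP <- as.numeric(outer(unname(agg), unname(eltab), `*`))
    agg <- tapply(newP, newOff, sum)
  }
  out <- numeric(max(as.numeric(names(agg))) + 1L)
  out[as.numeric(names(agg)) + 1L] <- agg
  out
}

# Naive all-positions substring scan (oracle for the uniqueness search).
naiveFind <- function(pattern, subject) {
  n <- nchar(subject); m <- nchar(pattern)
  if (m > n) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(n - m + 1L))
    if (substr(subject, i, i + m - 1L) == pattern) hits <- c(hits, i)
  hits
}

# Random run generator for I/O round-trip property tests.
randomRun <- function(seed, nSpec = 6L) {
  set.seed(seed)
  spectra <- lapply(seq_len(nSpec), function(i) {
    ms <- if (i %% 3 == 0) 2L else 1L
    np <- sample(0:20, 1)
    mz <- sort(runif(np, 100, 1500))
    mz <- mz[!duplicated(mz)]
    spectrum(sprintf("s%d", i), ms, rt = i * 2.5,
             mz = mz, intensity = rexp(length(mz), 1e-4),
             precursorMz = if (ms == 2L) runif(1, 300, 800) else NA_real_,
             precursorCharge = if (ms == 2L) 2L else NA_integer_,
             isolationHalfWidth = if (ms == 2L) 0.85 else NA_real_)
  })
  msRun(sprintf("rand%d", seed), spectra)
}

# Low-noise sample spec used across quantification tests.
quietSpec <- function(sampleId, sex = "male", era = "modern", seed = 1L, ...) {
  sampleSpec(sampleId, sex, era, ppmJitter = 0, noiseCV = 0, baseline = 0,
             decoyDensity = 0, seed = seed, ...)
}

expectRunsEqual <- function(a, b, tol = 1e-6) {
  expect_equal(nScans(a), nScans(b))
  for (i in seq_len(nScans(a))) {
    sa <- a@spectra[[i]]; sb <- b@spectra[[i]]
    expect_equal(sa@msLevel, sb@msLevel)
    expect_equal(sa@rt, sb@rt, tolerance = tol)
    expect_equal(sa@mz, sb@mz, tolerance = tol)
    expect_equal(sa@intensity, sb@intensity, tolerance = tol)
    if (sa@msLevel == 2L)
      expect_equal(sa@precursorMz, sb@precursorMz, tolerance = tol)
  }
}
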