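test_that("XIC extraction sums only peaks inside the ppm window", {
  run <- msRun("t", list(
    spectrum("s1", 1L, rt = 1, mz = c(400.0, 404.7212, 404.7300), intensity = c(5, 10, 7)),
    spectrum("s2", 1L, rt = 2, mz = c(404.7215, 404.72121), intensity = c(3, 2)),
    spectrum("s3", 1L, rt = 3, mz = 900, intensity = 4)))
  xic <- extractXIC(run, 404.7212, tolPpm = 10)[[1]]
  expect_equal(xic$intensity, c(10, 5, 0))  # 404.73 is ~22 ppm away
  empty <- extractXIC(run, 600, tolPpm = 10)[[1]]
  expect_true(all(empty$intensity == 0))
  expect_error(extractXIC(msRun("no"), 500, 10), "no MS1")
})

test_that("peak integration recovers the closed-form Gaussian area", {
  rt <- seq(0, 200, by = 1)
  apex <- 1e6; sd <- 3; mu <- 90
  tr <- data.frame(rt = rt, intensity = apex * exp(-(rt - mu)^2 / (2 * sd^2)))
  res <- detectAndIntegrate(list(tr))
  expect_equal(res$apexRt, mu)
  expect_lt(abs(res$area / (apex * sd * sqrt(2 * pi)) - 1), 0.02)
  expect_true(res$rtStart < mu && res$rtEnd > mu)
  # all-zero trace
  z <- detectAndIntegrate(list(data.frame(rt = rt, intensity = 0)))
  expect_true(is.na(z$apexRt))
  expect_equal(z$area, 0)
})

test_that("an expected RT window selects the smaller of two disjoint peaks", {
  rt <- seq(0, 300, by = 1)
  big <- 1e6 * exp(-(rt - 80)^2 / 18)
  small <- 2e5 * exp(-(rt - 220)^2 / 18)
  tr <- data.frame(rt = rt, intensity = big + small)
  unrestricted <- detectAndIntegrate(list(tr))
  expect_equal(unrestricted$apexRt, 80)
  windowed <- detectAndIntegrate(list(tr), expectedRt = 225)
  expect_equal(windowed$apexRt, 220)
  expect_lt(windowed$area, unrestricted$area)
})

test_that("envelope score is a bounded scale-invariant cosine", {
  th <- isotopeEnvelope("LRYPYP", z = 2)$abundance
  expect_equal(envelopeScore(3.7 * th, th), 1, tolerance = 1e-12)
  expect_equal(envelopeScore(th, 3.7 * th), 1, tolerance = 1e-12)
  expect_lt(envelopeScore(c(1, 0, 0, 0), th), 0.9)
  expect_equal(envelopeScore(c(0, 0, 0, 0), th), 0)
  expect_equal(envelopeScore(c(0, 1, 0, 0), c(1, 0, 0, 0)), 0)
  set.seed(2)
  for (i in 1:10) {
    a <- runif(4); b <- runif(4)
    s <- envelopeScore(a, b)
    expect_true(s >= 0 && s <= 1)
    expect_equal(s, envelopeScore(b, a), tolerance = 1e-12)
    expect_equal(s, envelopeScore(5 * a, b), tolerance = 1e-12)
  }
  expect_error(envelopeScore(c(1, 2), c(1, 2, 3)), "length")
})

test_that("a 10 ppm window captures ~95% of 5-ppm-jittered intensity", {
  # with Gaussian mass error of sd 5 ppm, a +/-10 ppm window captures a peak
  # with probability 2*pnorm(2) - 1 = 0.9545 >= 0.95; the Monte-Carlo
  # estimate over seeds must agree with that expectation
  expect_gte(2 * pnorm(2) - 1, 0.95)
  kept <- vapply(1:6, function(seed) {
    spec <- sampleSpec("j", "male", "modern", seed = seed, runLength = 200,
                       ppmJitter = 5, noiseCV = 0, baseline = 0,
                       decoyDensity = 0,
                       markerApex = c(Y2 = 0, X1 = 0, X2 = 0),
                       background = defaultBackground(200)[0, ])
    sim <- simulateRun(spec, ms2 = FALSE)
    env <- isotopeEnvelope("LRYPYP", z = 2, nPeaks = 4)
    xics <- extractXIC(sim$run, env$mz, tolPpm = 10)
    sum(vapply(xics, function(x) sum(x$intensity), numeric(1))) /
      (spec@markerApex[["Y1"]] / spec@scanInterval * spec@peakWidth * sqrt(2 * pi))
  }, numeric(1))
  expect_equal(mean(kept), 2 * pnorm(2) - 1, tolerance = 0.03)
})

test_that("MS2 validation counts fragments and degrades gracefully", {
  marker <- defaultPanel()@markers[[1]]  # Y1 = LRYPYP, 404.7212
  frag <- fragmentIons("LRYPYP")
  full <- msRun("v", list(
    spectrum("s1", 1L, rt = 1, mz = 404.7212, intensity = 1e6),
    spectrum("s2", 2L, rt = 1.1, mz = sort(frag$mz[frag$mz >= 100]),
             intensity = rep(1e4, sum(frag$mz >= 100)),
             precursorMz = 404.7212, precursorCharge = 2L,
             isolationHalfWidth = 0.85)))
  v <- ms2Validate(full, marker)
  expect_true(v$pass)
  expect_gte(v$matched, 8)
  # decoy-only MS2 near the precursor fails
  decoy <- msRun("d", list(
    spectrum("s1", 1L, rt = 1, mz = 404.7212, intensity = 1e6),
    spectrum("s2", 2L, rt = 1.1, mz = c(111.11, 222.22, 333.33),
             intensity = rep(1e3, 3), precursorMz = 404.75,
             precursorCharge = 2L, isolationHalfWidth = 0.85)))
  vd <- ms2Validate(decoy, marker)
  expect_false(vd$pass)
  # MS1-only run: not evaluated, quantification proceeds
  ms1only <- msRun("m", list(spectrum("s1", 1L, rt = 1, mz = 404.7212,
                                      intensity = 1e6)))
  vn <- ms2Validate(ms1only, marker)
  expect_identical(vn$matched, 0L)
  expect_true(is.na(vn$pass))
})

test_that("marker quantification detects true signal and records failures", {
  panel <- defaultPanel()
  male <- simulateRun(sampleSpec("m", "male", "modern", seed = 31,
                                 runLength = 300,
                                 background = defaultBackground(300)[0, ]))
  qm <- quantifyMarker(male$run, panel@markers[[1]])
  expect_true(qm$detected)
  expect_equal(qm$reasons, "")
  expect_gte(qm$envelopeScore, 0.95)
  # female run without baseline: area is zero
  fem <- simulateRun(sampleSpec("f", "female", "modern", seed = 32,
                                runLength = 300, baseline = 0,
                                decoyDensity = 0,
                                background = defaultBackground(300)[0, ]))
  qf <- quantifyMarker(fem$run, panel@markers[[1]])
  expect_false(qf$detected)
  expect_match(qf$reasons, "area below floor")
  # corrupted envelope: keep only the monoisotopic trace
  ms1 <- spectraOf(male$run, msLevel = 1L)
  corrupt <- lapply(ms1, function(s) {
    keep <- abs(s@mz - 404.7212) / 404.7212 <= 10e-6 | s@mz > 407
    spectrum(s@scanId, 1L, s@rt, s@mz[keep], s@intensity[keep])
  })
  qc <- quantifyMarker(msRun("c", corrupt), panel@markers[[1]])
  expect_false(qc$detected)
  expect_match(qc$reasons, "envelope_score")
})

test_that("areas scale exactly linearly with run intensity", {
  sim <- simulateRun(quietSpec("lin", runLength = 200,
                               background = defaultBackground(200)[0, ]),
                     ms2 = FALSE)
  scaled <- msRun("lin2", lapply(sim$run@spectra, function(s)
    spectrum(s@scanId, s@msLevel, s@rt, s@mz, s@intensity * 3.5)))
  q1 <- quantifyPanel(sim$run, defaultPanel())
  q2 <- quantifyPanel(scaled, defaultPanel())
  expect_equal(q2$area, 3.5 * q1$area, tolerance = 1e-12)
})

test_that("quantified areas recover injected ground truth within 5%", {
  for (seed in 1:3) {
    spec <- sampleSpec("r", "male", "modern", seed = seed, runLength = 300,
                       ppmJitter = 1, noiseCV = 0.02, baseline = 0,
                       decoyDensity = 0, background = defaultBackground(300)[0, ])
    sim <- simulateRun(spec)
    q <- quantifyPanel(sim$run, defaultPanel())
    gt <- sim$groundTruth$forms
    relerr <- abs(q$area / gt$area[match(q$marker, gt$id)] - 1)
    expect_true(all(relerr < 0.05))
  }
})
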