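# Simulator tests use shortened runs where the property does not depend on
# the full 600 s default, to keep the suite fast.

test_that("simulation is byte-identical under a fixed seed", {
  spec <- sampleSpec("d1", "male", "modern", seed = 99L, runLength = 120)
  fa <- tempfile(); fb <- tempfile()
  writeRun(simulateRun(spec)$run, fa, "internal")
  writeRun(simulateRun(spec)$run, fb, "internal")
  expect_identical(readLines(fa), readLines(fb))
})

test_that("female runs without baseline or decoys have no AmelY signal", {
  spec <- sampleSpec("f1", "female", "modern", baseline = 0, decoyDensity = 0,
                     seed = 5L, runLength = 200,
                     background = defaultBackground(200))
  run <- simulateRun(spec)$run
  xic <- extractXIC(run, 404.7212, tolPpm = 10)[[1]]
  expect_true(all(xic$intensity == 0))
  # the AmelX control signal is still there
  xicX <- extractXIC(run, 508.7527, tolPpm = 10)[[1]]
  expect_gt(max(xicX$intensity), 0)
})

test_that("zero-noise XIC sum matches the closed-form Gaussian integral", {
  spec <- quietSpec("g1", runLength = 300,
                    markerApex = c(Y2 = 0, X1 = 0, X2 = 0),
                    background = defaultBackground(300)[0, ])
  sim <- simulateRun(spec, ms2 = FALSE)
  env <- isotopeEnvelope("LRYPYP", z = 2, nPeaks = 4)
  xics <- extractXIC(sim$run, env$mz, tolPpm = 10)
  total <- sum(vapply(xics, function(x) sum(x$intensity), numeric(1))) *
    spec@scanInterval
  closed <- spec@markerApex[["Y1"]] * spec@peakWidth * sqrt(2 * pi)
  expect_lt(abs(total / closed - 1), 0.01)
  # ground truth records the same closed-form area
  gt <- sim$groundTruth$forms
  expect_equal(gt$area[gt$id == "Y1"], unname(closed), tolerance = 1e-9)
})

test_that("doubling a marker apex exactly doubles its injected intensity", {
  base <- quietSpec("l1", runLength = 200, background = defaultBackground(200)[0, ])
  spec2 <- quietSpec("l1", runLength = 200, background = defaultBackground(200)[0, ],
                     markerApex = c(Y1 = 1e8))
  x1 <- extractXIC(simulateRun(base, ms2 = FALSE)$run, 404.7212, 10)[[1]]
  x2 <- extractXIC(simulateRun(spec2, ms2 = FALSE)$run, 404.7212, 10)[[1]]
  nz <- x1$intensity > 0
  expect_true(any(nz))
  expect_equal(x2$intensity[nz] / x1$intensity[nz], rep(2, sum(nz)),
               tolerance = 1e-12)
})

test_that("cohorts carry AmelY signal in exactly the male samples", {
  coh <- simulateCohort(8, rep(c("male", "female"), each = 4), "modern",
                        seed = 123, runLength = 150,
                        background = defaultBackground(150)[0, ])
  hasY <- vapply(coh$samples, function(s) {
    xic <- extractXIC(s$run, 404.7212, 10)[[1]]
    sum(xic$intensity) > 1e5
  }, logical(1))
  expect_equal(sum(hasY), 4L)
  expect_equal(hasY, coh$manifest$sex == "male")
  expect_error(simulateCohort(0, "male", "modern"), ">= 1")
})

test_that("archaeological specs default to higher deamidation occupancies", {
  coh <- simulateCohort(4, "female", c("modern", "modern",
                                       "archaeological", "archaeological"),
                        seed = 7, runLength = 150)
  pN <- vapply(coh$samples, function(s) s$groundTruth$pN, numeric(1))
  pQ <- vapply(coh$samples, function(s) s$groundTruth$pQ, numeric(1))
  expect_equal(mean(pN[3:4]) / mean(pN[1:2]), 3, tolerance = 1e-9)
  expect_equal(mean(pQ[3:4]) / mean(pQ[1:2]), 5, tolerance = 1e-9)
})

test_that("changing one sample's sub-seed leaves other samples unchanged", {
  coh1 <- simulateCohort(3, "male", "modern", seed = 11, runLength = 100,
                         background = defaultBackground(100)[0, ])
  # regenerate sample 2 with a different seed; samples 1 and 3 as before
  spec2 <- coh1$samples[[2]]$spec
  spec2@seed <- spec2@seed + 1000L
  sim2 <- simulateRun(spec2)
  coh2 <- simulateCohort(3, "male", "modern", seed = 11, runLength = 100,
                         background = defaultBackground(100)[0, ])
  f1 <- tempfile(); f2 <- tempfile()
  writeRun(coh1$samples[[1]]$run, f1); writeRun(coh2$samples[[1]]$run, f2)
  expect_identical(readLines(f1), readLines(f2))
  writeRun(coh1$samples[[3]]$run, f1); writeRun(coh2$samples[[3]]$run, f2)
  expect_identical(readLines(f1), readLines(f2))
  # and the regenerated sample 2 differs from the original
  writeRun(coh1$samples[[2]]$run, f1); writeRun(sim2$run, f2)
  expect_false(identical(readLines(f1), readLines(f2)))
})

test_that("marker RT outside the run length is rejected", {
  expect_error(sampleSpec("bad", "male", "modern", runLength = 100,
                          markerRt = c(Y1 = 500),
                          background = defaultBackground(100)),
               "within the run length")
})

test_that("DDA MS2 spectra carry the marker fragments with precursor info", {
  spec <- sampleSpec("ms2", "male", "modern", seed = 21, runLength = 150,
                     background = defaultBackground(150)[0, ],
                     decoyDensity = 2)
  run <- simulateRun(spec)$run
  ms2 <- spectraOf(run, msLevel = 2L)
  expect_gt(length(ms2), 0)
  pre <- vapply(ms2, function(s) s@precursorMz, numeric(1))
  near <- abs(pre - 404.7212) < 0.01
  expect_true(any(near))
  s <- ms2[near][[1]]
  frag <- fragmentIons("LRYPYP")
  matched <- vapply(frag$mz[frag$mz >= 100], function(fm)
    any(abs(s@mz - fm) / fm < 20e-6), logical(1))
  expect_gte(sum(matched), 8)
})
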