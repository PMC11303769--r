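# Deterministic DDA run simulator with ground truth.
#
# The simulator emulates, at desk scale, the structure of the enamel
# peptidome runs the pipeline is designed for: MS1 survey scans over
# 350-1650 m/z containing Gaussian chromatographic elution peaks for the
# four marker peptides (AmelY markers present only in male samples),
# partially deamidated AmelX-like background peptides whose occupancy is
# higher in "archaeological" samples, random decoy peaks, and top-N DDA MS2
# spectra with dynamic exclusion.

#' Default background peptides
#'
#' Asn/Gln-containing peptides drawn from the synthetic AmelX-like protein
#' shipped with the package, used by the simulator to carry the deamidation
#' signal and by [occupancyFromRun()] as the default quantified forms. One
#' peptide carries only Asn sites and the other only Gln sites: positional
#' deamidation isomers are isobaric, so per-class occupancy is identifiable
#' from MS1 signal only when a peptide's sites are all of one class.
#'
#' @param runLength run length (s) the elution apexes are placed within.
#' @return data.frame with columns \code{sequence}, \code{apex}, \code{rt}.
#' @export
defaultBackground <- function(runLength = 600) {
  data.frame(sequence = c("INHSYENSHSA", "QQHPPQHTLQ"),
             apex = c(2e7, 2e7), rt = runLength * c(1 / 3, 0.7),
             stringsAsFactors = FALSE)
}

#' Specify a synthetic sample
#'
#' Builds a [SampleSpec-class] with study-condition defaults: a 600 s run at
#' 1 s MS1 cycle time, 6 s FWHM Gaussian elution (sd 2.548 s), marker apex
#' intensities of 5e7 ion counts, 2 ppm mass jitter, 5\% multiplicative
#' intensity noise, a baseline of 50 counts at each marker m/z, 20 decoy
#' peaks per scan, and era-dependent deamidation occupancies (modern:
#' pN = 0.20, pQ = 0.10; archaeological: pN = 0.60, pQ = 0.50, i.e. 3x and
#' 5x the modern values). Female samples have their AmelY marker apex
#' intensities forced to zero.
#'
#' @param sampleId sample identifier.
#' @param sex \code{"male"} or \code{"female"}.
#' @param era \code{"modern"} or \code{"archaeological"}.
#' @param panel the [MarkerPanel-class] the marker parameters refer to.
#' @param markerApex named apex intensities per marker id (defaults filled
#'   for missing markers).
#' @param markerRt named elution apex RTs (s); defaults spread the markers
#'   across the run.
#' @param peakWidth Gaussian elution sd in seconds.
#' @param scanInterval,runLength MS1 cycle time and run length (s).
#' @param ppmJitter Gaussian sd of mass error, ppm.
#' @param baseline additive background intensity at each marker m/z.
#' @param noiseCV multiplicative intensity noise CV (0 = noise-free).
#' @param pN,pQ deamidation occupancies; default by era as above.
#' @param background background peptide table (see [defaultBackground()]);
#'   pass a 0-row data.frame for none.
#' @param decoyDensity expected decoy peaks per MS1 scan.
#' @param seed integer RNG seed.
#' @return a [SampleSpec-class].
#' @examples
#' sampleSpec("s1", "male", "modern", seed = 1)
#' @export
sampleSpec <- function(sampleId, sex = c("male", "female"),
                       era = c("modern", "archaeological"),
                       panel = defaultPanel(),
                       markerApex = NULL, markerRt = NULL,
                       peakWidth = 6 / (2 * sqrt(2 * log(2))),
                       scanInterval = 1, runLength = 600,
                       ppmJitter = 2, baseline = 50, noiseCV = 0.05,
                       pN = NULL, pQ = NULL,
                       background = defaultBackground(runLength),
                       decoyDensity = 20, seed = 1L) {
  sex <- match.arg(sex)
  era <- match.arg(era)
  ids <- .markerIds(panel)
  apex <- stats::setNames(rep(5e7, length(ids)), ids)
  if (!is.null(markerApex)) apex[names(markerApex)] <- markerApex
  src <- .markerSources(panel)
  if (sex == "female") apex[ids[src == "AmelY"]] <- 0
  rts <- stats::setNames(runLength * seq(0.15, 0.85, length.out = length(ids)), ids)
  if (!is.null(markerRt)) rts[names(markerRt)] <- markerRt
  if (is.null(pN)) pN <- if (era == "archaeological") 0.60 else 0.20
  if (is.null(pQ)) pQ <- if (era == "archaeological") 0.50 else 0.10
  new("SampleSpec", sampleId = sampleId, sex = sex, era = era,
      markerApex = apex, markerRt = rts, peakWidth = peakWidth,
      scanInterval = scanInterval, runLength = runLength,
      ppmJitter = ppmJitter, baseline = baseline, noiseCV = noiseCV,
      pN = pN, pQ = pQ, background = background,
      decoyDensity = decoyDensity, seed = as.integer(seed))
}

# Enumerate the deamidated forms of a background peptide: each N/Q site is
# independently deamidated with probability pN/pQ and the intensity is split
# deterministically across forms by the product of the per-site weights.
# Forms below `prune` of the total are dropped and the remaining weights are
# renormalized.
.deamidationForms <- function(sequence, pN, pQ, prune = 0.001) {
  letters1 <- strsplit(sequence, "")[[1]]
  sites <- which(letters1 %in% c("N", "Q"))
  p <- ifelse(letters1[sites] == "N", pN, pQ)
  k <- length(sites)
  if (!k)
    return(data.frame(sequence = sequence, deamidated = I(list(integer(0))),
                      weight = 1, nDeamN = 0L, nDeamQ = 0L))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    on <- as.logical(combos[i, ])
    w <- prod(ifelse(on, p, 1 - p))
    data.frame(sequence = sequence,
               deamidated = I(list(sites[on])),
               weight = w,
               nDeamN = sum(on & letters1[sites] == "N"),
               nDeamQ = sum(on & letters1[sites] == "Q"))
  })
  out <- do.call(rbind, rows)
  out <- out[out$weight >= prune, , drop = FALSE]
  out$weight <- out$weight / sum(out$weight)
  rownames(out) <- NULL
  out
}

# Build the peptide form table for a spec: markers plus background forms.
.formTable <- function(spec, panel, nPeaks = 4L) {
  forms <- list()
  for (m in panel@markers) {
    env <- isotopeEnvelope(m@peptide, z = m@charge, nPeaks = nPeaks)
    forms[[length(forms) + 1L]] <- list(
      id = m@id, kind = "marker", peptide = m@peptide, charge = m@charge,
      apex = unname(spec@markerApex[m@id]), rt = unname(spec@markerRt[m@id]),
      envMz = env$mz, envAb = env$abundance,
      nSitesN = NA_integer_, nDeamN = NA_integer_,
      nSitesQ = NA_integer_, nDeamQ = NA_integer_)
  }
  bg <- spec@background
  if (nrow(bg)) {
    for (b in seq_len(nrow(bg))) {
      letters1 <- strsplit(bg$sequence[b], "")[[1]]
      nN <- sum(letters1 == "N"); nQ <- sum(letters1 == "Q")
      ft <- .deamidationForms(bg$sequence[b], spec@pN, spec@pQ)
      for (i in seq_len(nrow(ft))) {
        sites <- ft$deamidated[[i]]
        mods <- if (length(sites))
          lapply(sites, function(p) list(position = p, name = "Deamidation"))
        else list()
        pep <- modifiedPeptide(bg$sequence[b], mods)
        env <- isotopeEnvelope(pep, z = 2L, nPeaks = nPeaks)
        forms[[length(forms) + 1L]] <- list(
          id = sprintf("bg%d.f%d", b, i), kind = "background",
          peptide = pep, charge = 2L,
          apex = bg$apex[b] * ft$weight[i], rt = bg$rt[b],
          envMz = env$mz, envAb = env$abundance,
          nSitesN = nN, nDeamN = ft$nDeamN[i],
          nSitesQ = nQ, nDeamQ = ft$nDeamQ[i])
      }
    }
  }
  forms
}

#' Simulate one DDA run
#'
#' Generates an MS1/MS2 run from a [SampleSpec-class] with known ground
#' truth. Each peptide form contributes its 4 aggregated isotopologues
#' scaled by a Gaussian elution profile; ppm jitter and multiplicative noise
#' are applied per emitted peak. MS2 spectra are generated DDA-style per
#' cycle: the top-N MS1 peaks above the trigger intensity and not on the
#' 20 s dynamic-exclusion list are "fragmented" into their singly charged
#' b/y ions plus decoy peaks (ties broken by intensity descending, then m/z
#' ascending). The output is deterministic given the spec's seed.
#'
#' @param spec a [SampleSpec-class].
#' @param panel the [MarkerPanel-class] quantified downstream.
#' @param topN precursors selected per DDA cycle.
#' @param exclusionWindow dynamic exclusion time, seconds.
#' @param minMs2Intensity minimum MS1 peak intensity to trigger MS2.
#' @param ms2 set FALSE to skip MS2 generation (MS1-only run).
#' @return list with elements \code{run} (an [MSRun-class]) and
#'   \code{groundTruth}: a list with the per-form table (\code{forms}:
#'   id, kind, sequence, charge, injected closed-form area
#'   apex*width*sqrt(2*pi), deamidation site/mod counts), \code{sex},
#'   \code{era}, \code{pN}, \code{pQ}.
#' @examples
#' sim <- simulateRun(sampleSpec("toy", "male", "modern", runLength = 100,
#'                               background = defaultBackground()[0, ],
#'                               seed = 7))
#' sim$run
#' @export
simulateRun <- function(spec, panel = defaultPanel(), topN = 10L,
                        exclusionWindow = 20, minMs2Intensity = 1e4,
                        ms2 = TRUE) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec@seed)

  forms <- .formTable(spec, panel)
  if (any(vapply(forms, function(f) f$rt, numeric(1)) > spec@runLength))
    stop("marker RT outside run length")
  scanTimes <- seq(0, spec@runLength, by = spec@scanInterval)
  nScan <- length(scanTimes)
  nPeaks <- length(forms[[1]]$envMz)

  # emit peaks: per form, scans where the Gaussian is non-negligible
  emitScan <- integer(0); emitMz <- numeric(0); emitInt <- numeric(0)
  emitForm <- integer(0)
  for (fi in seq_along(forms)) {
    f <- forms[[fi]]
    if (f$apex <= 0) next
    g <- f$apex * exp(-(scanTimes - f$rt)^2 / (2 * spec@peakWidth^2))
    keep <- which(g >= f$apex * 1e-4)
    if (!length(keep)) next
    nk <- length(keep)
    emitScan <- c(emitScan, rep(keep, each = nPeaks))
    emitMz <- c(emitMz, rep(f$envMz, times = nk))
    emitInt <- c(emitInt, as.numeric(t(outer(g[keep], f$envAb))))
    emitForm <- c(emitForm, rep(fi, nk * nPeaks))
  }
  # baseline peaks at each marker monoisotopic m/z, every scan
  if (spec@baseline > 0) {
    markerMz0 <- vapply(panel@markers, function(m)
      ionMz(monoisotopicMass(m@peptide), m@charge), numeric(1))
    emitScan <- c(emitScan, rep(seq_len(nScan), each = length(markerMz0)))
    emitMz <- c(emitMz, rep(markerMz0, times = nScan))
    emitInt <- c(emitInt, rep(spec@baseline, nScan * length(markerMz0)))
    emitForm <- c(emitForm, rep(NA_integer_, nScan * length(markerMz0)))
  }
  # noise
  npk <- length(emitMz)
  if (npk) {
    if (spec@ppmJitter > 0)
      emitMz <- emitMz * (1 + stats::rnorm(npk, 0, spec@ppmJitter) * 1e-6)
    if (spec@noiseCV > 0) {
      sdlog <- sqrt(log(1 + spec@noiseCV^2))
      emitInt <- emitInt * stats::rlnorm(npk, -sdlog^2 / 2, sdlog)
    }
  }
  # decoys: uniform m/z in [350, 1650], exponential intensities (mean 1000)
  if (spec@decoyDensity > 0) {
    nd <- stats::rpois(nScan, spec@decoyDensity)
    td <- sum(nd)
    if (td) {
      emitScan <- c(emitScan, rep(seq_len(nScan), times = nd))
      emitMz <- c(emitMz, stats::runif(td, 350, 1650))
      emitInt <- c(emitInt, stats::rexp(td, rate = 1 / 1000))
      emitForm <- c(emitForm, rep(NA_integer_, td))
    }
  }

  byScan <- split(seq_along(emitScan), factor(emitScan, levels = seq_len(nScan)))
  spectra <- vector("list", 0)
  exclMz <- numeric(0); exclUntil <- numeric(0)
  scanCounter <- 0L
  for (si in seq_len(nScan)) {
    idx <- byScan[[si]]
    t <- scanTimes[si]
    scanCounter <- scanCounter + 1L
    spectra[[length(spectra) + 1L]] <- spectrum(
      scanId = sprintf("scan=%d", scanCounter), msLevel = 1L, rt = t,
      mz = emitMz[idx], intensity = emitInt[idx])
    if (!ms2 || !length(idx)) next
    # DDA precursor selection
    keepEx <- exclUntil > t
    exclMz <- exclMz[keepEx]; exclUntil <- exclUntil[keepEx]
    cand <- idx[emitInt[idx] >= minMs2Intensity]
    if (!length(cand)) next
    if (length(exclMz)) {
      excluded <- vapply(emitMz[cand], function(m)
        any(abs(m - exclMz) / m <= 10e-6), logical(1))
      cand <- cand[!excluded]
    }
    if (!length(cand)) next
    o <- order(-emitInt[cand], emitMz[cand])
    sel <- cand[o][seq_len(min(topN, length(cand)))]
    for (k in seq_along(sel)) {
      pk <- sel[k]
      scanCounter <- scanCounter + 1L
      fi <- emitForm[pk]
      if (!is.na(fi)) {
        f <- forms[[fi]]
        fr <- fragmentIons(f$peptide, maxCharge = 1L)
        fmz <- fr$mz[fr$mz >= 100]
        fint <- rep(emitInt[pk] * 0.1, length(fmz))
      } else {
        fmz <- numeric(0); fint <- numeric(0)
      }
      ndec <- stats::rpois(1, max(1, spec@decoyDensity / 2))
      fmz <- c(fmz, stats::runif(ndec, 100, 1200))
      fint <- c(fint, stats::rexp(ndec, rate = 1 / 1000))
      spectra[[length(spectra) + 1L]] <- spectrum(
        scanId = sprintf("scan=%d", scanCounter), msLevel = 2L,
        rt = t + k * spec@scanInterval / (topN + 2),
        mz = fmz, intensity = fint,
        precursorMz = emitMz[pk],
        precursorCharge = if (!is.na(fi)) forms[[fi]]$charge else NA_integer_,
        isolationHalfWidth = 0.85)
      exclMz <- c(exclMz, emitMz[pk])
      exclUntil <- c(exclUntil, t + exclusionWindow)
    }
  }

  gt <- data.frame(
    id = vapply(forms, `[[`, character(1), "id"),
    kind = vapply(forms, `[[`, character(1), "kind"),
    sequence = vapply(forms, function(f) f$peptide@sequence, character(1)),
    charge = vapply(forms, `[[`, integer(1), "charge"),
    apex = vapply(forms, `[[`, numeric(1), "apex"),
    rt = vapply(forms, `[[`, numeric(1), "rt"),
    area = vapply(forms, function(f) f$apex * spec@peakWidth * sqrt(2 * pi),
                  numeric(1)),
    nSitesN = vapply(forms, `[[`, integer(1), "nSitesN"),
    nDeamN = vapply(forms, `[[`, integer(1), "nDeamN"),
    nSitesQ = vapply(forms, `[[`, integer(1), "nSitesQ"),
    nDeamQ = vapply(forms, `[[`, integer(1), "nDeamQ"),
    stringsAsFactors = FALSE)

  run <- msRun(spec@sampleId, spectra,
               metadata = list(sex = spec@sex, era = spec@era, seed = spec@seed))
  list(run = run, groundTruth = list(forms = gt, sex = spec@sex, era = spec@era,
                                     pN = spec@pN, pQ = spec@pQ))
}

#' Simulate a cohort of runs
#'
#' Generates \code{n} runs with per-sample sub-seeds derived
#' deterministically from the master seed, so changing one sample's
#' sub-seed leaves the others unchanged. Per-sample apex intensities are
#' jittered log-normally (sdlog 0.4) around the spec defaults to emulate
#' sample-dependent signal.
#'
#' @param n number of samples (>= 1).
#' @param sexes character vector of length n (\code{"male"}/\code{"female"}),
#'   recycled if length 1.
#' @param eras character vector of length n, recycled if length 1.
#' @param seed master seed.
#' @param panel marker panel.
#' @param ... further arguments passed to [sampleSpec()] (e.g. noise
#'   settings).
#' @return list with \code{samples}: a list of
#'   \code{list(run, groundTruth, spec)}, and \code{manifest}: a data.frame
#'   (sample_id, sex, era, seed).
#' @examples
#' coh <- simulateCohort(2, c("male", "female"), "modern", seed = 1,
#'                       runLength = 100, background = defaultBackground()[0, ])
#' coh$manifest
#' @export
simulateCohort <- function(n, sexes, eras, seed = 1L, panel = defaultPanel(),
                           ...) {
  if (n < 1L) stop("n must be >= 1")
  sexes <- rep_len(sexes, n)
  eras <- rep_len(eras, n)
  # sub-seeds: fixed arithmetic derivation from (master seed, sample index)
  subSeeds <- (as.integer(seed) %% 100000L) * 10000L + 7919L * seq_len(n)
  samples <- vector("list", n)
  dots <- list(...)
  for (k in seq_len(n)) {
    sid <- sprintf("S%02d", k)
    args <- c(list(sampleId = sid, sex = sexes[k], era = eras[k], panel = panel,
                   seed = subSeeds[k]), dots)
    spec <- do.call(sampleSpec, args)
    # sample-dependent marker intensities, drawn from the sample's own stream
    if (is.null(dots$markerApex)) {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      set.seed(subSeeds[k] + 1L)
      jit <- stats::rlnorm(length(spec@markerApex), 0, 0.4)
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      spec@markerApex <- spec@markerApex * jit
    }
    samples[[k]] <- c(simulateRun(spec, panel = panel), list(spec = spec))
  }
  manifest <- data.frame(
    sample_id = vapply(samples, function(s) s$spec@sampleId, character(1)),
    sex = sexes, era = eras, seed = subSeeds, stringsAsFactors = FALSE)
  list(samples = samples, manifest = manifest)
}
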