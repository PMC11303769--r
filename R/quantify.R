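#' Quantification parameters
#'
#' One place for every threshold the pipeline uses. The ppm tolerances are
#' the standard targeted-search settings for this instrument class (MS1
#' 10 ppm, MS2 20 ppm); the remaining defaults are this package's documented
#' choices: 4 isotopologue peaks, minimum envelope cosine 0.90, detection
#' floor 10x the local baseline estimate, at least 4 matched b/y ions when
#' MS2 is present, and a +/- 30 s apex search window when an expected RT is
#' given.
#'
#' @param tolPpmMs1 MS1 XIC extraction tolerance, ppm.
#' @param tolPpmMs2 MS2 fragment matching tolerance, ppm.
#' @param nPeaks isotopologue peaks per envelope.
#' @param minEnvelopeScore minimum observed/theoretical envelope cosine.
#' @param minIons minimum distinct matched b/y ions for MS2 validation.
#' @param floorFactor detection floor multiplier over the baseline estimate.
#' @param rtWindow apex search half-window (s) around an expected RT.
#' @param boundsFrac peak bounds extend from the apex until the trace falls
#'   below this fraction of the apex intensity.
#' @return named list of parameters.
#' @export
quantParams <- function(tolPpmMs1 = 10, tolPpmMs2 = 20, nPeaks = 4L,
                        minEnvelopeScore = 0.90, minIons = 4L,
                        floorFactor = 10, rtWindow = 30, boundsFrac = 0.01) {
  list(tolPpmMs1 = tolPpmMs1, tolPpmMs2 = tolPpmMs2, nPeaks = as.integer(nPeaks),
       minEnvelopeScore = minEnvelopeScore, minIons = as.integer(minIons),
       floorFactor = floorFactor, rtWindow = rtWindow, boundsFrac = boundsFrac)
}

# Flatten the MS1 peaks of a run once; reused across XIC targets.
.flattenMs1 <- function(run) {
  sp <- spectraOf(run, msLevel = 1L)
  if (!length(sp)) stop("run contains no MS1 scans")
  rts <- vapply(sp, function(s) s@rt, numeric(1))
  ns <- vapply(sp, function(s) length(s@mz), integer(1))
  mz <- unlist(lapply(sp, function(s) s@mz), use.names = FALSE)
  int <- unlist(lapply(sp, function(s) s@intensity), use.names = FALSE)
  scan <- rep(seq_along(sp), times = ns)
  o <- order(mz)
  list(mz = mz[o], intensity = int[o], scan = scan[o], rt = rts,
       nScan = length(sp))
}

#' Extract ion chromatograms
#'
#' For each target m/z, sums per MS1 scan the intensities of all peaks with
#' relative mass error within \code{tolPpm}; scans with no matching peak
#' contribute zero.
#'
#' @param run an [MSRun-class] with at least one MS1 scan.
#' @param targetMz numeric vector of target m/z values.
#' @param tolPpm extraction tolerance in ppm.
#' @return list (one element per target) of data.frames with columns
#'   \code{rt} and \code{intensity}.
#' @export
extractXIC <- function(run, targetMz, tolPpm = 10) {
  flat <- .flattenMs1(run)
  .extractXICFlat(flat, targetMz, tolPpm)
}

.extractXICFlat <- function(flat, targetMz, tolPpm) {
  lapply(targetMz, function(tm) {
    lo <- tm * (1 - tolPpm * 1e-6)
    hi <- tm * (1 + tolPpm * 1e-6)
    i1 <- findInterval(lo, flat$mz) + 1L
    i2 <- findInterval(hi, flat$mz)
    y <- numeric(flat$nScan)
    if (i2 >= i1) {
      idx <- i1:i2
      agg <- tapply(flat$intensity[idx], flat$scan[idx], sum)
      y[as.integer(names(agg))] <- as.numeric(agg)
    }
    data.frame(rt = flat$rt, intensity = y)
  })
}

#' Detect and integrate a chromatographic peak
#'
#' The apex is the global maximum of the first (monoisotopic) trace,
#' restricted to \code{expectedRt} +/- \code{rtWindow} when an expected RT
#' is given; ties at equal apex intensity go to the earliest RT. Peak bounds
#' extend from the apex in both directions until the trace falls below
#' \code{boundsFrac} of the apex (or the trace ends). Each isotopologue
#' trace is then integrated over the bounds by the trapezoidal rule.
#'
#' @param chromatograms list of chromatogram data.frames (first = A0), as
#'   returned by [extractXIC()] on the envelope m/z values.
#' @param expectedRt optional expected apex RT (s).
#' @param params see [quantParams()].
#' @return list with \code{apexRt} (NA when the trace is all zero),
#'   \code{rtStart}, \code{rtEnd}, \code{areas} (per isotopologue,
#'   intensity*s), \code{area} (their sum) and \code{baselineEstimate}
#'   (median scan-wise summed intensity outside the bounds).
#' @export
detectAndIntegrate <- function(chromatograms, expectedRt = NULL,
                               params = quantParams()) {
  a0 <- chromatograms[[1]]
  rt <- a0$rt
  y <- a0$intensity
  searchable <- rep(TRUE, length(rt))
  if (!is.null(expectedRt) && !is.na(expectedRt))
    searchable <- abs(rt - expectedRt) <= params$rtWindow
  if (!any(searchable) || all(y[searchable] <= 0))
    return(list(apexRt = NA_real_, rtStart = NA_real_, rtEnd = NA_real_,
                areas = rep(0, length(chromatograms)), area = 0,
                baselineEstimate = 0))
  ycand <- ifelse(searchable, y, -Inf)
  apexIdx <- which(ycand == max(ycand))[1]  # earliest RT on ties
  apexInt <- y[apexIdx]
  thr <- apexInt * params$boundsFrac
  lo <- apexIdx
  while (lo > 1L && y[lo - 1L] >= thr) lo <- lo - 1L
  hi <- apexIdx
  while (hi < length(y) && y[hi + 1L] >= thr) hi <- hi + 1L
  idx <- lo:hi
  areas <- vapply(chromatograms, function(ch) {
    if (length(idx) < 2L) return(0)
    sum(diff(ch$rt[idx]) * (utils::head(ch$intensity[idx], -1) +
                            utils::tail(ch$intensity[idx], -1)) / 2)
  }, numeric(1))
  total <- Reduce(`+`, lapply(chromatograms, `[[`, "intensity"))
  outside <- total[-idx]
  list(apexRt = rt[apexIdx], rtStart = rt[lo], rtEnd = rt[hi],
       areas = areas, area = sum(areas),
       baselineEstimate = if (length(outside)) stats::median(outside) else 0)
}

#' Isotope-envelope similarity score
#'
#' Cosine similarity (normalized dot product) between the observed and
#' theoretical isotopologue intensity vectors: 1 for proportional vectors,
#' 0 for orthogonal ones, and 0 when the observed vector is all zero.
#'
#' @param observed non-negative observed per-isotopologue areas.
#' @param theoretical theoretical abundances, same length.
#' @return score in [0, 1].
#' @examples
#' th <- isotopeEnvelope("LRYPYP", z = 2)$abundance
#' envelopeScore(3 * th, th)          # 1: scale invariant
#' envelopeScore(c(1, 0, 0, 0), th)   # < 0.9: monoisotopic peak alone
#' @export
envelopeScore <- function(observed, theoretical) {
  if (length(observed) != length(theoretical))
    stop("observed and theoretical vectors must have the same length")
  if (any(observed < 0) || any(theoretical < 0))
    stop("envelope vectors must be non-negative")
  no <- sqrt(sum(observed^2)); nt <- sqrt(sum(theoretical^2))
  if (no == 0 || nt == 0) return(0)
  min(1, sum(observed * theoretical) / (no * nt))
}

#' MS2 fragment validation of a marker
#'
#' Over all MS2 spectra whose precursor m/z lies within the isolation
#' half-width of the marker m/z, counts the distinct theoretical b/y ions
#' (charge 1 and 2) matched within \code{tolPpmMs2}. The marker passes if
#' the best spectrum matches at least \code{minIons} ions. A run without any
#' MS2 spectra is MS1-only: the result is (0, NA) and quantification
#' proceeds with MS2 not evaluated.
#'
#' @param run an [MSRun-class].
#' @param marker a [MarkerPeptide-class].
#' @param params see [quantParams()].
#' @return list with \code{matched} (max distinct matched ions over
#'   spectra), \code{pass} (logical, NA when not evaluated) and
#'   \code{nSpectra} (MS2 spectra inspected).
#' @export
ms2Validate <- function(run, marker, params = quantParams()) {
  ms2 <- spectraOf(run, msLevel = 2L)
  if (!length(ms2)) return(list(matched = 0L, pass = NA, nSpectra = 0L))
  markerMz <- ionMz(monoisotopicMass(marker@peptide), marker@charge)
  frags <- fragmentIons(marker@peptide, maxCharge = 2L)
  best <- 0L
  nInspected <- 0L
  for (s in ms2) {
    hw <- if (is.na(s@isolationHalfWidth)) 0.85 else s@isolationHalfWidth
    if (is.na(s@precursorMz) || abs(s@precursorMz - markerMz) > hw) next
    nInspected <- nInspected + 1L
    if (!length(s@mz)) next
    matched <- vapply(frags$mz, function(fm)
      any(abs(s@mz - fm) / fm <= params$tolPpmMs2 * 1e-6), logical(1))
    best <- max(best, length(unique(frags$label[matched])))
  }
  if (nInspected == 0L) return(list(matched = 0L, pass = FALSE, nSpectra = 0L))
  list(matched = best, pass = best >= params$minIons, nSpectra = nInspected)
}

# Quantify one targeted peptide form (marker or background form) from a
# pre-flattened run: XIC envelope extraction, peak integration, envelope
# score and detection-floor logic. Returns the fields shared by marker and
# form quantification.
.quantifyForm <- function(flat, peptide, charge, params, expectedRt = NULL) {
  env <- isotopeEnvelope(peptide, z = charge, nPeaks = params$nPeaks)
  xics <- .extractXICFlat(flat, env$mz, params$tolPpmMs1)
  pk <- detectAndIntegrate(xics, expectedRt = expectedRt, params = params)
  score <- envelopeScore(pk$areas, env$abundance)
  duration <- if (is.na(pk$rtStart)) 0 else pk$rtEnd - pk$rtStart
  floorLevel <- params$floorFactor * pk$baselineEstimate * duration
  list(area = pk$area, areas = pk$areas, apexRt = pk$apexRt,
       rtStart = pk$rtStart, rtEnd = pk$rtEnd, envelopeScore = score,
       floorLevel = floorLevel, theoretical = env$abundance)
}

#' Quantify a marker peptide in a run
#'
#' Composite targeted quantification: extracts the isotopologue XICs of the
#' marker at the MS1 tolerance, detects and integrates the elution peak,
#' scores the observed envelope against theory, and validates fragments in
#' MS2 (when present). The marker is \emph{detected} iff the area exceeds
#' the detection floor, the envelope score reaches
#' \code{params$minEnvelopeScore}, and MS2 validation passes or was not
#' evaluated; \code{reasons} records every failed criterion.
#'
#' @param run an [MSRun-class].
#' @param marker a [MarkerPeptide-class].
#' @param params see [quantParams()].
#' @param expectedRt optional expected apex RT (s).
#' @return one-row data.frame: \code{marker}, \code{source}, \code{area},
#'   \code{apexRt}, \code{rtStart}, \code{rtEnd}, \code{envelopeScore},
#'   \code{ms2Matched}, \code{ms2Pass}, \code{detected}, \code{reasons}.
#' @export
quantifyMarker <- function(run, marker, params = quantParams(),
                           expectedRt = NULL) {
  flat <- .flattenMs1(run)
  .quantifyMarkerFlat(flat, run, marker, params, expectedRt)
}

.quantifyMarkerFlat <- function(flat, run, marker, params, expectedRt = NULL) {
  q <- .quantifyForm(flat, marker@peptide, marker@charge, params, expectedRt)
  v <- ms2Validate(run, marker, params)
  reasons <- character(0)
  if (!(q$area > 0)) reasons <- c(reasons, "area below floor")
  else if (!(q$area > q$floorLevel)) reasons <- c(reasons, "area below floor")
  if (q$envelopeScore < params$minEnvelopeScore)
    reasons <- c(reasons, "envelope_score")
  if (isFALSE(v$pass)) reasons <- c(reasons, "ms2_validation")
  data.frame(marker = marker@id, source = marker@source,
             area = q$area, apexRt = q$apexRt,
             rtStart = q$rtStart, rtEnd = q$rtEnd,
             envelopeScore = q$envelopeScore,
             ms2Matched = v$matched, ms2Pass = v$pass,
             detected = length(reasons) == 0L,
             reasons = paste(reasons, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Quantify a full panel in a run
#'
#' @param run an [MSRun-class].
#' @param panel a [MarkerPanel-class].
#' @param params see [quantParams()].
#' @param expectedRt optional named vector of expected apex RTs by marker id.
#' @return data.frame with one row per marker (see [quantifyMarker()]).
#' @export
quantifyPanel <- function(run, panel, params = quantParams(),
                          expectedRt = NULL) {
  flat <- .flattenMs1(run)
  rows <- lapply(panel@markers, function(m) {
    ert <- if (!is.null(expectedRt) && m@id %in% names(expectedRt))
      expectedRt[[m@id]] else NULL
    .quantifyMarkerFlat(flat, run, m, params, ert)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
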