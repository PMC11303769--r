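#' Construct a spectrum / run
#'
#' Low-level constructors for the run model. Peaks with identical m/z are
#' merged (intensities summed) and sorted ascending so the m/z array is
#' strictly ascending.
#'
#' @param scanId scan identifier string.
#' @param msLevel 1 or 2.
#' @param rt retention time in seconds.
#' @param mz,intensity equal-length peak arrays.
#' @param precursorMz,precursorCharge,isolationHalfWidth precursor
#'   information; required when \code{msLevel == 2}.
#' @return a [Spectrum-class].
#' @export
spectrum <- function(scanId, msLevel, rt, mz, intensity,
                     precursorMz = NA_real_, precursorCharge = NA_integer_,
                     isolationHalfWidth = NA_real_) {
  if (length(mz)) {
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]
    if (anyDuplicated(mz)) {
      intensity <- as.numeric(tapply(intensity, match(mz, unique(mz)), sum))
      mz <- unique(mz)
    }
  }
  new("Spectrum", scanId = as.character(scanId), msLevel = as.integer(msLevel),
      rt = as.numeric(rt), mz = as.numeric(mz), intensity = as.numeric(intensity),
      precursorMz = as.numeric(precursorMz),
      precursorCharge = as.integer(precursorCharge),
      isolationHalfWidth = as.numeric(isolationHalfWidth))
}

#' @rdname spectrum
#' @param sampleId sample identifier.
#' @param spectra list of [Spectrum-class], ordered by retention time.
#' @param metadata named list of free-form metadata.
#' @return \code{msRun}: an [MSRun-class].
#' @export
msRun <- function(sampleId, spectra = list(), metadata = list()) {
  new("MSRun", sampleId = as.character(sampleId), spectra = spectra,
      metadata = metadata)
}

#' Run accessors
#'
#' @param run an [MSRun-class].
#' @param msLevel optional filter (1 or 2).
#' @return \code{spectraOf}: list of [Spectrum-class]; \code{nScans}: integer;
#'   \code{sampleId}: character; \code{rtime}: numeric vector of retention
#'   times.
#' @export
spectraOf <- function(run, msLevel = NULL) {
  sp <- run@spectra
  if (!is.null(msLevel))
    sp <- sp[vapply(sp, function(s) s@msLevel, integer(1)) == msLevel]
  sp
}

#' @rdname spectraOf
#' @export
nScans <- function(run) length(run@spectra)

#' @rdname spectraOf
#' @export
sampleId <- function(run) run@sampleId

#' @rdname spectraOf
#' @export
rtime <- function(run) vapply(run@spectra, function(s) s@rt, numeric(1))

#' Read an LC-MS run
#'
#' Reads a centroided run from mzML (via mzR) or from the package's internal
#' JSON-lines format (one JSON object per spectrum; see the README for the
#' schema). Retention times are normalized to seconds. Profile-mode mzML
#' spectra are rejected.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"mzml"} or
#'   \code{"internal"}.
#' @param sampleId sample identifier; defaults to the file base name.
#' @return an [MSRun-class].
#' @examples
#' f <- tempfile(fileext = ".jsonl")
#' writeRun(msRun("empty"), f)
#' nScans(readRun(f))
#' @export
readRun <- function(path, format = c("auto", "mzml", "internal"),
                    sampleId = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml" else "internal"
  if (is.null(sampleId))
    sampleId <- sub("\\.[^.]*$", "", basename(path))
  if (format == "mzml") .readMzml(path, sampleId) else .readInternal(path, sampleId)
}

#' Write an LC-MS run
#'
#' Inverse of [readRun()]: \code{readRun(writeRun(run, path))} reproduces the
#' run (scan ids, retention times, peak arrays) within float tolerance. The
#' mzML dialect written is a minimal valid subset: centroided spectra, 64-bit
#' m/z, 32-bit intensity, no chromatogram elements.
#'
#' @param run an [MSRun-class].
#' @param path output path.
#' @param format \code{"auto"}, \code{"mzml"} or \code{"internal"}.
#' @return the path, invisibly.
#' @export
writeRun <- function(run, path, format = c("auto", "mzml", "internal")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml" else "internal"
  if (format == "mzml") .writeMzml(run, path) else .writeInternal(run, path)
  invisible(path)
}

.readInternal <- function(path, sampleId) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  spectra <- lapply(lines, function(l) {
    r <- jsonlite::fromJSON(l)
    prec <- r$precursor
    spectrum(r$scan_id, r$ms_level, r$rt,
             mz = as.numeric(unlist(r$mz)), intensity = as.numeric(unlist(r$intensity)),
             precursorMz = if (is.null(prec)) NA_real_ else prec$mz,
             precursorCharge = if (is.null(prec) || is.null(prec$charge)) NA_integer_
                               else as.integer(prec$charge),
             isolationHalfWidth = if (is.null(prec)) NA_real_ else prec$isolation_half_width)
  })
  msRun(sampleId, spectra)
}

.writeInternal <- function(run, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (s in run@spectra) {
    rec <- list(scan_id = s@scanId, ms_level = s@msLevel, rt = s@rt,
                mz = s@mz, intensity = s@intensity)
    if (s@msLevel == 2L)
      rec$precursor <- list(mz = s@precursorMz, charge = s@precursorCharge,
                            isolation_half_width = s@isolationHalfWidth)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                na = "null"), con)
  }
}

.readMzml <- function(path, sampleId) {
  f <- mzR::openMSfile(path)
  on.exit(try(mzR::close(f), silent = TRUE))
  hdr <- mzR::header(f)
  if (!nrow(hdr)) return(msRun(sampleId))
  if (any(!is.na(hdr$centroided) & !hdr$centroided))
    stop("profile-mode spectra found; centroided input is required")
  pks <- mzR::peaks(f)
  if (is.matrix(pks)) pks <- list(pks)
  spectra <- lapply(seq_len(nrow(hdr)), function(i) {
    h <- hdr[i, ]
    spectrum(scanId = as.character(h$acquisitionNum), msLevel = h$msLevel,
             rt = h$retentionTime,  # mzR reports seconds
             mz = pks[[i]][, 1], intensity = pks[[i]][, 2],
             precursorMz = if (h$msLevel >= 2L) h$precursorMZ else NA_real_,
             precursorCharge = if (h$msLevel >= 2L) as.integer(h$precursorCharge)
                               else NA_integer_,
             isolationHalfWidth = if (h$msLevel >= 2L) h$isolationWindowUpperOffset
                                  else NA_real_)
  })
  msRun(sampleId, spectra)
}

.writeMzml <- function(run, path) {
  n <- length(run@spectra)
  if (!n) stop("cannot write an empty run as mzML; use the internal format")
  ms <- vapply(run@spectra, function(s) s@msLevel, integer(1))
  rts <- rtime(run)
  npk <- vapply(run@spectra, function(s) length(s@mz), integer(1))
  tic <- vapply(run@spectra, function(s) sum(s@intensity), numeric(1))
  bpi <- vapply(run@spectra, function(s) if (length(s@intensity)) max(s@intensity) else 0, numeric(1))
  bpm <- vapply(run@spectra, function(s)
    if (length(s@mz)) s@mz[which.max(s@intensity)] else 0, numeric(1))
  pmz <- vapply(run@spectra, function(s) s@precursorMz, numeric(1))
  pch <- vapply(run@spectra, function(s) s@precursorCharge, integer(1))
  ihw <- vapply(run@spectra, function(s) s@isolationHalfWidth, numeric(1))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = ms,
    polarity = rep(1L, n), peaksCount = npk, totIonCurrent = tic,
    retentionTime = rts, basePeakMZ = bpm, basePeakIntensity = bpi,
    collisionEnergy = ifelse(ms == 2L, 27, NA_real_),
    ionisationEnergy = rep(0, n),
    lowMZ = vapply(run@spectra, function(s) if (length(s@mz)) min(s@mz) else 0, numeric(1)),
    highMZ = vapply(run@spectra, function(s) if (length(s@mz)) max(s@mz) else 0, numeric(1)),
    precursorScanNum = rep(NA_integer_, n), precursorMZ = pmz,
    precursorCharge = pch, precursorIntensity = rep(NA_real_, n),
    mergedScan = rep(NA_integer_, n), mergedResultScanNum = rep(NA_integer_, n),
    mergedResultStartScanNum = rep(NA_integer_, n),
    mergedResultEndScanNum = rep(NA_integer_, n),
    injectionTime = rep(0, n), filterString = rep(NA_character_, n),
    spectrumId = paste0("scan=", seq_len(n)), centroided = rep(TRUE, n),
    ionMobilityDriftTime = rep(NA_real_, n),
    isolationWindowTargetMZ = pmz, isolationWindowLowerOffset = ihw,
    isolationWindowUpperOffset = ihw,
    scanWindowLowerLimit = rep(NA_real_, n), scanWindowUpperLimit = rep(NA_real_, n),
    stringsAsFactors = FALSE)
  pks <- lapply(run@spectra, function(s) cbind(mz = s@mz, intensity = s@intensity))
  mzR::writeMSData(object = pks, file = path, header = hdr)
}

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum %s: MS%d, rt %.2f s, %d peaks\n",
              object@scanId, object@msLevel, object@rt, length(object@mz)))
})

setMethod("show", "MSRun", function(object) {
  ms <- vapply(object@spectra, function(s) s@msLevel, integer(1))
  cat(sprintf("MSRun '%s': %d spectra (%d MS1, %d MS2)\n", object@sampleId,
              length(object@spectra), sum(ms == 1L), sum(ms == 2L)))
  if (length(object@spectra))
    cat(sprintf("  rt range: %.1f - %.1f s\n", min(rtime(object)), max(rtime(object))))
})

setMethod("show", "MarkerPeptide", function(object) {
  cat(sprintf("MarkerPeptide %s (%s): %s, z=%d, m/z %.4f\n", object@id,
              object@source, object@peptide@sequence, object@charge,
              object@referenceMz))
})

setMethod("show", "MarkerPanel", function(object) {
  cat(sprintf("MarkerPanel with %d markers:\n", length(object@markers)))
  for (m in object@markers) show(m)
})

setMethod("show", "ModifiedPeptide", function(object) {
  mods <- if (nrow(object@modifications))
    paste0(" [", paste(object@modifications$position,
                       object@modifications$name, sep = ":", collapse = "; "), "]")
  else ""
  cat(sprintf("ModifiedPeptide %s%s, M = %.4f Da\n", object@sequence, mods,
              monoisotopicMass(object)))
})
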