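#' Call sex from a quantified marker panel
#'
#' Decision rule (presence/absence, no intensity ratio):
#' \itemize{
#'   \item no AmelX marker detected: \code{indeterminate} -- the
#'     enamel-recovery control failed, so the absence of AmelY carries no
#'     information;
#'   \item at least one AmelY marker detected: \code{male}, with
#'     \code{high} confidence iff both AmelY markers are detected;
#'   \item otherwise: \code{female} (negative-evidence call gated on AmelX
#'     positivity), with \code{high} confidence iff both AmelX markers are
#'     detected.
#' }
#'
#' @param quant per-marker quantification table from [quantifyPanel()]; must
#'   cover at least one AmelX and one AmelY marker.
#' @param sampleId sample identifier recorded in the call.
#' @param deamidation optional occupancy result from [occupancyFromRun()].
#' @return a [SexCall-class].
#' @export
callSex <- function(quant, sampleId = "sample", deamidation = list()) {
  if (!all(c("source", "detected") %in% names(quant)))
    stop("quant must be a quantifyPanel() table")
  if (!any(quant$source == "AmelX") || !any(quant$source == "AmelY"))
    stop("panel must contain both AmelX and AmelY markers")
  xDet <- quant$detected[quant$source == "AmelX"]
  yDet <- quant$detected[quant$source == "AmelY"]
  if (!any(xDet)) {
    call <- "indeterminate"; conf <- "standard"
  } else if (any(yDet)) {
    call <- "male"; conf <- if (all(yDet)) "high" else "standard"
  } else {
    call <- "female"; conf <- if (all(xDet)) "high" else "standard"
  }
  new("SexCall", sampleId = sampleId, call = call, confidence = conf,
      evidence = quant,
      deamidation = if (length(deamidation)) deamidation else list())
}

#' Run the full sex-determination pipeline over a cohort
#'
#' For each run in the manifest: quantify all panel markers, call sex, and
#' (optionally) estimate bulk deamidation occupancy. When group labels are
#' supplied with both \code{"modern"} and \code{"archaeological"} groups
#' present, the modern-vs-archaeological occupancy fold comparison is added.
#' An unreadable run is flagged failed and the pipeline continues; if every
#' run fails, the pipeline errors.
#'
#' @param manifest data.frame with columns \code{sample_id} and either
#'   \code{path} (files read with [readRun()]) or \code{run} (a list column
#'   of [MSRun-class] objects); optional columns \code{group}
#'   (modern/archaeological) and \code{known_sex} for validation mode. A
#'   path to a TSV manifest file is also accepted.
#' @param panel a [MarkerPanel-class].
#' @param params see [quantParams()]; echoed into the report.
#' @param background background peptide table for deamidation, or NULL to
#'   skip the deamidation stage.
#' @return a [CohortReport-class].
#' @export
runPipeline <- function(manifest, panel = defaultPanel(),
                        params = quantParams(), background = NULL) {
  if (is.character(manifest) && length(manifest) == 1L)
    manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  if (!nrow(manifest)) stop("empty manifest")
  if (!"sample_id" %in% names(manifest)) stop("manifest needs a sample_id column")
  hasRuns <- "run" %in% names(manifest)
  if (!hasRuns && !"path" %in% names(manifest))
    stop("manifest needs a 'path' or 'run' column")
  calls <- list()
  occ <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$sample_id[i]
    res <- tryCatch({
      run <- if (hasRuns) manifest$run[[i]] else readRun(manifest$path[i])
      quant <- quantifyPanel(run, panel, params)
      sc <- callSex(quant, sampleId = sid)
      oc <- if (!is.null(background))
        occupancyFromRun(run, background, params) else NULL
      list(sc = sc, oc = oc, failed = FALSE)
    }, error = function(e) list(sc = NULL, oc = NULL, failed = TRUE,
                                msg = conditionMessage(e)))
    if (res$failed) {
      calls[[i]] <- data.frame(sample_id = sid, call = "failed",
                               confidence = NA_character_,
                               nAmelX = NA_integer_, nAmelY = NA_integer_,
                               stringsAsFactors = FALSE)
    } else {
      ev <- res$sc@evidence
      calls[[i]] <- data.frame(
        sample_id = sid, call = res$sc@call, confidence = res$sc@confidence,
        nAmelX = sum(ev$detected[ev$source == "AmelX"]),
        nAmelY = sum(ev$detected[ev$source == "AmelY"]),
        stringsAsFactors = FALSE)
      if (!is.null(res$oc))
        occ[[length(occ) + 1L]] <- data.frame(
          sample_id = sid,
          group = if ("group" %in% names(manifest)) manifest$group[i] else NA,
          occupancyN = res$oc$occupancyN, occupancyQ = res$oc$occupancyQ,
          stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, calls)
  if (all(calls$call == "failed")) stop("all runs failed to process")
  levelsAll <- c("male", "female", "indeterminate", "failed")
  counts <- stats::setNames(
    vapply(levelsAll, function(l) sum(calls$call == l), integer(1)), levelsAll)
  deam <- list()
  if (length(occ)) {
    occTab <- do.call(rbind, occ)
    deam$occupancies <- occTab
    if ("group" %in% names(occTab) &&
        all(c("modern", "archaeological") %in% occTab$group)) {
      deam$comparison <- compareGroups(
        occTab[occTab$group == "modern", , drop = FALSE],
        occTab[occTab$group == "archaeological", , drop = FALSE])
    }
  }
  new("CohortReport", calls = calls, counts = counts, deamidation = deam,
      params = params)
}

#' CohortReport accessors
#'
#' @param report a [CohortReport-class].
#' @return \code{sexCalls}: the per-sample call table; \code{callCounts}:
#'   named counts per call.
#' @export
sexCalls <- function(report) report@calls

#' @rdname sexCalls
#' @export
callCounts <- function(report) report@counts

setMethod("show", "SexCall", function(object) {
  cat(sprintf("SexCall %s: %s (%s confidence)\n", object@sampleId,
              object@call, object@confidence))
  det <- object@evidence
  cat(sprintf("  detected: %s\n",
              paste(det$marker[det$detected], collapse = ", ")))
})

setMethod("show", "CohortReport", function(object) {
  cat(sprintf("CohortReport: %d samples\n", nrow(object@calls)))
  cat("  calls:", paste(names(object@counts), object@counts, sep = "=",
                        collapse = ", "), "\n")
  cat(sprintf("  thresholds: MS1 %g ppm, MS2 %g ppm, envelope >= %.2f, floor %gx baseline, >= %d ions\n",
              object@params$tolPpmMs1, object@params$tolPpmMs2,
              object@params$minEnvelopeScore, object@params$floorFactor,
              object@params$minIons))
  if (length(object@deamidation) && !is.null(object@deamidation$comparison)) {
    cmp <- object@deamidation$comparison
    cat(sprintf("  deamidation fold (archaeological/modern): N %.2f, Q %.2f\n",
                cmp$fold[cmp$class == "N"], cmp$fold[cmp$class == "Q"]))
  }
})
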