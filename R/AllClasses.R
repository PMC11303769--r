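#' @import methods
NULL

#' Elemental composition of a molecule
#'
#' A named count vector over the elements C, H, N, O, S and P. Behaves like a
#' named integer vector; closed under addition via [addComposition()].
#'
#' @slot .Data named integer vector of non-negative atom counts.
#' @export
setClass("ElementalComposition", contains = "integer", validity = function(object) {
  if (is.null(names(object)) || !all(names(object) %in% .ELEMENTS))
    return("composition names must be among C, H, N, O, S, P")
  if (anyDuplicated(names(object)))
    return("duplicated element names")
  if (any(object < 0))
    return("atom counts must be non-negative")
  TRUE
})

#' A peptide with positioned modifications
#'
#' The unit of mass, isotopic-envelope and fragment-ion computation. The
#' sequence uses the 20 standard one-letter codes; each modification is a
#' (position, name) pair where the position is a 1-based residue index or
#' \code{"N-term"}, and the name refers to an entry of the modification
#' registry (see [defaultModifications()]).
#'
#' @slot sequence single string over the 20 standard amino-acid letters.
#' @slot modifications data.frame with character columns \code{position}
#'   and \code{name}.
#' @export
setClass("ModifiedPeptide",
  slots = c(sequence = "character", modifications = "data.frame"),
  validity = function(object) {
    s <- object@sequence
    if (length(s) != 1L || is.na(s) || nchar(s) < 1L)
      return("sequence must be a single non-empty string")
    letters1 <- strsplit(s, "")[[1]]
    bad <- setdiff(letters1, names(.RESIDUE_MASS))
    if (length(bad))
      return(paste0("unknown residue letter(s): ", paste(unique(bad), collapse = ", ")))
    m <- object@modifications
    if (!all(c("position", "name") %in% names(m)))
      return("modifications must have columns 'position' and 'name'")
    if (nrow(m)) {
      pos <- m$position
      num <- suppressWarnings(as.integer(pos))
      isNterm <- pos == "N-term"
      if (any(!isNterm & (is.na(num) | num < 1L | num > nchar(s))))
        return("modification positions must be 'N-term' or within [1, length]")
      if (anyDuplicated(paste(m$position, m$name)))
        return("at most one modification per position per name")
    }
    TRUE
  })

#' A sex-diagnostic marker peptide
#'
#' One diagnostic amelogenin peptide: its modified sequence, source protein
#' (AmelX or AmelY), charge state, the reference m/z it is quantified at and
#' the single-amino-acid-variant (SAAV) positions it carries in protein
#' coordinates. On construction the m/z computed from sequence and
#' modifications must agree with \code{referenceMz} to within 0.002.
#'
#' @slot id marker identifier (e.g. "Y1").
#' @slot peptide a [ModifiedPeptide-class].
#' @slot source \code{"AmelX"} or \code{"AmelY"}.
#' @slot charge positive integer charge state.
#' @slot referenceMz the reference m/z (as printed/curated).
#' @slot saavPositions integer SAAV positions in the source protein
#'   (annotation only; not used in computation).
#' @export
setClass("MarkerPeptide",
  slots = c(id = "character", peptide = "ModifiedPeptide", source = "character",
            charge = "integer", referenceMz = "numeric",
            saavPositions = "integer"),
  validity = function(object) {
    if (!object@source %in% c("AmelX", "AmelY"))
      return("source must be 'AmelX' or 'AmelY'")
    if (object@charge < 1L) return("charge must be >= 1")
    calc <- ionMz(monoisotopicMass(object@peptide), object@charge)
    if (abs(calc - object@referenceMz) > 0.002)
      return(sprintf("marker %s: computed m/z %.4f differs from reference %.4f by more than 0.002",
                     object@id, calc, object@referenceMz))
    TRUE
  })

#' A panel of marker peptides
#'
#' The set of diagnostic peptides quantified per sample. A valid panel has
#' unique marker ids and at least one AmelX and one AmelY marker (AmelX
#' positivity is the enamel-recovery control; AmelY presence is the male
#' signal).
#'
#' @slot markers list of [MarkerPeptide-class] objects.
#' @export
setClass("MarkerPanel", slots = c(markers = "list"), validity = function(object) {
  if (!length(object@markers)) return("panel is empty")
  if (!all(vapply(object@markers, is, logical(1), "MarkerPeptide")))
    return("all panel entries must be MarkerPeptide objects")
  ids <- vapply(object@markers, function(m) m@id, character(1))
  if (anyDuplicated(ids)) return("marker ids must be unique")
  src <- vapply(object@markers, function(m) m@source, character(1))
  if (!any(src == "AmelX")) return("panel must contain at least one AmelX marker")
  if (!any(src == "AmelY")) return("panel must contain at least one AmelY marker")
  TRUE
})

#' A single centroided mass spectrum
#'
#' @slot scanId scan identifier.
#' @slot msLevel 1 (survey) or 2 (fragment).
#' @slot rt retention time, seconds.
#' @slot mz strictly ascending m/z values.
#' @slot intensity non-negative intensities, same length as \code{mz}.
#' @slot precursorMz,precursorCharge,isolationHalfWidth precursor information,
#'   required for MS2 spectra (\code{NA} on MS1).
#' @export
setClass("Spectrum",
  slots = c(scanId = "character", msLevel = "integer", rt = "numeric",
            mz = "numeric", intensity = "numeric",
            precursorMz = "numeric", precursorCharge = "integer",
            isolationHalfWidth = "numeric"),
  validity = function(object) {
    if (!object@msLevel %in% c(1L, 2L)) return("msLevel must be 1 or 2")
    if (is.na(object@rt) || object@rt < 0) return("rt must be >= 0 seconds")
    if (length(object@mz) != length(object@intensity))
      return("mz and intensity arrays must have equal length")
    if (length(object@mz) > 1L && any(diff(object@mz) <= 0))
      return("mz array must be strictly ascending")
    if (any(object@intensity < 0)) return("intensities must be >= 0")
    if (object@msLevel == 2L && is.na(object@precursorMz))
      return("MS2 spectrum requires precursor m/z")
    TRUE
  })

#' An LC-MS run
#'
#' An ordered collection of centroided MS1/MS2 spectra with retention times,
#' plus free-form metadata.
#'
#' @slot sampleId sample identifier.
#' @slot spectra list of [Spectrum-class], ordered by retention time.
#' @slot metadata named list.
#' @export
setClass("MSRun",
  slots = c(sampleId = "character", spectra = "list", metadata = "list"),
  validity = function(object) {
    if (length(object@spectra)) {
      if (!all(vapply(object@spectra, is, logical(1), "Spectrum")))
        return("all elements of spectra must be Spectrum objects")
      rts <- vapply(object@spectra, function(s) s@rt, numeric(1))
      if (any(diff(rts) < 0)) return("retention times must be non-decreasing")
    }
    TRUE
  })

#' Specification of a synthetic sample
#'
#' Ground-truth parameters for one simulated DDA run: which sex and era the
#' sample emulates, per-marker apex intensities and elution parameters,
#' noise levels, deamidation occupancies of the AmelX-like background
#' peptides, decoy density and the RNG seed.
#'
#' @slot sampleId,sex,era identifiers; sex is \code{"male"}/\code{"female"},
#'   era \code{"modern"}/\code{"archaeological"}.
#' @slot markerApex named apex intensities (ion counts) per marker id.
#' @slot markerRt named elution apex retention times (s) per marker id.
#' @slot peakWidth Gaussian elution sd (s).
#' @slot scanInterval,runLength MS1 cycle time and run length (s).
#' @slot ppmJitter Gaussian sd of the mass error (ppm).
#' @slot baseline additive background intensity at each marker m/z.
#' @slot noiseCV multiplicative intensity noise (coefficient of variation).
#' @slot pN,pQ deamidation occupancy of Asn / Gln sites in [0, 1].
#' @slot background data.frame(sequence, apex, rt) of background peptides.
#' @slot decoyDensity expected number of random decoy peaks per MS1 scan.
#' @slot seed integer RNG seed.
#' @export
setClass("SampleSpec",
  slots = c(sampleId = "character", sex = "character", era = "character",
            markerApex = "numeric", markerRt = "numeric", peakWidth = "numeric",
            scanInterval = "numeric", runLength = "numeric",
            ppmJitter = "numeric", baseline = "numeric", noiseCV = "numeric",
            pN = "numeric", pQ = "numeric", background = "data.frame",
            decoyDensity = "numeric", seed = "integer"),
  validity = function(object) {
    if (!object@sex %in% c("male", "female")) return("sex must be 'male' or 'female'")
    if (!object@era %in% c("modern", "archaeological"))
      return("era must be 'modern' or 'archaeological'")
    if (object@pN < 0 || object@pN > 1 || object@pQ < 0 || object@pQ > 1)
      return("occupancies pN, pQ must lie in [0, 1]")
    if (any(object@markerApex < 0)) return("apex intensities must be >= 0")
    if (any(object@markerRt < 0) || any(object@markerRt > object@runLength))
      return("marker RT centers must lie within the run length")
    if (object@peakWidth <= 0 || object@scanInterval <= 0 || object@runLength <= 0)
      return("peakWidth, scanInterval and runLength must be positive")
    TRUE
  })

#' A per-sample sex call
#'
#' @slot sampleId sample identifier.
#' @slot call \code{"male"}, \code{"female"} or \code{"indeterminate"}.
#' @slot confidence \code{"high"} or \code{"standard"}.
#' @slot evidence per-marker quantification table (one row per panel marker).
#' @slot deamidation optional named list with occupancy results.
#' @export
setClass("SexCall",
  slots = c(sampleId = "character", call = "character", confidence = "character",
            evidence = "data.frame", deamidation = "list"),
  validity = function(object) {
    if (!object@call %in% c("male", "female", "indeterminate"))
      return("call must be male, female or indeterminate")
    if (!object@confidence %in% c("high", "standard"))
      return("confidence must be high or standard")
    TRUE
  })

#' A cohort-level report
#'
#' @slot calls data.frame with one row per sample (sample_id, call,
#'   confidence, per-marker detection flags, failure flag).
#' @slot counts named integer vector of call counts (sums to n samples).
#' @slot deamidation per-sample occupancy table and, when group labels were
#'   supplied, the modern-vs-archaeological fold comparison.
#' @slot params the thresholds the pipeline ran with (echoed for audit).
#' @export
setClass("CohortReport",
  slots = c(calls = "data.frame", counts = "integer", deamidation = "list",
            params = "list"),
  validity = function(object) {
    if (nrow(object@calls) && sum(object@counts) != nrow(object@calls))
      return("call counts must sum to the number of samples")
    TRUE
  })
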