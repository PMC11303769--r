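#' Construct a marker peptide
#'
#' @param id marker identifier.
#' @param sequence peptide sequence, or a [ModifiedPeptide-class].
#' @param source source protein, \code{"AmelX"} or \code{"AmelY"}.
#' @param charge charge state the marker is quantified at.
#' @param referenceMz curated reference m/z; the value recomputed from the
#'   sequence and modifications must agree to within 0.002 or construction
#'   fails.
#' @param modifications as in [modifiedPeptide()] (ignored when
#'   \code{sequence} is already a ModifiedPeptide).
#' @param saavPositions integer SAAV positions in protein coordinates
#'   (annotation only).
#' @param registry modification registry.
#' @return a [MarkerPeptide-class].
#' @examples
#' markerPeptide("Y1", "LRYPYP", "AmelY", 2, 404.7212, saavPositions = c(46, 48))
#' @export
markerPeptide <- function(id, sequence, source, charge, referenceMz,
                          modifications = list(), saavPositions = integer(0),
                          registry = defaultModifications()) {
  pep <- if (is(sequence, "ModifiedPeptide")) sequence
         else modifiedPeptide(sequence, modifications, registry)
  new("MarkerPeptide", id = id, peptide = pep, source = source,
      charge = as.integer(charge), referenceMz = referenceMz,
      saavPositions = as.integer(saavPositions))
}

#' Construct a marker panel
#'
#' @param markers list of [MarkerPeptide-class] objects; must contain at
#'   least one AmelX and one AmelY marker, with unique ids.
#' @return a [MarkerPanel-class].
#' @export
markerPanel <- function(markers) new("MarkerPanel", markers = markers)

#' The default bovine amelogenin panel
#'
#' Four diagnostic native peptides quantified as doubly protonated ions:
#' two unique to AmelY (male-specific) -- LRYPYP at 404.7212 m/z and
#' LRYPYPSY at 529.7689 m/z -- and two unique to AmelX (the
#' enamel-recovery control) -- SM(ox)IRHPYP at 508.7527 m/z and IRHPYPSY at
#' 516.7667 m/z. SAAV annotations use protein coordinates (AmelX
#' Ser44/Ile46/His48; AmelY Leu46/Tyr48).
#'
#' @return a [MarkerPanel-class] of four markers.
#' @examples
#' defaultPanel()
#' @export
defaultPanel <- function() {
  markerPanel(list(
    markerPeptide("Y1", "LRYPYP",   "AmelY", 2, 404.7212, saavPositions = c(46, 48)),
    markerPeptide("Y2", "LRYPYPSY", "AmelY", 2, 529.7689, saavPositions = c(46, 48)),
    markerPeptide("X1", "SMIRHPYP", "AmelX", 2, 508.7527,
                  modifications = list(list(position = 2, name = "Oxidation")),
                  saavPositions = c(44, 46, 48)),
    markerPeptide("X2", "IRHPYPSY", "AmelX", 2, 516.7667, saavPositions = c(46, 48))
  ))
}

#' Load / write a marker panel file
#'
#' Panel files are tab-separated key-value text with columns \code{id},
#' \code{sequence}, \code{mods} (semicolon-separated \code{pos:name} pairs,
#' empty for none), \code{charge}, \code{reference_mz} and \code{source}.
#' All panel invariants (m/z agreement to 0.002, both sources present,
#' unique ids) are checked at load; a mismatching reference m/z is a hard
#' error naming the marker.
#'
#' @param path panel file path.
#' @param panel a [MarkerPanel-class].
#' @param registry modification registry.
#' @return \code{loadPanel}: a [MarkerPanel-class]; \code{writePanel}: the
#'   path, invisibly.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writePanel(defaultPanel(), f)
#' loadPanel(f)
#' @export
loadPanel <- function(path, registry = defaultModifications()) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
  req <- c("id", "sequence", "mods", "charge", "reference_mz", "source")
  if (!all(req %in% names(tab)))
    stop("panel file must have columns: ", paste(req, collapse = ", "))
  markers <- lapply(seq_len(nrow(tab)), function(i) {
    mods <- list()
    if (nzchar(trimws(tab$mods[i]))) {
      mods <- lapply(strsplit(tab$mods[i], ";")[[1]], function(s) {
        kv <- strsplit(trimws(s), ":")[[1]]
        if (length(kv) != 2L) stop("cannot parse modification spec: ", s)
        list(position = kv[1], name = kv[2])
      })
    }
    saav <- integer(0)
    if ("saav_positions" %in% names(tab) && nzchar(trimws(tab$saav_positions[i])))
      saav <- as.integer(strsplit(tab$saav_positions[i], ",")[[1]])
    markerPeptide(tab$id[i], tab$sequence[i], tab$source[i],
                  as.integer(tab$charge[i]), as.numeric(tab$reference_mz[i]),
                  modifications = mods, saavPositions = saav,
                  registry = registry)
  })
  markerPanel(markers)
}

#' @rdname loadPanel
#' @export
writePanel <- function(panel, path) {
  rows <- lapply(panel@markers, function(m) {
    mods <- ""
    if (nrow(m@peptide@modifications))
      mods <- paste(m@peptide@modifications$position,
                    m@peptide@modifications$name, sep = ":", collapse = ";")
    data.frame(id = m@id, sequence = m@peptide@sequence, mods = mods,
               charge = m@charge, reference_mz = sprintf("%.4f", m@referenceMz),
               source = m@source,
               saav_positions = paste(m@saavPositions, collapse = ","))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Panel uniqueness check against protein sequences
#'
#' Locates each marker sequence in the supplied AmelX and AmelY protein
#' sequences by exact substring matching (optionally allowing up to
#' \code{maxMismatch} mismatches). A marker passes iff it occurs in its
#' source protein and not in the other. This reproduces, at panel scope, the
#' requirement that the diagnostic peptides are specific to their amelogenin
#' isoform; it is not a proteome-wide homology search.
#'
#' @param panel a [MarkerPanel-class].
#' @param proteins a named \code{Biostrings::AAStringSet} (or named character
#'   vector) with entries whose names contain \code{"AmelX"} and
#'   \code{"AmelY"}, or the path to such a FASTA file.
#' @param maxMismatch allowed mismatches in the substring search (default 0).
#' @return data.frame with one row per marker: \code{id}, \code{source},
#'   \code{found_in_source}, \code{found_in_other}, \code{positions_source},
#'   \code{positions_other} (comma-joined 1-based start positions) and
#'   \code{pass}.
#' @examples
#' fa <- system.file("extdata", "synthetic_amelogenin.fasta", package = "enamelLFQ")
#' validateUniqueness(defaultPanel(), fa)
#' @export
validateUniqueness <- function(panel, proteins, maxMismatch = 0L) {
  if (is.character(proteins) && length(proteins) == 1L && file.exists(proteins))
    proteins <- Biostrings::readAAStringSet(proteins)
  if (is.character(proteins)) proteins <- Biostrings::AAStringSet(proteins)
  nm <- names(proteins)
  ix <- grep("AmelX", nm, ignore.case = TRUE)
  iy <- grep("AmelY", nm, ignore.case = TRUE)
  if (length(ix) != 1L || length(iy) != 1L)
    stop("proteins must contain exactly one AmelX and one AmelY record")
  seqs <- list(AmelX = proteins[[ix]], AmelY = proteins[[iy]])
  rows <- lapply(panel@markers, function(m) {
    hits <- lapply(seqs, function(s)
      Biostrings::start(Biostrings::matchPattern(m@peptide@sequence, s,
                                                 max.mismatch = maxMismatch)))
    other <- setdiff(c("AmelX", "AmelY"), m@source)
    data.frame(id = m@id, source = m@source,
               found_in_source = length(hits[[m@source]]) > 0L,
               found_in_other = length(hits[[other]]) > 0L,
               positions_source = paste(hits[[m@source]], collapse = ","),
               positions_other = paste(hits[[other]], collapse = ","),
               pass = length(hits[[m@source]]) > 0L && length(hits[[other]]) == 0L)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Internal helpers used across modules.
.markerIds <- function(panel) vapply(panel@markers, function(m) m@id, character(1))
.markerSources <- function(panel) vapply(panel@markers, function(m) m@source, character(1))
.getMarker <- function(panel, id) {
  i <- match(id, .markerIds(panel))
  if (is.na(i)) stop("no marker with id ", id)
  panel@markers[[i]]
}
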