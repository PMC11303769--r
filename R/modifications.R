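# The modification registry: fixed monoisotopic mass deltas with their
# elemental-composition deltas and residue constraints.

.modEntry <- function(name, dC = 0, dH = 0, dN = 0, dO = 0, dS = 0, dP = 0,
                      residues = "", nterm = FALSE) {
  d <- c(C = dC, H = dH, N = dN, O = dO, S = dS, P = dP)
  data.frame(name = name, dC = dC, dH = dH, dN = dN, dO = dO, dS = dS, dP = dP,
             deltaMass = sum(d * .ELEMENT_MONO),
             residues = residues, nterm = nterm, stringsAsFactors = FALSE)
}

#' Default modification registry
#'
#' The set of variable modifications the pipeline knows about, matching the
#' search settings used for enamel peptidomes: Oxidation (F,H,K,M,P,W,Y),
#' Deamidation (N,Q,R), N-terminal acetylation, Gln/Glu to pyro-Glu at the
#' N-terminus, phosphorylation (S), and di-oxidation as a distinct entry.
#' Mass deltas are derived from the composition deltas, so the two can never
#' disagree.
#'
#' @return data.frame with columns \code{name}, element deltas
#'   \code{dC..dP}, \code{deltaMass} (Da), \code{residues} (allowed residue
#'   letters, collapsed) and \code{nterm} (must sit at the N-terminus).
#' @examples
#' defaultModifications()
#' @export
defaultModifications <- function() {
  rbind(
    .modEntry("Oxidation",      dO = 1, residues = "FHKMPWY"),
    .modEntry("Deamidation",    dH = -1, dN = -1, dO = 1, residues = "NQR"),
    .modEntry("Dioxidation",    dO = 2, residues = "FMPWY"),
    .modEntry("Phosphorylation", dH = 1, dO = 3, dP = 1, residues = "S"),
    .modEntry("Acetyl",         dC = 2, dH = 2, dO = 1, residues = "", nterm = TRUE),
    .modEntry("Gln->pyro-Glu",  dH = -3, dN = -1, residues = "Q", nterm = TRUE),
    .modEntry("Glu->pyro-Glu",  dH = -2, dO = -1, residues = "E", nterm = TRUE)
  )
}

#' Read / write a modification registry file
#'
#' The registry is serialized as a plain key-value text file, one
#' modification per line:
#' \code{name <tab> composition-delta <tab> residues <tab> nterm}, where the
#' composition delta uses signed element counts like \code{"O1"} or
#' \code{"H-1 N-1 O1"}. The mass delta is always recomputed from the
#' composition, and checked against an optional \code{mass} column to
#' < 1e-4 Da.
#'
#' @param path file path.
#' @param registry a registry data.frame as returned by
#'   [defaultModifications()].
#' @return \code{loadModifications}: a registry data.frame;
#'   \code{writeModifications}: the path, invisibly.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeModifications(defaultModifications(), f)
#' identical(loadModifications(f)$name, defaultModifications()$name)
#' @export
loadModifications <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("name", "composition", "residues", "nterm")
  if (!all(req %in% names(tab)))
    stop("modification file must have columns: ", paste(req, collapse = ", "))
  out <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    d <- .parseCompositionDelta(tab$composition[i])
    e <- .modEntry(tab$name[i], d["C"], d["H"], d["N"], d["O"], d["S"], d["P"],
                   residues = ifelse(is.na(tab$residues[i]), "", tab$residues[i]),
                   nterm = isTRUE(as.logical(tab$nterm[i])))
    if ("mass" %in% names(tab) && !is.na(tab$mass[i]) &&
        abs(e$deltaMass - tab$mass[i]) > 1e-4)
      stop(sprintf("modification '%s': stated mass %.6f inconsistent with composition (%.6f)",
                   tab$name[i], tab$mass[i], e$deltaMass))
    e
  }))
  rownames(out) <- NULL
  out
}

#' @rdname loadModifications
#' @export
writeModifications <- function(registry, path) {
  comp <- vapply(seq_len(nrow(registry)), function(i) {
    d <- unlist(registry[i, c("dC", "dH", "dN", "dO", "dS", "dP")])
    names(d) <- .ELEMENTS
    d <- d[d != 0]
    paste0(names(d), d, collapse = " ")
  }, character(1))
  out <- data.frame(name = registry$name, composition = comp,
                    residues = registry$residues, nterm = registry$nterm,
                    mass = sprintf("%.6f", registry$deltaMass))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# "H-1 N-1 O1" -> named vector over .ELEMENTS
.parseCompositionDelta <- function(s) {
  d <- stats::setNames(numeric(length(.ELEMENTS)), .ELEMENTS)
  if (is.na(s) || !nzchar(trimws(s))) return(d)
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  for (t in toks) {
    m <- regmatches(t, regexec("^([CHNOSP])(-?[0-9]+)$", t))[[1]]
    if (length(m) != 3L) stop("cannot parse composition token: ", t)
    d[m[2]] <- d[m[2]] + as.numeric(m[3])
  }
  d
}

# Look up a modification by name; registry defaults to the shipped set.
.getMod <- function(name, registry = defaultModifications()) {
  i <- match(name, registry$name)
  if (is.na(i)) stop("unknown modification: ", name)
  registry[i, , drop = FALSE]
}
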