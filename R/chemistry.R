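#' Construct a modified peptide
#'
#' @param sequence peptide sequence (20 standard one-letter codes; I and L
#'   are distinct letters with identical mass).
#' @param modifications either a data.frame with columns \code{position}
#'   (1-based index or \code{"N-term"}) and \code{name}, or a list of
#'   \code{list(position =, name =)} pairs. Positions and residue
#'   constraints are validated against \code{registry}.
#' @param registry modification registry (see [defaultModifications()]).
#' @return a [ModifiedPeptide-class] object.
#' @examples
#' modifiedPeptide("LRYPYP")
#' modifiedPeptide("SMIRHPYP", list(list(position = 2, name = "Oxidation")))
#' @export
modifiedPeptide <- function(sequence, modifications = list(),
                            registry = defaultModifications()) {
  if (is.data.frame(modifications)) {
    mods <- data.frame(position = as.character(modifications$position),
                       name = as.character(modifications$name),
                       stringsAsFactors = FALSE)
  } else {
    mods <- do.call(rbind, lapply(modifications, function(m)
      data.frame(position = as.character(m$position), name = as.character(m$name),
                 stringsAsFactors = FALSE)))
    if (is.null(mods))
      mods <- data.frame(position = character(0), name = character(0))
  }
  pep <- new("ModifiedPeptide", sequence = toupper(sequence), modifications = mods)
  .checkModResidues(pep, registry)
  pep
}

# Residue-constraint check against the registry (beyond structural validity).
.checkModResidues <- function(pep, registry = defaultModifications()) {
  m <- pep@modifications
  if (!nrow(m)) return(invisible(TRUE))
  letters1 <- strsplit(pep@sequence, "")[[1]]
  for (i in seq_len(nrow(m))) {
    entry <- .getMod(m$name[i], registry)
    allowed <- strsplit(entry$residues, "")[[1]]
    if (m$position[i] == "N-term") {
      if (!entry$nterm)
        stop(sprintf("modification '%s' is not an N-terminal modification", m$name[i]))
      if (length(allowed) && !letters1[1] %in% allowed)
        stop(sprintf("'%s' requires an N-terminal residue among %s (found %s)",
                     m$name[i], entry$residues, letters1[1]))
    } else {
      pos <- as.integer(m$position[i])
      if (entry$nterm && pos != 1L)
        stop(sprintf("modification '%s' must sit at the N-terminus", m$name[i]))
      if (length(allowed) && !letters1[pos] %in% allowed)
        stop(sprintf("modification '%s' not allowed on residue %s at position %d (allowed: %s)",
                     m$name[i], letters1[pos], pos, entry$residues))
    }
  }
  invisible(TRUE)
}

#' Monoisotopic mass of a modified peptide
#'
#' Sum of residue monoisotopic masses, one water, and all modification mass
#' deltas.
#'
#' @inheritParams elementalComposition
#' @return neutral monoisotopic mass in Da.
#' @examples
#' monoisotopicMass(modifiedPeptide("G"))        # 75.03203, free glycine
#' monoisotopicMass(modifiedPeptide("LRYPYP"))   # 807.4279
#' @export
monoisotopicMass <- function(peptide, registry = defaultModifications()) {
  peptide <- .asPeptide(peptide, registry)
  letters1 <- strsplit(peptide@sequence, "")[[1]]
  m <- sum(.RESIDUE_MASS[letters1]) + WATER_MASS
  if (nrow(peptide@modifications))
    m <- m + sum(vapply(peptide@modifications$name,
                        function(n) .getMod(n, registry)$deltaMass, numeric(1)))
  m
}

#' Convert between neutral mass and m/z
#'
#' \code{ionMz} computes the m/z of the z-fold protonated ion,
#' \code{(M + z * 1.00727646688) / z}; \code{neutralMass} inverts it.
#'
#' @param mass neutral monoisotopic mass (Da).
#' @param z positive integer charge.
#' @param mz an observed or theoretical m/z.
#' @return m/z (resp. neutral mass) in Da.
#' @examples
#' ionMz(monoisotopicMass(modifiedPeptide("LRYPYP")), 2)   # 404.7212
#' neutralMass(404.7212, 2)
#' @export
ionMz <- function(mass, z) {
  z <- as.integer(z)
  if (any(is.na(z)) || any(z < 1L)) stop("charge z must be a positive integer")
  (mass + z * PROTON_MASS) / z
}

#' @rdname ionMz
#' @export
neutralMass <- function(mz, z) {
  z <- as.integer(z)
  if (any(is.na(z)) || any(z < 1L)) stop("charge z must be a positive integer")
  mz * z - z * PROTON_MASS
}

#' Elemental composition of a modified peptide
#'
#' @param peptide a [ModifiedPeptide-class] (or a bare sequence string,
#'   taken as unmodified).
#' @param registry modification registry.
#' @return an [ElementalComposition-class] (named integer vector over
#'   C, H, N, O, S, P).
#' @examples
#' elementalComposition("G")    # C2 H5 N1 O2
#' elementalComposition("GG")   # C4 H8 N2 O3: condensation removes water
#' @export
elementalComposition <- function(peptide, registry = defaultModifications()) {
  peptide <- .asPeptide(peptide, registry)
  letters1 <- strsplit(peptide@sequence, "")[[1]]
  counts <- Reduce(`+`, .RESIDUE_FORMULA[letters1])
  counts["H"] <- counts["H"] + 2  # water
  counts["O"] <- counts["O"] + 1
  if (nrow(peptide@modifications)) {
    for (n in peptide@modifications$name) {
      e <- .getMod(n, registry)
      counts <- counts + c(C = e$dC, H = e$dH, N = e$dN, O = e$dO, S = e$dS, P = e$dP)
    }
  }
  if (any(counts < 0)) stop("modifications produce a negative atom count")
  new("ElementalComposition", stats::setNames(as.integer(counts), .ELEMENTS))
}

#' Add two elemental compositions
#'
#' @param a,b [ElementalComposition-class] objects.
#' @return their element-wise sum.
#' @export
addComposition <- function(a, b) {
  out <- stats::setNames(integer(length(.ELEMENTS)), .ELEMENTS)
  out[names(a)] <- out[names(a)] + as.integer(a)
  out[names(b)] <- out[names(b)] + as.integer(b)
  new("ElementalComposition", out)
}

#' Mass of an elemental composition
#'
#' @param composition an [ElementalComposition-class].
#' @return monoisotopic mass in Da.
#' @export
compositionMass <- function(composition) {
  sum(as.integer(composition) * .ELEMENT_MONO[names(composition)])
}

# Accept a string where a peptide is expected.
.asPeptide <- function(x, registry = defaultModifications()) {
  if (is(x, "ModifiedPeptide")) return(x)
  if (is.character(x) && length(x) == 1L) return(modifiedPeptide(x, registry = registry))
  stop("expected a ModifiedPeptide or a sequence string")
}

#' Theoretical isotopic envelope
#'
#' Computes the aggregated isotopologue distribution (A0, A+1, ...) of an
#' elemental composition by per-element convolution of single-atom isotope
#' distributions, binned at nominal-mass (one-neutron) resolution. Peak
#' m/z values are spaced by 1.0033548/z above the monoisotopic ion.
#'
#' @param x an [ElementalComposition-class], [ModifiedPeptide-class] or
#'   sequence string.
#' @param z charge state (default 1).
#' @param nPeaks number of isotopologue peaks to return (default 4; for
#'   ~1 kDa peptides these carry >99\% of the intensity).
#' @param normalize if TRUE (default) the returned abundances are rescaled
#'   to sum to 1; if FALSE they are the absolute probabilities of the full
#'   distribution (which sums to 1 over all isotopologues).
#' @return data.frame with columns \code{mz} and \code{abundance},
#'   \code{nPeaks} rows.
#' @examples
#' isotopeEnvelope("LRYPYP", z = 2)
#' # single carbon atom: A1/A0 equals the natural 13C/12C ratio
#' cc <- new("ElementalComposition", c(C = 1L))
#' e <- isotopeEnvelope(cc, nPeaks = 2, normalize = FALSE)
#' e$abundance[2] / e$abundance[1]
#' @export
isotopeEnvelope <- function(x, z = 1L, nPeaks = 4L, normalize = TRUE) {
  if (nPeaks < 1L) stop("nPeaks must be >= 1")
  comp <- if (is(x, "ElementalComposition")) x else elementalComposition(x)
  if (sum(as.integer(comp)) == 0L) stop("empty elemental composition")
  dist <- .aggregatedIsotopeDistribution(comp)
  n <- min(nPeaks, length(dist))
  ab <- c(dist[seq_len(n)], rep(0, max(0L, nPeaks - length(dist))))
  if (normalize) ab <- ab / sum(ab)
  mono <- compositionMass(comp)
  mzs <- (mono + (seq_len(nPeaks) - 1L) * NEUTRON_SPACING + z * PROTON_MASS) / z
  data.frame(mz = mzs, abundance = ab)
}

# Full aggregated (nominal-mass) isotopologue distribution of a composition.
# Per element: single-atom offset distribution raised to the atom count by
# exponentiation-by-squaring under polynomial convolution; elements then
# convolved together. Tails below 1e-15 are dropped.
.aggregatedIsotopeDistribution <- function(comp) {
  result <- 1.0
  for (el in names(comp)) {
    n <- as.integer(comp[el])
    if (n == 0L) next
    iso <- .ISOTOPES[[el]]
    # offsets in neutron units relative to the lightest isotope
    off <- round(iso[, "mass"] - iso[1, "mass"])
    single <- numeric(max(off) + 1L)
    single[off + 1L] <- iso[, "abundance"]
    result <- .convolve(result, .polyPower(single, n))
  }
  result[result < 0] <- 0
  result
}

.convolve <- function(a, b) {
  if (length(a) == 1L) return(a * b)
  if (length(b) == 1L) return(b * a)
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  # truncate negligible tail to keep vectors short
  keep <- max(which(out > 1e-15), 1L)
  out[seq_len(keep)]
}

.polyPower <- function(p, n) {
  result <- 1.0
  base <- p
  while (n > 0L) {
    if (n %% 2L == 1L) result <- .convolve(result, base)
    base <- .convolve(base, base)
    n <- n %/% 2L
  }
  result
}

#' Theoretical b and y fragment ions
#'
#' Generates singly- to \code{maxCharge}-fold protonated b and y ions of a
#' modified peptide. Position-resolved modifications are assigned to the
#' fragment containing their residue; N-terminal modifications follow the b
#' series (and the full-length y ion).
#'
#' @param peptide a [ModifiedPeptide-class] or sequence string.
#' @param series character subset of \code{c("b", "y")}.
#' @param maxCharge maximum fragment charge (default 1).
#' @param registry modification registry.
#' @return data.frame with columns \code{label} (e.g. \code{"b3^1"}),
#'   \code{series}, \code{index}, \code{charge}, \code{mz}.
#' @examples
#' fragmentIons("LR")                 # b1/y1/b... of a dipeptide
#' fragmentIons("LRYPYP", maxCharge = 2)
#' @export
fragmentIons <- function(peptide, series = c("b", "y"), maxCharge = 1L,
                         registry = defaultModifications()) {
  series <- match.arg(series, c("b", "y"), several.ok = TRUE)
  if (!length(series)) stop("series must be a non-empty subset of {b, y}")
  peptide <- .asPeptide(peptide, registry)
  letters1 <- strsplit(peptide@sequence, "")[[1]]
  n <- length(letters1)
  if (n < 2L) stop("fragment ions require a peptide of length >= 2")
  resMass <- .RESIDUE_MASS[letters1]
  # per-residue modification deltas; N-term delta rides with residue 1 in b
  # ions (and with the full peptide in y_n)
  modDelta <- numeric(n)
  ntermDelta <- 0
  if (nrow(peptide@modifications)) {
    for (i in seq_len(nrow(peptide@modifications))) {
      d <- .getMod(peptide@modifications$name[i], registry)$deltaMass
      if (peptide@modifications$position[i] == "N-term") ntermDelta <- ntermDelta + d
      else {
        p <- as.integer(peptide@modifications$position[i])
        modDelta[p] <- modDelta[p] + d
      }
    }
  }
  cumFwd <- cumsum(resMass + modDelta)      # neutral b-fragment residue sums
  total <- cumFwd[n]
  rows <- list()
  for (zc in seq_len(as.integer(maxCharge))) {
    if ("b" %in% series) {
      i <- seq_len(n)                       # b_n (full acylium) included
      rows[[length(rows) + 1L]] <- data.frame(
        label = sprintf("b%d^%d", i, zc), series = "b", index = i, charge = zc,
        mz = (cumFwd[i] + ntermDelta + zc * PROTON_MASS) / zc)
    }
    if ("y" %in% series) {
      j <- seq_len(n)
      ySum <- total - c(0, cumFwd)[n - j + 1L]  # residues (n-j+1)..n + mods
      ySum[j == n] <- ySum[j == n] + ntermDelta # full-length y carries N-term mods
      rows[[length(rows) + 1L]] <- data.frame(
        label = sprintf("y%d^%d", j, zc), series = "y", index = j, charge = zc,
        mz = (ySum + WATER_MASS + zc * PROTON_MASS) / zc)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
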