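#' Bulk deamidation occupancy
#'
#' Intensity-weighted site-level deamidation fraction over a set of
#' quantified peptide forms:
#' \deqn{occ(X) = \frac{\sum_i area_i \cdot nDeam_i(X)}{\sum_i area_i \cdot
#'   nSites_i(X)}}
#' for residue class X in {N, Q}. Site-level weighting (areas times site
#' counts) makes the statistic unbiased when forms carry unequal numbers of
#' sites. When no eligible intensity exists (denominator zero) the result is
#' missing (NA), not 0.
#'
#' @param forms data.frame with columns \code{area}, \code{nSitesN},
#'   \code{nDeamN}, \code{nSitesQ}, \code{nDeamQ}.
#' @param class \code{"N"} or \code{"Q"}.
#' @return occupancy in [0, 1], or NA when undefined.
#' @examples
#' f <- data.frame(area = c(1, 1), nSitesN = c(1, 1), nDeamN = c(0, 1),
#'                 nSitesQ = 0, nDeamQ = 0)
#' bulkOccupancy(f, "N")  # 0.5
#' @export
bulkOccupancy <- function(forms, class = c("N", "Q")) {
  class <- match.arg(class)
  nd <- forms[[paste0("nDeam", class)]]
  ns <- forms[[paste0("nSites", class)]]
  if (any(nd > ns, na.rm = TRUE) || any(forms$area < 0, na.rm = TRUE))
    stop("invalid form table: nDeam > nSites or negative area")
  ok <- !is.na(nd) & !is.na(ns) & !is.na(forms$area)
  den <- sum(forms$area[ok] * ns[ok])
  if (!is.finite(den) || den <= 0) return(NA_real_)
  sum(forms$area[ok] * nd[ok]) / den
}

#' Deamidation occupancy from a run
#'
#' Quantifies the deamidated forms of the declared background peptides by
#' targeted XIC extraction and applies [bulkOccupancy()] per residue class.
#'
#' Deamidation shifts the mass by +0.984016 Da per site regardless of which
#' site carries it, so positional isomers are isobaric: the MS1-observable
#' species of a peptide with k N/Q sites are the deamidation \emph{counts}
#' d = 0..k, not the site combinations. One XIC envelope is therefore
#' extracted per count. The per-class (N vs Q) attribution of a count is
#' only identifiable when all of a peptide's sites belong to one class;
#' mixed-class peptides are quantified but flagged \code{ambiguous} and
#' excluded from the per-class occupancy statistic (the shipped
#' [defaultBackground()] peptides are single-class by design).
#'
#' Forms whose observed isotope envelope fails the score threshold, and
#' zero-area forms, are excluded from the weighting.
#'
#' @param run an [MSRun-class].
#' @param background data.frame with a \code{sequence} column (e.g.
#'   [defaultBackground()]).
#' @param params see [quantParams()].
#' @param charge charge state the background forms are extracted at.
#' @return list with \code{occupancyN}, \code{occupancyQ} (NA when
#'   undefined), \code{totalIntensity}, \code{nForms} (forms passing the
#'   envelope filter) and \code{forms} (the per-form quantification table).
#' @export
occupancyFromRun <- function(run, background = defaultBackground(),
                             params = quantParams(), charge = 2L) {
  if (!nrow(background))
    return(list(occupancyN = NA_real_, occupancyQ = NA_real_,
                totalIntensity = 0, nForms = 0L,
                forms = data.frame()))
  flat <- .flattenMs1(run)
  rows <- list()
  for (b in seq_len(nrow(background))) {
    seqb <- background$sequence[b]
    letters1 <- strsplit(seqb, "")[[1]]
    sites <- which(letters1 %in% c("N", "Q"))
    nN <- sum(letters1 == "N"); nQ <- sum(letters1 == "Q")
    singleClass <- if (nN > 0 && nQ == 0) "N" else if (nQ > 0 && nN == 0) "Q"
                   else NA_character_
    for (d in 0:length(sites)) {
      mods <- lapply(sites[seq_len(d)], function(p)
        list(position = p, name = "Deamidation"))
      pep <- modifiedPeptide(seqb, mods)
      q <- .quantifyForm(flat, pep, charge, params)
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = seqb,
        form = paste0(seqb, if (d) paste0("+", d, "deam") else ""),
        nDeam = d, ambiguous = is.na(singleClass),
        area = q$area, envelopeScore = q$envelopeScore,
        nSitesN = if (identical(singleClass, "N")) nN else
          if (identical(singleClass, "Q")) 0L else NA_integer_,
        nDeamN = if (identical(singleClass, "N")) d else
          if (identical(singleClass, "Q")) 0L else NA_integer_,
        nSitesQ = if (identical(singleClass, "Q")) nQ else
          if (identical(singleClass, "N")) 0L else NA_integer_,
        nDeamQ = if (identical(singleClass, "Q")) d else
          if (identical(singleClass, "N")) 0L else NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  forms <- do.call(rbind, rows)
  keep <- forms$area > 0 & forms$envelopeScore >= params$minEnvelopeScore
  used <- forms[keep, , drop = FALSE]
  list(occupancyN = bulkOccupancy(used, "N"),
       occupancyQ = bulkOccupancy(used, "Q"),
       totalIntensity = sum(used$area), nForms = nrow(used), forms = forms)
}

#' Compare deamidation between two sample groups
#'
#' Descriptive per-class comparison of bulk occupancies, e.g. modern (A)
#' versus archaeological (B): group means (missing values excluded) and the
#' fold change mean_B / mean_A. A zero reference mean gives an infinite fold
#' and is flagged.
#'
#' @param groupA,groupB data.frames (or lists) with elements/columns
#'   \code{occupancyN} and \code{occupancyQ}, one entry per sample.
#' @return data.frame with one row per class: \code{class}, \code{meanA},
#'   \code{meanB}, \code{fold}, \code{flagged}.
#' @examples
#' a <- data.frame(occupancyN = c(0.1, 0.1), occupancyQ = c(0.1, 0.1))
#' b <- data.frame(occupancyN = c(0.3, 0.3), occupancyQ = c(0.5, 0.5))
#' compareGroups(a, b)
#' @export
compareGroups <- function(groupA, groupB) {
  groupA <- as.data.frame(groupA)
  groupB <- as.data.frame(groupB)
  rows <- lapply(c("N", "Q"), function(cl) {
    colname <- paste0("occupancy", cl)
    a <- groupA[[colname]]; b <- groupB[[colname]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (!length(a) || !length(b))
      stop("each group needs at least one defined occupancy for class ", cl)
    ma <- mean(a); mb <- mean(b)
    fold <- if (ma == 0) Inf else mb / ma
    data.frame(class = cl, meanA = ma, meanB = mb, fold = fold,
               flagged = !is.finite(fold), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
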