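#' Build a gold-standard PSM set from closed-search results
#'
#' Retains exactly the PSMs whose peptide equals the mouse member of some
#' cognate pair (exact string match: closed-search peptides come from a
#' sequence database, so I and L are disambiguated). When one tool reports
#' several peptides for a spectrum, only the best-scoring row is kept.
#'
#' @param closed_psms data.frame of normalized PSMs from one tool's
#'   closed search against the human+mouse database (columns \code{sample_id},
#'   \code{spectrum_id}, \code{peptide}; optional \code{score}, \code{tool}).
#' @param pairs A [CognatePairSet-class].
#' @return A [GoldStandard-class] with tool provenance.
#' @export
buildGoldStandard <- function(closed_psms, pairs) {
    stopifnot(is.data.frame(closed_psms), is(pairs, "CognatePairSet"))
    closed_psms <- .bestPerSpectrum(closed_psms)
    mouse <- unique(pairsTable(pairs)$mouse_peptide)
    keep <- closed_psms$peptide %in% mouse
    if (!any(keep)) {
        warning("no closed-search PSM matches a catalog mouse peptide")
    }
    tool <- if ("tool" %in% colnames(closed_psms) && nrow(closed_psms)) {
        closed_psms$tool[1]
    } else "unknown"
    GoldStandard(closed_psms[keep, , drop = FALSE], provenance = tool)
}

#' Build the dependent-search gold standard
#'
#' As [buildGoldStandard()], further restricted to mouse peptides whose paired
#' human cognate peptide was itself identified among the same sample's
#' closed-search PSMs — the assumption under which a dependent peptide search
#' operates (the variant is explained as a modified form of an identified base
#' peptide).
#'
#' @inheritParams buildGoldStandard
#' @return A [GoldStandard-class].
#' @export
buildDependentGoldStandard <- function(closed_psms, pairs) {
    gs <- buildGoldStandard(closed_psms, pairs)
    k <- goldKeys(gs)
    if (nrow(k) == 0L) return(gs)
    pt <- pairsTable(pairs)
    closed_psms <- .bestPerSpectrum(closed_psms)
    human_by_sample <- split(closed_psms$peptide, closed_psms$sample_id)
    cognates <- split(pt$human_peptide, pt$mouse_peptide)
    keep <- vapply(seq_len(nrow(k)), function(i) {
        any(cognates[[k$peptide[i]]] %in% human_by_sample[[k$sample_id[i]]])
    }, logical(1))
    GoldStandard(k[keep, , drop = FALSE],
                 provenance = paste0(provenance(gs), "_dependent"))
}

#' Combine two gold standards into a mixed gold standard
#'
#' Per-sample set intersection or union of (spectrum, peptide) keys. The
#' intersection is the stricter ground truth used for sensitivity; the union
#' is the more inclusive one used for precision.
#'
#' @param gs_a,gs_b [GoldStandard-class] objects over the same samples.
#' @param mode \code{"intersection"} or \code{"union"}.
#' @return A [GoldStandard-class] with provenance set to the mode.
#' @export
mixGoldStandards <- function(gs_a, gs_b, mode = c("intersection", "union")) {
    mode <- match.arg(mode)
    a <- goldKeys(gs_a)
    b <- goldKeys(gs_b)
    ka <- paste(a$sample_id, a$spectrum_id, a$peptide, sep = "\r")
    kb <- paste(b$sample_id, b$spectrum_id, b$peptide, sep = "\r")
    keys <- if (mode == "intersection") {
        a[ka %in% kb, , drop = FALSE]
    } else {
        rbind(a, b[!(kb %in% ka), , drop = FALSE])
    }
    GoldStandard(keys, provenance = mode)
}

# one PSM per (sample, spectrum): keep the best-scoring row (ties/no score:
# first occurrence)
.bestPerSpectrum <- function(psms) {
    if (nrow(psms) == 0L) return(psms)
    o <- if ("score" %in% colnames(psms)) {
        order(psms$sample_id, psms$spectrum_id,
              -replace(psms$score, is.na(psms$score), -Inf))
    } else {
        seq_len(nrow(psms))
    }
    psms <- psms[o, , drop = FALSE]
    key <- paste(psms$sample_id, psms$spectrum_id, sep = "\r")
    psms[!duplicated(key), , drop = FALSE]
}
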