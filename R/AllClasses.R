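#' CognatePairSet: cross-species SAAV catalog
#'
#' Holds cognate human/mouse tryptic peptide pairs of equal length that differ
#' at exactly one site, each annotated with its SAAV (human-to-mouse
#' orientation), mass shift and biochemical-category classification.
#'
#' @slot pairs DataFrame with columns \code{gene_symbol},
#'   \code{human_peptide}, \code{mouse_peptide}, \code{site}, \code{from_aa},
#'   \code{to_aa}, \code{delta_mass}, \code{same_category}.
#' @export
setClass("CognatePairSet", representation(pairs = "DataFrame"))

setValidity("CognatePairSet", function(object) {
    p <- object@pairs
    need <- c("gene_symbol", "human_peptide", "mouse_peptide", "site",
              "from_aa", "to_aa", "delta_mass", "same_category")
    miss <- setdiff(need, colnames(p))
    if (length(miss)) {
        return(paste("missing pair columns:", paste(miss, collapse = ", ")))
    }
    if (nrow(p) == 0L) return(TRUE)
    if (any(nchar(p$human_peptide) != nchar(p$mouse_peptide))) {
        return("cognate peptides must have equal length")
    }
    hs <- substr(p$human_peptide, p$site, p$site)
    ms <- substr(p$mouse_peptide, p$site, p$site)
    if (any(hs != p$from_aa) || any(ms != p$to_aa)) {
        return("recorded SAAV does not match peptide residues at the site")
    }
    TRUE
})

#' Construct a CognatePairSet
#' @param pairs data.frame or DataFrame of cognate pairs (see class slots).
#' @return A [CognatePairSet-class] object.
#' @export
CognatePairSet <- function(pairs) {
    new("CognatePairSet", pairs = DataFrame(pairs))
}

#' @describeIn CognatePairSet-class Number of cognate pairs.
#' @param x A CognatePairSet.
#' @export
setMethod("length", "CognatePairSet", function(x) nrow(x@pairs))

setMethod("show", "CognatePairSet", function(object) {
    cat(sprintf("CognatePairSet with %d pair(s), %d gene(s), %d SAAV type(s)\n",
                nrow(object@pairs),
                length(unique(object@pairs$gene_symbol)),
                nrow(unique(object@pairs[, c("from_aa", "to_aa")]))))
})

#' Extract the pair table of a CognatePairSet
#' @param x A [CognatePairSet-class].
#' @return data.frame of cognate pairs.
#' @export
pairsTable <- function(x) {
    stopifnot(is(x, "CognatePairSet"))
    as.data.frame(x@pairs)
}

#' GoldStandard: per-sample set of gold PSM keys
#'
#' A gold standard is the set of (sample, spectrum, mouse peptide) keys that a
#' closed search against the concatenated human+mouse database assigned to a
#' catalog mouse peptide. Provenance records the producing tool, or
#' \code{"intersection"}/\code{"union"} for mixed gold standards.
#'
#' @slot keys DataFrame with columns \code{sample_id}, \code{spectrum_id},
#'   \code{peptide}.
#' @slot provenance Single character label.
#' @export
setClass("GoldStandard",
         representation(keys = "DataFrame", provenance = "character"))

setValidity("GoldStandard", function(object) {
    k <- object@keys
    need <- c("sample_id", "spectrum_id", "peptide")
    miss <- setdiff(need, colnames(k))
    if (length(miss)) {
        return(paste("missing key columns:", paste(miss, collapse = ", ")))
    }
    if (anyDuplicated(paste(k$sample_id, k$spectrum_id, k$peptide))) {
        return("duplicate gold keys")
    }
    if (length(object@provenance) != 1L) {
        return("provenance must be a single label")
    }
    TRUE
})

#' Construct a GoldStandard
#' @param keys data.frame with columns sample_id, spectrum_id, peptide.
#' @param provenance Label of the producing tool or combination.
#' @return A [GoldStandard-class] object.
#' @export
GoldStandard <- function(keys, provenance = "unknown") {
    keys <- unique(as.data.frame(keys)[, c("sample_id", "spectrum_id",
                                           "peptide")])
    rownames(keys) <- NULL
    new("GoldStandard", keys = DataFrame(keys), provenance = provenance)
}

#' @describeIn GoldStandard-class Number of gold PSM keys.
#' @param x A GoldStandard.
#' @export
setMethod("length", "GoldStandard", function(x) nrow(x@keys))

setMethod("show", "GoldStandard", function(object) {
    cat(sprintf("GoldStandard [%s]: %d PSM key(s) in %d sample(s)\n",
                object@provenance, nrow(object@keys),
                length(unique(object@keys$sample_id))))
})

#' Extract the key table of a GoldStandard
#' @param x A [GoldStandard-class].
#' @return data.frame with sample_id, spectrum_id, peptide.
#' @export
goldKeys <- function(x) {
    stopifnot(is(x, "GoldStandard"))
    as.data.frame(x@keys)
}

#' Provenance label of a GoldStandard
#' @param x A [GoldStandard-class].
#' @return Character label.
#' @export
provenance <- function(x) {
    stopifnot(is(x, "GoldStandard"))
    x@provenance
}

#' Spectrum: a stick spectrum
#'
#' Sorted m/z values with nonnegative intensities; at least one intensity must
#' be positive.
#'
#' @slot mz Strictly increasing positive numeric vector (Da/charge).
#' @slot intensity Nonnegative numeric vector of the same length.
#' @export
setClass("Spectrum", representation(mz = "numeric", intensity = "numeric"))

setValidity("Spectrum", function(object) {
    if (length(object@mz) != length(object@intensity)) {
        return("mz and intensity lengths differ")
    }
    if (length(object@mz) == 0L) return("empty spectrum")
    if (any(object@mz <= 0) || is.unsorted(object@mz, strictly = TRUE)) {
        return("mz must be positive and strictly increasing")
    }
    if (any(object@intensity < 0) || all(object@intensity == 0)) {
        return("intensities must be nonnegative with at least one positive")
    }
    TRUE
})

#' Construct a Spectrum
#'
#' Peaks are sorted by m/z; peaks with (numerically) identical m/z are merged
#' by summing their intensities.
#'
#' @param mz Positive numeric m/z values.
#' @param intensity Nonnegative intensities, same length as \code{mz}.
#' @return A [Spectrum-class] object.
#' @export
Spectrum <- function(mz, intensity) {
    o <- order(mz)
    mz <- mz[o]
    intensity <- intensity[o]
    grp <- cumsum(c(TRUE, diff(mz) > 1e-9))
    new("Spectrum",
        mz = as.numeric(tapply(mz, grp, `[`, 1L)),
        intensity = as.numeric(tapply(intensity, grp, sum)))
}

#' @describeIn Spectrum-class Number of peaks.
#' @param x A Spectrum.
#' @export
setMethod("length", "Spectrum", function(x) length(x@mz))

setMethod("show", "Spectrum", function(object) {
    cat(sprintf("Spectrum with %d peak(s), m/z %.4f-%.4f\n",
                length(object@mz), min(object@mz), max(object@mz)))
})

#' Peak table of a Spectrum
#' @param x A [Spectrum-class].
#' @return data.frame with columns mz, intensity.
#' @export
peaks <- function(x) {
    stopifnot(is(x, "Spectrum"))
    data.frame(mz = x@mz, intensity = x@intensity)
}
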