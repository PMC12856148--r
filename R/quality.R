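#' Retention-time deviation
#'
#' Absolute difference between observed and predicted retention time; smaller
#' values indicate higher PSM quality.
#'
#' @param rt_observed,rt_predicted Retention times in minutes (vectorised).
#' @return Numeric vector of |observed - predicted|.
#' @export
rtDelta <- function(rt_observed, rt_predicted) {
    if (any(!is.finite(rt_observed)) || any(!is.finite(rt_predicted))) {
        stop("retention times must be finite")
    }
    abs(rt_observed - rt_predicted)
}

# greedy nearest-m/z peak matching; each peak matched at most once.
# Returns the padded intensity vectors (unmatched peaks get a zero partner).
.matchPeaks <- function(s1, s2, tol) {
    p1 <- peaks(s1)
    p2 <- peaks(s2)
    cand <- expand.grid(i = seq_len(nrow(p1)), j = seq_len(nrow(p2)))
    cand$d <- abs(p1$mz[cand$i] - p2$mz[cand$j])
    cand <- cand[cand$d <= tol, , drop = FALSE]
    cand <- cand[order(cand$d, cand$i, cand$j), , drop = FALSE]
    used1 <- logical(nrow(p1))
    used2 <- logical(nrow(p2))
    m1 <- integer(0)
    m2 <- integer(0)
    for (r in seq_len(nrow(cand))) {
        i <- cand$i[r]; j <- cand$j[r]
        if (used1[i] || used2[j]) next
        used1[i] <- TRUE; used2[j] <- TRUE
        m1 <- c(m1, i); m2 <- c(m2, j)
    }
    v1 <- c(p1$intensity[m1], p1$intensity[!used1],
            rep(0, sum(!used2)))
    v2 <- c(p2$intensity[m2], rep(0, sum(!used1)),
            p2$intensity[!used2])
    list(v1 = v1, v2 = v2)
}

#' Normalized spectral angle between two spectra
#'
#' Peaks are matched greedily by nearest m/z within \code{binning} Da (each
#' peak at most once; unmatched peaks contribute zero to the counterpart),
#' the intensity vectors are unit (L2) normalized, and the similarity is
#' SA = 1 - 2 * arccos(s1 . s2) / pi, in \code{[0, 1]}: 1 for identical
#' normalized spectra, 0 for spectra sharing no peaks. Greater SA indicates
#' higher PSM quality.
#'
#' @param s1,s2 [Spectrum-class] objects (e.g. experimental and predicted).
#' @param binning Peak-matching tolerance in Da (default 0.02).
#' @return SA value in \code{[0, 1]}.
#' @export
spectralAngle <- function(s1, s2, binning = 0.02) {
    m <- .matchPeaks(s1, s2, binning)
    n1 <- sqrt(sum(m$v1^2))
    n2 <- sqrt(sum(m$v2^2))
    if (n1 == 0 || n2 == 0) stop("all-zero intensity after peak matching")
    dot <- sum(m$v1 * m$v2) / (n1 * n2)
    dot <- min(max(dot, -1), 1)
    1 - 2 * acos(dot) / pi
}

#' Theoretical singly charged b/y fragment spectrum of a peptide
#'
#' b_i is the sum of the first i residue masses plus a proton; y_i the sum of
#' the last i residues plus water plus a proton, for i = 1 .. length-1. All
#' intensities are 1. \code{'X'} is treated as the isobaric Leu/Ile mass.
#'
#' @param peptide Amino-acid string of length >= 2.
#' @param table Residue mass table.
#' @return A [Spectrum-class] of 2*(length-1) fragments (coinciding m/z
#'   merged).
#' @export
predictFragmentMz <- function(peptide, table = aaMassTable()) {
    res <- strsplit(peptide, "")[[1]]
    res[res == "X"] <- "L"
    if (length(res) < 2L) {
        stop("peptide too short to fragment: ", peptide)
    }
    m <- unname(table[res])
    if (anyNA(m)) {
        stop("unknown residue(s) in peptide: ",
             paste(unique(res[is.na(m)]), collapse = ", "))
    }
    n <- length(m)
    b <- cumsum(m)[-n] + .PROTON
    y <- rev(cumsum(rev(m))[-n]) + .WATER + .PROTON
    Spectrum(c(b, y), rep(1, 2 * (n - 1L)))
}

#' Hydrophobicity-based retention-time prediction
#'
#' A linear device mapping summed residue hydropathy (Kyte-Doolittle scale,
#' with Ile set equal to Leu so the I/L-ambiguous class 'X' is well defined)
#' to minutes: rt = a * sum(hydropathy) + b. This is a simulation device for
#' producing observed/predicted retention-time pairs, not a chromatography
#' model.
#'
#' @param peptide Amino-acid string (vectorised); may contain \code{'X'}.
#' @param a,b Slope (min per hydropathy unit) and intercept (min).
#' @return Predicted retention time in minutes.
#' @export
predictRetentionTime <- function(peptide, a = 1.5, b = 30) {
    kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
            E = -3.5, G = -0.4, H = -3.2, I = 3.8, L = 3.8, K = -3.9,
            M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
            Y = -1.3, V = 4.2, X = 3.8)
    vapply(peptide, function(p) {
        res <- strsplit(p, "")[[1]]
        h <- kd[res]
        if (anyNA(h)) stop("unknown residue(s) in peptide: ", p)
        a * sum(h) + b
    }, numeric(1), USE.NAMES = FALSE)
}

#' Rank-sum separation of a quality metric between true and false PSMs
#'
#' One-sided Wilcoxon rank-sum test that correctly identified PSMs score
#' better than incorrect ones in the stated direction: \code{"smaller"} for
#' deviations like RT delta, \code{"larger"} for similarities like the
#' spectral angle.
#'
#' @param true_values,false_values Numeric metric values for the two groups.
#' @param direction \code{"smaller"} or \code{"larger"}: expected position of
#'   the TRUE group.
#' @return The \code{htest} object of the one-sided test.
#' @export
qualitySeparation <- function(true_values, false_values,
                              direction = c("smaller", "larger")) {
    direction <- match.arg(direction)
    if (length(true_values) == 0L || length(false_values) == 0L) {
        stop("both groups must be non-empty")
    }
    stats::wilcox.test(true_values, false_values,
                       alternative = switch(direction, smaller = "less",
                                            larger = "greater"),
                       exact = length(true_values) < 50 &&
                           length(false_values) < 50)
}

#' Read a two-column peak list
#'
#' @param path TSV/whitespace-delimited file with m/z and intensity columns
#'   (header optional; comment lines start with \code{#}).
#' @return A [Spectrum-class].
#' @export
readPeakList <- function(path) {
    d <- utils::read.table(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
    if (!is.numeric(d[[1]])) d <- d[-1, , drop = FALSE] # header line
    Spectrum(as.numeric(d[[1]]), as.numeric(d[[2]]))
}

#' Read spectra from an MGF file
#'
#' Minimal reader for BEGIN IONS / END IONS blocks; KEY=VALUE header lines
#' inside a block become attributes of the returned element.
#'
#' @param path Path to an MGF file.
#' @return Named list of [Spectrum-class] objects (named by TITLE when
#'   present).
#' @export
readMgf <- function(path) {
    lines <- readLines(path)
    starts <- which(lines == "BEGIN IONS")
    ends <- which(lines == "END IONS")
    if (length(starts) != length(ends) || any(ends < starts)) {
        stop("malformed MGF file: ", path)
    }
    out <- vector("list", length(starts))
    nms <- character(length(starts))
    for (k in seq_along(starts)) {
        block <- lines[(starts[k] + 1L):(ends[k] - 1L)]
        hdr <- grepl("=", block, fixed = TRUE)
        peaksl <- strsplit(trimws(block[!hdr]), "[ \t]+")
        mz <- as.numeric(vapply(peaksl, `[`, character(1), 1L))
        int <- as.numeric(vapply(peaksl, `[`, character(1), 2L))
        out[[k]] <- Spectrum(mz, int)
        title <- sub("^TITLE=", "", grep("^TITLE=", block[hdr], value = TRUE))
        nms[k] <- if (length(title)) title[1] else sprintf("spectrum_%d", k)
    }
    stats::setNames(out, nms)
}
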