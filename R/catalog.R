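#' Load a human/mouse ortholog symbol map
#'
#' Reads a two-column tab-delimited file (human symbol, mouse symbol). A
#' header line is detected and skipped when its first field is
#' \code{human_symbol}. Duplicated human symbols keep the first mapping with a
#' warning.
#'
#' @param path Path to the TSV file.
#' @return Named character vector mapping human symbol to mouse symbol.
#' @export
loadOrthologMap <- function(path) {
    if (!file.exists(path)) stop("ortholog map not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines) == 0L) stop("empty ortholog map: ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 2L)) {
        stop("malformed ortholog map line ", which(nf < 2L)[1],
             " (expected 2 tab-separated columns)")
    }
    human <- vapply(fields, `[`, character(1), 1L)
    mouse <- vapply(fields, `[`, character(1), 2L)
    if (human[1] %in% c("human_symbol", "human")) {
        human <- human[-1]; mouse <- mouse[-1]
    }
    dup <- duplicated(human)
    if (any(dup)) {
        warning(sum(dup), " duplicated human symbol(s); first mapping kept")
        human <- human[!dup]; mouse <- mouse[!dup]
    }
    stats::setNames(mouse, human)
}

# hamming distance between equal-length strings; returns Inf for unequal
.hamming <- function(a, b) {
    if (nchar(a) != nchar(b)) return(Inf)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Apply a single-residue substitution to a peptide
#'
#' @param peptide Amino-acid string.
#' @param site 1-based position.
#' @param to_aa Replacement residue (may be \code{"X"}).
#' @return The substituted peptide.
#' @export
applySaav <- function(peptide, site, to_aa) {
    stopifnot(site >= 1L, site <= nchar(peptide))
    paste0(substr(peptide, 1L, site - 1L), to_aa,
           substr(peptide, site + 1L, nchar(peptide)))
}

#' Pair cognate human/mouse peptides differing at exactly one residue
#'
#' For every orthologous gene pair, all combinations of one human and one
#' mouse tryptic peptide of equal length at Hamming distance exactly 1 are
#' emitted as cognate pairs carrying their SAAV (human-to-mouse orientation),
#' deduplicated on the peptide pair. Genes absent from one species are skipped
#' (counted in a message).
#'
#' @param peptide_index Gene-keyed peptide index from [digestProteome()],
#'   containing both species.
#' @param ortholog_map Named vector human symbol -> mouse symbol, as from
#'   [loadOrthologMap()].
#' @param mass_table Residue mass table.
#' @param category_map Biochemical category map.
#' @return A [CognatePairSet-class].
#' @export
findCognatePairs <- function(peptide_index, ortholog_map,
                             mass_table = aaMassTable(),
                             category_map = biochemCategories()) {
    hu <- peptide_index[peptide_index$species == "human", , drop = FALSE]
    mo <- peptide_index[peptide_index$species == "mouse", , drop = FALSE]
    hu_by_gene <- split(hu$peptide, hu$gene_symbol)
    mo_by_gene <- split(mo$peptide, mo$gene_symbol)
    n_missing <- 0L
    res <- vector("list", length(ortholog_map))
    for (i in seq_along(ortholog_map)) {
        hsym <- names(ortholog_map)[i]
        msym <- unname(ortholog_map[i])
        hp <- unique(hu_by_gene[[hsym]])
        mp <- unique(mo_by_gene[[msym]])
        if (is.null(hp) || is.null(mp)) {
            n_missing <- n_missing + 1L
            next
        }
        # compare only equal-length peptides
        hl <- nchar(hp); ml <- nchar(mp)
        hits <- list(); nh <- 0L
        for (len in intersect(unique(hl), unique(ml))) {
            hs <- hp[hl == len]
            ms <- mp[ml == len]
            hmat <- do.call(rbind, strsplit(hs, ""))
            mmat <- do.call(rbind, strsplit(ms, ""))
            for (a in seq_along(hs)) {
                diffs <- mmat != matrix(hmat[a, ], nrow(mmat), len,
                                        byrow = TRUE)
                nd <- rowSums(diffs)
                for (b in which(nd == 1L)) {
                    nh <- nh + 1L
                    hits[[nh]] <- c(hs[a], ms[b],
                                    which(diffs[b, ])[1])
                }
            }
        }
        if (nh == 0L) next
        hmem <- vapply(hits, `[`, character(1), 1L)
        mmem <- vapply(hits, `[`, character(1), 2L)
        site <- as.integer(vapply(hits, `[`, character(1), 3L))
        res[[i]] <- data.frame(
            gene_symbol = hsym, human_peptide = hmem, mouse_peptide = mmem,
            site = site, stringsAsFactors = FALSE
        )
    }
    if (n_missing > 0L) {
        message(n_missing, " ortholog pair(s) absent from one species, skipped")
    }
    pairs <- do.call(rbind, res)
    if (is.null(pairs)) {
        pairs <- data.frame(gene_symbol = character(0),
                            human_peptide = character(0),
                            mouse_peptide = character(0), site = integer(0),
                            stringsAsFactors = FALSE)
    }
    pairs <- pairs[!duplicated(paste(pairs$human_peptide,
                                     pairs$mouse_peptide)), , drop = FALSE]
    pairs$from_aa <- substr(pairs$human_peptide, pairs$site, pairs$site)
    pairs$to_aa <- substr(pairs$mouse_peptide, pairs$site, pairs$site)
    if (nrow(pairs)) {
        pairs$delta_mass <- saavMassShift(pairs$from_aa, pairs$to_aa,
                                          mass_table)
        pairs$same_category <- classifySubstitution(pairs$from_aa,
                                                    pairs$to_aa, category_map)
    } else {
        pairs$delta_mass <- numeric(0)
        pairs$same_category <- logical(0)
    }
    rownames(pairs) <- NULL
    CognatePairSet(pairs)
}

#' Census of SAAV frequencies
#'
#' Counts ordered substitutions, ranked descending (ties broken
#' lexicographically on from/to), and flags each as within- or
#' across-category. Accepts either a [CognatePairSet-class] (counting distinct
#' peptide pairs) or any data.frame with \code{from_aa}/\code{to_aa} columns,
#' e.g. a mutation-derived substitution list.
#'
#' @param x CognatePairSet or data.frame of substitutions.
#' @param top_n Keep the top n rows (default all).
#' @param weighting \code{"pair_instances"} counts every row;
#'   \code{"unique_types"} counts each ordered substitution once.
#' @param category_map Biochemical category map.
#' @return data.frame with columns \code{from_aa}, \code{to_aa}, \code{count},
#'   \code{same_category}, ranked by descending count.
#' @export
saavCensus <- function(x, top_n = Inf,
                       weighting = c("pair_instances", "unique_types"),
                       category_map = biochemCategories()) {
    weighting <- match.arg(weighting)
    if (is(x, "CognatePairSet")) x <- pairsTable(x)
    stopifnot(all(c("from_aa", "to_aa") %in% colnames(x)))
    if (nrow(x) == 0L) {
        return(data.frame(from_aa = character(0), to_aa = character(0),
                          count = integer(0), same_category = logical(0)))
    }
    key <- paste(x$from_aa, x$to_aa, sep = ">")
    tab <- table(key)
    if (weighting == "unique_types") tab[] <- 1L
    parts <- strsplit(names(tab), ">", fixed = TRUE)
    out <- data.frame(
        from_aa = vapply(parts, `[`, character(1), 1L),
        to_aa = vapply(parts, `[`, character(1), 2L),
        count = as.integer(tab),
        stringsAsFactors = FALSE
    )
    out$same_category <- classifySubstitution(out$from_aa, out$to_aa,
                                              category_map)
    out <- out[order(-out$count, out$from_aa, out$to_aa), ]
    rownames(out) <- NULL
    utils::head(out, top_n)
}
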