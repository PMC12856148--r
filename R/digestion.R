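#' Read a protein FASTA file into protein records
#'
#' Reads a (possibly gzipped) protein FASTA and extracts a gene symbol from
#' each header with a configurable regular expression. Sequences are
#' uppercased; entries containing letters outside the 20 standard amino acids
#' are retained but flagged non-digestible.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @param species Species label for all records, \code{"human"} or
#'   \code{"mouse"}.
#' @param symbol_pattern Regular expression with one capture group extracting
#'   the gene symbol from the header line. The default matches the
#'   \code{GN=SYMBOL} dialect; use e.g. \code{"^[^|]*\\\\|[^|]*\\\\|([^| ]+)"}
#'   for bar-delimited headers.
#' @return data.frame with columns \code{accession}, \code{gene_symbol},
#'   \code{species}, \code{sequence}, \code{digestible}.
#' @export
readProteomeFasta <- function(path, species = c("human", "mouse"),
                              symbol_pattern = "GN=([^ ]+)") {
    species <- match.arg(species)
    if (!file.exists(path)) {
        stop("FASTA file not found: ", path)
    }
    seqs <- Biostrings::readAAStringSet(path)
    if (length(seqs) == 0L) {
        stop("empty FASTA file: ", path)
    }
    headers <- names(seqs)
    accession <- sub("\\s.*$", "", headers)
    m <- regexec(symbol_pattern, headers)
    symbol <- vapply(regmatches(headers, m), function(g) {
        if (length(g) >= 2L) g[2L] else NA_character_
    }, character(1))
    sequence <- toupper(as.character(seqs))
    standard <- paste(names(aaMassTable()), collapse = "")
    digestible <- !grepl(sprintf("[^%s]", standard), sequence)
    if (anyDuplicated(accession)) {
        stop("duplicated accessions in ", path, ": ",
             paste(unique(accession[duplicated(accession)]), collapse = ", "))
    }
    data.frame(
        accession = accession, gene_symbol = symbol, species = species,
        sequence = sequence, digestible = digestible,
        stringsAsFactors = FALSE
    )
}

# cleavage indicator: cut[i] is TRUE when the bond after residue i is cleaved
# (trypsin: after K/R, not before P)
.trypticCuts <- function(residues) {
    n <- length(residues)
    if (n == 0L) return(logical(0))
    after_kr <- residues %in% c("K", "R")
    before_p <- c(residues[-1] == "P", FALSE)
    cuts <- after_kr & !before_p
    cuts[n] <- FALSE # C-terminus is a boundary, not a cut
    cuts
}

#' In silico tryptic digestion of one protein sequence
#'
#' Cleaves after K or R except when followed by P, allows up to
#' \code{max_missed} missed cleavages, and keeps peptides whose length falls
#' in \code{[min_len, max_len]} (the length filter is applied after
#' enumeration, as search engines do).
#'
#' @param sequence Protein sequence over the 20 standard amino acids.
#' @param max_missed Maximum internal missed cleavage sites (default 2).
#' @param min_len,max_len Peptide length bounds (defaults 6 and 61).
#' @return data.frame with columns \code{peptide}, \code{start} (1-based
#'   position in the protein), \code{missed_cleavages}.
#' @examples
#' digestProtein("AAAAAAKPGGGGGGRTTTTTTK")
#' @export
digestProtein <- function(sequence, max_missed = 2L, min_len = 6L,
                          max_len = 61L) {
    residues <- strsplit(sequence, "")[[1]]
    standard <- names(aaMassTable())
    bad <- which(!(residues %in% standard))
    if (length(bad) > 0L) {
        stop(sprintf("non-standard residue '%s' at position %d",
                     residues[bad[1]], bad[1]))
    }
    n <- length(residues)
    cuts <- .trypticCuts(residues)
    # fully cleaved units delimited by cut positions
    ends <- c(which(cuts), n)
    starts <- c(1L, head(ends, -1L) + 1L)
    k <- length(starts)
    out_pep <- character(0)
    out_start <- integer(0)
    out_mc <- integer(0)
    for (i in seq_len(k)) {
        for (mc in 0:max_missed) {
            j <- i + mc
            if (j > k) break
            len <- ends[j] - starts[i] + 1L
            if (len < min_len || len > max_len) next
            out_pep <- c(out_pep,
                         substr(sequence, starts[i], ends[j]))
            out_start <- c(out_start, starts[i])
            out_mc <- c(out_mc, mc)
        }
    }
    data.frame(peptide = out_pep, start = out_start,
               missed_cleavages = out_mc, stringsAsFactors = FALSE)
}

#' Digest a proteome into a gene-keyed peptide index
#'
#' Digests every digestible protein record and unions peptides per
#' (species, gene symbol) across isoforms, deduplicating by sequence. Records
#' flagged non-digestible (non-standard letters) or lacking a gene symbol are
#' skipped; their count is reported in a message.
#'
#' @param records data.frame from [readProteomeFasta()] (possibly several
#'   species rbound together).
#' @param max_missed,min_len,max_len Digestion parameters, see
#'   [digestProtein()].
#' @return data.frame with columns \code{species}, \code{gene_symbol},
#'   \code{peptide}, \code{missed_cleavages}, \code{parents}
#'   (comma-separated accessions carrying the peptide).
#' @export
digestProteome <- function(records, max_missed = 2L, min_len = 6L,
                           max_len = 61L) {
    stopifnot(is.data.frame(records), nrow(records) > 0L)
    usable <- records$digestible & !is.na(records$gene_symbol)
    n_skip <- sum(!usable)
    if (n_skip > 0L) {
        message(n_skip, " record(s) skipped (non-digestible or no gene symbol)")
    }
    records <- records[usable, , drop = FALSE]
    per_record <- lapply(seq_len(nrow(records)), function(i) {
        d <- digestProtein(records$sequence[i], max_missed, min_len, max_len)
        if (nrow(d) == 0L) return(NULL)
        data.frame(
            species = records$species[i],
            gene_symbol = records$gene_symbol[i],
            peptide = d$peptide,
            missed_cleavages = d$missed_cleavages,
            accession = records$accession[i],
            stringsAsFactors = FALSE
        )
    })
    all <- do.call(rbind, per_record)
    if (is.null(all)) {
        return(data.frame(species = character(0), gene_symbol = character(0),
                          peptide = character(0),
                          missed_cleavages = integer(0),
                          parents = character(0), stringsAsFactors = FALSE))
    }
    key <- paste(all$species, all$gene_symbol, all$peptide, sep = "\r")
    idx <- split(seq_len(nrow(all)), key)
    first <- vapply(idx, `[`, integer(1), 1L)
    parents <- vapply(idx, function(ii) {
        paste(sort(unique(all$accession[ii])), collapse = ",")
    }, character(1))
    out <- all[first, c("species", "gene_symbol", "peptide",
                        "missed_cleavages")]
    out$parents <- parents
    out <- out[order(out$species, out$gene_symbol, out$peptide), ]
    rownames(out) <- NULL
    out
}
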