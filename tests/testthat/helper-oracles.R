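# Independent oracles used by unit and acceptance tests. These deliberately
# take a different route from the implementation: digestion is checked by
# exhaustive substring enumeration, SAAV assignment by scoring the full
# uncollapsed ordered-pair universe.

# every substring of `sequence` whose boundaries are tryptic cleavage points
# (or the termini), with at most max_missed internal cleavage points and
# length within [min_len, max_len]
bruteDigest <- function(sequence, max_missed = 2L, min_len = 6L,
                        max_len = 61L) {
    res <- strsplit(sequence, "")[[1]]
    n <- length(res)
    # cut[i]: the bond after residue i is cleaved
    cut <- res %in% c("K", "R") & c(res[-1] != "P", FALSE)
    cut[n] <- FALSE
    ncuts <- cumsum(cut)
    out <- character(0)
    starts <- integer(0)
    mcs <- integer(0)
    for (s in seq_len(n)) {
        if (s > 1L && !cut[s - 1L]) next
        for (e in s:n) {
            len <- e - s + 1L
            if (len > max_len) break
            if (e < n && !cut[e]) next
            internal <- ncuts[max(e - 1L, 1L)] -
                (if (s > 1L) ncuts[s - 1L] else 0L)
            if (e == s) internal <- 0L
            if (internal > max_missed) break
            if (len < min_len) next
            out <- c(out, substr(sequence, s, e))
            starts <- c(starts, s)
            mcs <- c(mcs, internal)
        }
    }
    data.frame(peptide = out, start = starts, missed_cleavages = mcs,
               stringsAsFactors = FALSE)
}

# exhaustive three-criterion scorer over the uncollapsed 380 ordered residue
# pairs (mass-silent I/L interchanges excluded); destination collapsed to 'X'
# only when reporting
bruteAssign <- function(peptide, delta_mass, site, tolerance = 0.1,
                        tie_eps = 1e-4) {
    tab <- aaMassTable()
    aas <- names(tab)
    pairs <- expand.grid(from = aas, to = aas, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to, ]
    pairs$shift <- unname(tab[pairs$to] - tab[pairs$from])
    pairs <- pairs[abs(pairs$shift) > 1e-6, ]
    d <- abs(delta_mass - pairs$shift)
    if (min(d) >= tolerance) {
        return(list(accepted = FALSE, reason = "no_pair_within_tolerance"))
    }
    tie <- pairs[d <= min(d) + tie_eps, ]
    base <- substr(peptide, site, site)
    hit <- tie[tie$from == base, ]
    if (nrow(hit) == 0L) {
        return(list(accepted = FALSE, reason = "origin_mismatch"))
    }
    to <- unique(ifelse(hit$to %in% c("I", "L"), "X", hit$to))
    if (length(to) > 1L) {
        return(list(accepted = FALSE, reason = "ambiguous"))
    }
    list(accepted = TRUE, from = base, to = to)
}

# random peptide over the standard alphabet
randomPeptide <- function(len) {
    paste(sample(names(aaMassTable()), len, replace = TRUE), collapse = "")
}

# random protein sequence with tryptic sites
randomProtein <- function(len) {
    p <- rep(0.8 / 18, 20)
    names(p) <- names(aaMassTable())
    p[c("K", "R")] <- 0.10
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

# 95% binomial check: is observed count k out of n consistent with rate p?
withinBinomialCI <- function(k, n, p) {
    abs(k / n - p) <= 1.96 * sqrt(p * (1 - p) / n)
}

# small fixture: a peptide index + ortholog map with known cognate pairs
tinyCatalogFixture <- function() {
    idx <- data.frame(
        species = c("human", "human", "mouse", "mouse"),
        gene_symbol = c("ALB", "TTN", "Alb", "Ttn"),
        peptide = c("VLDELTK", "AAAAGGK", "ILDELTK", "AAAAGGK"),
        missed_cleavages = 0L,
        parents = c("h1", "h2", "m1", "m2"),
        stringsAsFactors = FALSE
    )
    map <- c(ALB = "Alb", TTN = "Ttn")
    findCognatePairs(idx, map)
}
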