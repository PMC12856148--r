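#' Does a variant peptide equal a database peptide up to I/L ambiguity?
#'
#' An \code{'X'} in the variant peptide matches I or L at the same position;
#' all other positions must match exactly.
#'
#' @param variant,reference Character vectors of equal-length peptides.
#' @return Logical vector.
#' @keywords internal
.peptideMatchesIL <- function(variant, reference) {
    same_len <- nchar(variant) == nchar(reference)
    out <- logical(length(variant))
    for (i in which(same_len)) {
        v <- strsplit(variant[i], "")[[1]]
        r <- strsplit(reference[i], "")[[1]]
        ok <- v == r | (v == "X" & r %in% c("I", "L"))
        out[i] <- all(ok)
    }
    out
}

#' Match candidate SAAV PSMs to a gold standard
#'
#' A candidate is a true positive iff its (sample, spectrum) key appears in
#' the gold standard and its variant peptide equals the gold mouse peptide
#' under I/L ambiguity ('X' at the variant site matches I or L; every other
#' position exact). Matching is PSM-level: the right peptide on the wrong
#' spectrum does not count.
#'
#' @param candidates data.frame of accepted candidates from [assignSaav()]
#'   (columns \code{sample_id}, \code{spectrum_id}, \code{variant_peptide}).
#' @param gold A [GoldStandard-class].
#' @return Logical vector along rows of \code{candidates}.
#' @export
matchCandidatesToGold <- function(candidates, gold) {
    k <- goldKeys(gold)
    if (nrow(candidates) == 0L) return(logical(0))
    gold_pep <- split(k$peptide, paste(k$sample_id, k$spectrum_id,
                                       sep = "\r"))
    ckey <- paste(candidates$sample_id, candidates$spectrum_id, sep = "\r")
    vapply(seq_len(nrow(candidates)), function(i) {
        peps <- gold_pep[[ckey[i]]]
        if (is.null(peps)) return(FALSE)
        any(.peptideMatchesIL(rep(candidates$variant_peptide[i],
                                  length(peps)), peps))
    }, logical(1))
}

#' F1 score
#'
#' Harmonic mean of precision and sensitivity:
#' F1 = 2 * precision * sensitivity / (precision + sensitivity); 0 when both
#' inputs are 0.
#'
#' @param precision,sensitivity Fractions in \code{[0, 1]} (vectorised; NA
#'   propagates).
#' @return Numeric vector.
#' @export
f1Score <- function(precision, sensitivity) {
    ok <- is.na(precision) | is.na(sensitivity) |
        (precision >= 0 & precision <= 1 & sensitivity >= 0 &
             sensitivity <= 1)
    if (!all(ok)) stop("precision and sensitivity must lie in [0, 1]")
    denom <- precision + sensitivity
    ifelse(!is.na(denom) & denom == 0, 0,
           2 * precision * sensitivity / denom)
}

#' PSM-level precision, sensitivity and F1 for one sample
#'
#' Sensitivity is the fraction of gold PSMs recovered; precision the fraction
#' of candidate PSMs that are true positives. In mixed-gold mode the
#' sensitivity denominator is the intersection gold standard (strict ground
#' truth) and the precision denominator uses the union gold standard
#' (inclusive ground truth); in single mode both arguments are the same set.
#' Empty denominators yield NA, never 0/0 = 0.
#'
#' @param candidates Accepted candidate data.frame (one sample's rows or all;
#'   filtered by \code{sample_id}).
#' @param gold_for_sensitivity,gold_for_precision [GoldStandard-class]
#'   objects.
#' @param sample_id Sample to score.
#' @return One-row data.frame: \code{sample_id}, \code{gold_mode},
#'   \code{n_gold}, \code{n_candidates}, \code{n_true_positive},
#'   \code{precision}, \code{sensitivity}, \code{f1}.
#' @export
computeMetrics <- function(candidates, gold_for_sensitivity,
                           gold_for_precision = gold_for_sensitivity,
                           sample_id) {
    single <- identical(goldKeys(gold_for_sensitivity),
                        goldKeys(gold_for_precision))
    cand <- candidates[candidates$sample_id == sample_id, , drop = FALSE]
    cand <- cand[!duplicated(paste(cand$spectrum_id, cand$variant_peptide)),
                 , drop = FALSE]
    gs <- goldKeys(gold_for_sensitivity)
    gs <- gs[gs$sample_id == sample_id, , drop = FALSE]
    gp <- goldKeys(gold_for_precision)
    gp <- gp[gp$sample_id == sample_id, , drop = FALSE]
    tp_sens <- sum(matchCandidatesToGold(cand,
                                         GoldStandard(gs, "sens")))
    tp_prec <- sum(matchCandidatesToGold(cand,
                                         GoldStandard(gp, "prec")))
    sens <- if (nrow(gs) == 0L) NA_real_ else tp_sens / nrow(gs)
    prec <- if (nrow(cand) == 0L) NA_real_ else tp_prec / nrow(cand)
    data.frame(
        sample_id = sample_id,
        gold_mode = if (single) "single" else "mixed",
        n_gold = nrow(gs), n_candidates = nrow(cand),
        n_true_positive = tp_sens,
        precision = prec, sensitivity = sens,
        f1 = f1Score(prec, sens),
        stringsAsFactors = FALSE
    )
}

#' Per-sample metrics over all samples, with a median summary
#'
#' @inheritParams computeMetrics
#' @param sample_ids Samples to score (default: union of samples seen in
#'   candidates and gold).
#' @return data.frame of per-sample metrics (one row per sample).
#' @export
computeMetricsPerSample <- function(candidates, gold_for_sensitivity,
                                    gold_for_precision = gold_for_sensitivity,
                                    sample_ids = NULL) {
    if (is.null(sample_ids)) {
        sample_ids <- sort(unique(c(candidates$sample_id,
                                    goldKeys(gold_for_sensitivity)$sample_id)))
    }
    do.call(rbind, lapply(sample_ids, function(s) {
        computeMetrics(candidates, gold_for_sensitivity, gold_for_precision,
                       s)
    }))
}

#' Per-SAAV stratified metrics
#'
#' Sensitivity per substitution type is computed over gold PSMs whose true
#' SAAV (from the cognate catalog annotation) is that type; precision per
#' type over candidates calling that type. Types with neither candidates nor
#' gold are omitted. Gold destinations I/L are collapsed to 'X' so that
#' mass-based calls are comparable.
#'
#' @param candidates Accepted candidate data.frame (with \code{from_aa},
#'   \code{to_aa}).
#' @param gold A [GoldStandard-class].
#' @param pairs A [CognatePairSet-class] used to annotate gold keys with their
#'   true SAAV.
#' @return data.frame with per-SAAV \code{n_gold}, \code{n_candidates},
#'   \code{n_true_positive}, \code{precision}, \code{sensitivity}.
#' @export
stratifyBySaav <- function(candidates, gold, pairs) {
    k <- goldKeys(gold)
    pt <- pairsTable(pairs)
    saav_of <- split(paste(pt$from_aa,
                           ifelse(pt$to_aa %in% c("I", "L"), "X", pt$to_aa),
                           sep = ">"),
                     pt$mouse_peptide)
    # a mouse peptide can occur in several pairs; annotate with its first SAAV
    k$true_saav <- vapply(k$peptide, function(p) {
        s <- saav_of[[p]]
        if (is.null(s)) NA_character_ else s[1]
    }, character(1), USE.NAMES = FALSE)
    k <- k[!is.na(k$true_saav), , drop = FALSE]
    cand <- candidates[candidates$accepted, , drop = FALSE]
    cand$called_saav <- paste(cand$from_aa, cand$to_aa, sep = ">")
    cand$tp <- matchCandidatesToGold(cand, gold)
    types <- sort(unique(c(k$true_saav, cand$called_saav)))
    out <- do.call(rbind, lapply(types, function(s) {
        g <- k[k$true_saav == s, , drop = FALSE]
        cc <- cand[cand$called_saav == s, , drop = FALSE]
        n_tp_sens <- sum(matchCandidatesToGold(
            cand[cand$tp, , drop = FALSE],
            GoldStandard(g, "strat")))
        data.frame(
            saav = s, n_gold = nrow(g), n_candidates = nrow(cc),
            n_true_positive = sum(cc$tp),
            precision = if (nrow(cc)) sum(cc$tp) / nrow(cc) else NA_real_,
            sensitivity = if (nrow(g)) n_tp_sens / nrow(g) else NA_real_,
            stringsAsFactors = FALSE
        )
    }))
    rownames(out) <- NULL
    out
}

#' Combine candidate sets across tools
#'
#' Candidates are keyed by (sample, spectrum, variant peptide with 'X'
#' normalising I/L). Union keeps keys present in any tool, intersection keys
#' present in every tool; duplicates collapse to one row carrying the
#' per-tool provenance list in \code{tools}.
#'
#' @param candidate_sets Named list (>= 2) of accepted candidate data.frames.
#' @param mode \code{"union"} or \code{"intersection"}.
#' @return Combined candidate data.frame with a \code{tools} column.
#' @export
combineToolCandidates <- function(candidate_sets,
                                  mode = c("union", "intersection")) {
    mode <- match.arg(mode)
    stopifnot(length(candidate_sets) >= 2L)
    norm_pep <- function(p) chartr("IL", "XX", p)
    keyed <- lapply(candidate_sets, function(df) {
        df$.key <- paste(df$sample_id, df$spectrum_id,
                         norm_pep(df$variant_peptide), sep = "\r")
        df[!duplicated(df$.key), , drop = FALSE]
    })
    all_rows <- do.call(rbind, lapply(names(keyed), function(tl) {
        d <- keyed[[tl]]
        d$.tool <- tl
        d
    }))
    tool_of <- split(all_rows$.tool, all_rows$.key)
    keep_keys <- if (mode == "union") {
        names(tool_of)
    } else {
        names(tool_of)[lengths(tool_of) == length(candidate_sets)]
    }
    first <- all_rows[!duplicated(all_rows$.key), , drop = FALSE]
    out <- first[first$.key %in% keep_keys, , drop = FALSE]
    out$tools <- vapply(tool_of[out$.key], paste, character(1),
                        collapse = ",")
    out$.key <- NULL
    out$.tool <- NULL
    rownames(out) <- NULL
    out
}

#' Cross-tabulate called versus true SAAVs among false candidates
#'
#' Diagnoses systematic misassignment (e.g. a preset-PTM closed search
#' absorbing every +CH2 variant as D>E): false candidates are joined to the
#' gold truth on (sample, spectrum) and tabulated by (called SAAV, true
#' SAAV), with the difference between the two theoretical mass shifts per
#' cell. A near-zero shift difference with a differing site indicates
#' mislocalization rather than a mass error.
#'
#' @param false_candidates Candidate rows that are not true positives, on
#'   spectra present in the gold standard.
#' @param gold_truth data.frame of gold keys annotated with \code{from_aa},
#'   \code{to_aa}, \code{site} of the true SAAV (e.g. from the simulator's
#'   truth table or a catalog join).
#' @param mass_table Residue mass table.
#' @return data.frame with \code{called_saav}, \code{true_saav},
#'   \code{count}, \code{delta_shift} (Da).
#' @export
misassignmentCensus <- function(false_candidates, gold_truth,
                                mass_table = aaMassTable()) {
    if (nrow(false_candidates) == 0L) {
        return(data.frame(called_saav = character(0),
                          true_saav = character(0), count = integer(0),
                          delta_shift = numeric(0)))
    }
    gkey <- paste(gold_truth$sample_id, gold_truth$spectrum_id, sep = "\r")
    ckey <- paste(false_candidates$sample_id, false_candidates$spectrum_id,
                  sep = "\r")
    idx <- match(ckey, gkey)
    hit <- !is.na(idx)
    fc <- false_candidates[hit, , drop = FALSE]
    gt <- gold_truth[idx[hit], , drop = FALSE]
    collapse_x <- function(aa) ifelse(aa %in% c("I", "L"), "X", aa)
    called <- paste(fc$from_aa, fc$to_aa, sep = ">")
    true <- paste(gt$from_aa, collapse_x(gt$to_aa), sep = ">")
    cell <- paste(called, true, sep = "\r")
    tab <- table(cell)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    out <- data.frame(
        called_saav = vapply(parts, `[`, character(1), 1L),
        true_saav = vapply(parts, `[`, character(1), 2L),
        count = as.integer(tab), stringsAsFactors = FALSE
    )
    shift_of <- function(s) {
        fa <- sub(">.*", "", s)
        ta <- sub(".*>", "", s)
        saavMassShift(fa, ta, mass_table)
    }
    out$delta_shift <- shift_of(out$called_saav) - shift_of(out$true_saav)
    out <- out[order(-out$count), ]
    rownames(out) <- NULL
    out
}

#' Rank-sum comparison of per-sample metric vectors between tools
#'
#' Two-sided Wilcoxon rank-sum test by default, as used to compare tools'
#' per-sample precision or sensitivity distributions.
#'
#' @param metric_a,metric_b Numeric vectors of per-sample metric values (NA
#'   dropped).
#' @param alternative Passed to [stats::wilcox.test()].
#' @return The \code{htest} object.
#' @export
compareToolMetrics <- function(metric_a, metric_b,
                               alternative = "two.sided") {
    stats::wilcox.test(metric_a[!is.na(metric_a)], metric_b[!is.na(metric_b)],
                       alternative = alternative, exact = FALSE)
}
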