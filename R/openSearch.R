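.PSM_MANDATORY <- c("sample_id", "spectrum_id", "tool", "peptide")
.PSM_OPTIONAL <- c("charge", "delta_mass", "site", "site_probability",
                   "retention_time", "score", "preassigned_from",
                   "preassigned_to")

# column maps: normalized name -> native header, per engine dialect
.psmDialects <- function() {
    list(
        generic = NULL, # already in normalized schema
        msfragger_open = c(
            sample_id = "sample", spectrum_id = "spectrum",
            tool = NA, peptide = "peptide", charge = "charge",
            delta_mass = "massdiff", site = "best_site",
            site_probability = "localization_prob",
            retention_time = "retention", score = "hyperscore"
        ),
        maxquant_dp = c(
            sample_id = "Raw file", spectrum_id = "Scan number",
            tool = NA, peptide = "Base sequence", charge = "Charge",
            delta_mass = "Mass difference", site = "DP position",
            site_probability = "DP probability",
            retention_time = "Retention time", score = "DP score"
        ),
        openpfind = c(
            sample_id = "sample", spectrum_id = "File_Name",
            tool = NA, peptide = "Sequence", charge = "Charge",
            delta_mass = "Mass_Shift", site = "Mod_Site",
            site_probability = NA, retention_time = "RT",
            score = "Final_Score", preassigned_from = "SAAV_From",
            preassigned_to = "SAAV_To"
        )
    )
}

#' Normalize an open- or closed-search PSM table
#'
#' Reads a tab-delimited PSM table and maps the engine's native columns onto
#' the normalized schema (\code{sample_id}, \code{spectrum_id}, \code{tool},
#' \code{peptide}, plus optional \code{charge}, \code{delta_mass},
#' \code{site}, \code{site_probability}, \code{retention_time}, \code{score},
#' \code{preassigned_from}, \code{preassigned_to}). Rows missing a mandatory
#' field are dropped with a message. Open-pFind rows may carry a pre-assigned
#' SAAV, which is preserved and flagged in \code{preassigned}.
#'
#' @param path Path to a TSV file (lines starting with \code{#} are skipped).
#' @param dialect One of \code{"generic"}, \code{"msfragger_open"},
#'   \code{"maxquant_dp"}, \code{"openpfind"}.
#' @param tool Tool label stored in the \code{tool} column; defaults to the
#'   dialect name.
#' @return data.frame in the normalized PSM schema.
#' @export
normalizePsmTable <- function(path, dialect = "generic", tool = dialect) {
    dialects <- .psmDialects()
    if (!dialect %in% names(dialects)) {
        stop("unknown dialect '", dialect, "'; available: ",
             paste(names(dialects), collapse = ", "))
    }
    raw <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                             stringsAsFactors = FALSE)
    map <- dialects[[dialect]]
    if (is.null(map)) {
        out <- raw
    } else {
        out <- data.frame(row.names = seq_len(nrow(raw)))
        for (norm in names(map)) {
            native <- map[[norm]]
            if (is.na(native)) next
            if (native %in% colnames(raw)) out[[norm]] <- raw[[native]]
        }
    }
    miss <- setdiff(.PSM_MANDATORY, c(colnames(out), "tool"))
    if (length(miss)) {
        stop("mandatory column(s) absent after mapping: ",
             paste(miss, collapse = ", "))
    }
    if (!"tool" %in% colnames(out) || all(is.na(out$tool))) out$tool <- tool
    for (col in .PSM_OPTIONAL) if (!col %in% colnames(out)) out[[col]] <- NA
    complete <- !Reduce(`|`, lapply(.PSM_MANDATORY, function(c) {
        is.na(out[[c]]) | out[[c]] == ""
    }))
    if (any(!complete)) {
        message(sum(!complete), " row(s) dropped (missing mandatory fields)")
    }
    out <- out[complete, c(.PSM_MANDATORY, .PSM_OPTIONAL), drop = FALSE]
    for (col in c("charge", "site")) out[[col]] <- as.integer(out[[col]])
    for (col in c("delta_mass", "site_probability", "retention_time",
                  "score")) {
        out[[col]] <- as.numeric(out[[col]])
    }
    out$preassigned <- !is.na(out$preassigned_from) &
        !is.na(out$preassigned_to)
    rownames(out) <- NULL
    out
}

#' Filter PSMs to confidently localized mass shifts
#'
#' @param psms Normalized PSM data.frame.
#' @param tool_policy \code{"maxquant_dp"}: keep rows with exactly one
#'   localized site whose probability is strictly greater than 0.5;
#'   \code{"msfragger"}: keep rows whose localization resolves to exactly one
#'   site (non-missing \code{site}, and \code{ambiguous} column FALSE when
#'   present); \code{"generic"}: keep rows with a non-missing site.
#' @return Filtered data.frame.
#' @export
filterLocalizedPsms <- function(psms,
                                tool_policy = c("generic", "maxquant_dp",
                                                "msfragger")) {
    tool_policy <- match.arg(tool_policy)
    has_site <- !is.na(psms$site)
    keep <- switch(tool_policy,
        generic = has_site,
        maxquant_dp = has_site & !is.na(psms$site_probability) &
            psms$site_probability > 0.5,
        msfragger = has_site & if ("ambiguous" %in% colnames(psms)) {
            !isTRUE_vec(psms$ambiguous)
        } else TRUE
    )
    psms[keep, , drop = FALSE]
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Assign SAAVs to mass-shift PSMs by the three-criterion rule
#'
#' For each PSM carrying an open-search mass shift and a localized site, the
#' observed shift is compared with every theoretical amino-acid substitution
#' (ordered pairs, destinations Leu/Ile collapsed to the ambiguity class
#' \code{'X'}). A PSM is assigned an SAAV when all of: (1) the candidate
#' substitution's shift is nearest to the observed shift among all theoretical
#' pairs, (2) that absolute difference is strictly less than \code{tolerance},
#' and (3) the substitution's origin residue equals the base-peptide residue
#' at the localized site. Rejected PSMs carry a reason
#' (\code{no_pair_within_tolerance}, \code{origin_mismatch}, or
#' \code{ambiguous}) and are excluded from downstream candidacy.
#'
#' Substitutions that are chemically identical elemental changes (e.g. the
#' +CH2 family G>A, S>T, V>X, D>E, N>Q) have equal shifts and are treated as a
#' tie set; criterion (3) then selects the member whose origin matches the
#' base sequence. Rows with a pre-assigned SAAV (Open-pFind) bypass the
#' nearest-shift search but are still validated against criterion (3).
#'
#' @param psms Normalized PSM data.frame with \code{delta_mass} and
#'   \code{site}.
#' @param mass_table Residue mass table.
#' @param tolerance Maximum absolute difference between observed and
#'   theoretical shift in Da (default 0.1, strict comparison).
#' @return data.frame: input columns plus \code{from_aa}, \code{to_aa},
#'   \code{theoretical_shift}, \code{delta_delta_mass},
#'   \code{variant_peptide}, \code{accepted}, \code{reject_reason}.
#' @export
assignSaav <- function(psms, mass_table = aaMassTable(), tolerance = 0.1) {
    stopifnot(is.data.frame(psms))
    if (any(is.na(psms$delta_mass))) stop("PSM rows without delta_mass")
    if (any(is.na(psms$site))) stop("PSM rows without a localized site")
    if (any(psms$site < 1L | psms$site > nchar(psms$peptide))) {
        stop("localized site outside the peptide for some row(s)")
    }
    universe <- saavShiftTable(mass_table)
    n <- nrow(psms)
    from <- to <- rep(NA_character_, n)
    theo <- ddm <- rep(NA_real_, n)
    reason <- rep(NA_character_, n)
    base_res <- substr(psms$peptide, psms$site, psms$site)
    pre <- if ("preassigned" %in% colnames(psms)) {
        isTRUE_vec(psms$preassigned)
    } else rep(FALSE, n)
    # |observed - theoretical| for every (row, universe entry)
    absdiff <- abs(outer(psms$delta_mass, universe$delta_mass, `-`))
    for (i in seq_len(n)) {
        if (pre[i]) {
            # pre-assigned SAAV: validate origin only (criterion 3)
            if (psms$preassigned_from[i] != base_res[i]) {
                reason[i] <- "origin_mismatch"
            } else {
                from[i] <- psms$preassigned_from[i]
                to_i <- psms$preassigned_to[i]
                to[i] <- if (to_i %in% c("I", "L")) "X" else to_i
                theo[i] <- saavMassShift(from[i], to[i], mass_table)
                ddm[i] <- abs(psms$delta_mass[i] - theo[i])
            }
            next
        }
        d <- absdiff[i, ]
        dmin <- min(d)
        if (dmin >= tolerance) {
            reason[i] <- "no_pair_within_tolerance"
            next
        }
        # ties: chemically identical shifts are equal up to constant rounding
        tie <- which(d <= dmin + 1e-4)
        hit <- tie[universe$from_aa[tie] == base_res[i]]
        if (length(hit) == 0L) {
            reason[i] <- "origin_mismatch"
        } else if (length(hit) > 1L) {
            reason[i] <- "ambiguous"
        } else {
            from[i] <- universe$from_aa[hit]
            to[i] <- universe$to_aa[hit]
            theo[i] <- universe$delta_mass[hit]
            ddm[i] <- d[hit]
        }
    }
    out <- psms
    out$from_aa <- from
    out$to_aa <- to
    out$theoretical_shift <- theo
    out$delta_delta_mass <- ddm
    out$accepted <- is.na(reason)
    out$reject_reason <- ifelse(is.na(reason), "", reason)
    out$variant_peptide <- NA_character_
    acc <- which(out$accepted)
    if (length(acc)) {
        out$variant_peptide[acc] <- mapply(applySaav, out$peptide[acc],
                                           out$site[acc], out$to_aa[acc],
                                           USE.NAMES = FALSE)
    }
    # post-hoc assertion of the acceptance contract (pre-assigned SAAVs are
    # taken on trust for the mass criterion, origin is still enforced)
    acc_search <- setdiff(acc, which(pre))
    stopifnot(all(out$delta_delta_mass[acc_search] < tolerance),
              all(out$from_aa[acc] == base_res[acc]))
    out
}
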