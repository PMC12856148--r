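## Seeded RNG handle threaded explicitly through all simulator functions:
## draws happen inside withRng(), which swaps the handle's state into R's RNG
## and captures it back, so the caller's global RNG is left untouched.

#' Create an explicit random-number-generator handle
#' @param seed Integer seed.
#' @return An opaque RNG handle (environment holding the generator state).
#' @export
newRng <- function(seed) {
    rng <- new.env(parent = emptyenv())
    old <- .globalSeedGet()
    set.seed(seed)
    rng$state <- .globalSeedGet()
    .globalSeedSet(old)
    rng
}

.globalSeedGet <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        get(".Random.seed", envir = globalenv())
    } else NULL
}

.globalSeedSet <- function(state) {
    if (is.null(state)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
            rm(".Random.seed", envir = globalenv())
        }
    } else {
        assign(".Random.seed", state, envir = globalenv())
    }
}

#' Evaluate an expression under an RNG handle
#' @param rng Handle from [newRng()].
#' @param expr Expression drawing random numbers.
#' @return The value of \code{expr}.
#' @export
withRng <- function(rng, expr) {
    old <- .globalSeedGet()
    .globalSeedSet(rng$state)
    on.exit({
        rng$state <- .globalSeedGet()
        .globalSeedSet(old)
    })
    expr
}

#' Simulation configuration
#'
#' Parameters of the synthetic benchmark. Defaults describe the emulated
#' study conditions: a mixed-species PSM population with a 30% mouse
#' fraction, two imperfect closed-search tools agreeing on 67% of gold PSMs,
#' and an open search detecting half of the gold PSMs with small
#' mislocalization and mass-error rates.
#'
#' @param n_genes Number of orthologous genes.
#' @param protein_length_mean,protein_length_sd Protein length distribution
#'   (residues).
#' @param saav_rate Per-residue human-to-mouse substitution probability.
#' @param same_category_bias Probability that an injected substitution stays
#'   within its biochemical category.
#' @param mouse_psm_fraction Fraction of closed-search PSMs drawn from mouse
#'   (SAAV-bearing) peptides.
#' @param n_psms_per_sample,n_samples Closed-search PSMs per sample and
#'   number of samples.
#' @param tool_overlap Probability a gold PSM is reported by both simulated
#'   closed-search tools (otherwise exactly one, chosen uniformly).
#' @param detection_rate Probability the open search emits a candidate for a
#'   gold PSM.
#' @param misloc_rate Probability a detected candidate's site is moved to a
#'   uniformly chosen other position.
#' @param wrong_shift_rate Probability a detected candidate's mass shift is
#'   offset by a uniform 0.2-2.0 Da error of random sign.
#' @param background_rate Probability a human-only PSM spawns a spurious
#'   candidate (random site, mass shift of a random origin-matching SAAV).
#' @param rt_noise_sd Gaussian noise on observed retention times (minutes).
#' @param intensity_jitter_sd Multiplicative intensity jitter on experimental
#'   spectra.
#' @param rt_a,rt_b Slope/intercept of the hydrophobicity retention model.
#' @param seed Integer seed; identical config and seed give identical output.
#' @return A \code{saav_sim_config} list.
#' @export
simConfig <- function(n_genes = 200L,
                      protein_length_mean = 300,
                      protein_length_sd = 60,
                      saav_rate = 0.05,
                      same_category_bias = 0.575,
                      mouse_psm_fraction = 0.30,
                      n_psms_per_sample = 5000L,
                      n_samples = 4L,
                      tool_overlap = 0.672,
                      detection_rate = 0.5,
                      misloc_rate = 0.15,
                      wrong_shift_rate = 0.05,
                      background_rate = 0.05,
                      rt_noise_sd = 0.5,
                      intensity_jitter_sd = 0.1,
                      rt_a = 1.5, rt_b = 30,
                      seed = 1L) {
    cfg <- list(
        n_genes = as.integer(n_genes),
        protein_length_mean = protein_length_mean,
        protein_length_sd = protein_length_sd,
        saav_rate = saav_rate, same_category_bias = same_category_bias,
        mouse_psm_fraction = mouse_psm_fraction,
        n_psms_per_sample = as.integer(n_psms_per_sample),
        n_samples = as.integer(n_samples), tool_overlap = tool_overlap,
        detection_rate = detection_rate, misloc_rate = misloc_rate,
        wrong_shift_rate = wrong_shift_rate,
        background_rate = background_rate, rt_noise_sd = rt_noise_sd,
        intensity_jitter_sd = intensity_jitter_sd,
        rt_a = rt_a, rt_b = rt_b, seed = as.integer(seed)
    )
    rates <- c("saav_rate", "same_category_bias", "mouse_psm_fraction",
               "tool_overlap", "detection_rate", "misloc_rate",
               "wrong_shift_rate", "background_rate")
    for (r in rates) {
        if (cfg[[r]] < 0 || cfg[[r]] > 1) stop(r, " must lie in [0, 1]")
    }
    if (cfg$n_genes < 1L || cfg$n_psms_per_sample < 1L || cfg$n_samples < 1L) {
        stop("counts must be positive")
    }
    if (cfg$protein_length_mean < 6) {
        stop("mean protein length below the minimum peptide length")
    }
    class(cfg) <- "saav_sim_config"
    cfg
}

# residue sampling frequencies: K/R enriched to 10% each so tryptic peptides
# of in-range length are common; remaining mass spread uniformly
.residueFreqs <- function() {
    aas <- names(aaMassTable())
    p <- stats::setNames(rep(0.8 / 18, 20), aas)
    p[c("K", "R")] <- 0.10
    p
}

#' Generate a pair of ortholog proteomes with injected SAAVs
#'
#' Human proteins are sampled with tryptic-site-rich residue frequencies;
#' each mouse ortholog is a copy with independent per-residue substitutions
#' at \code{saav_rate}. The destination residue is drawn within the origin's
#' biochemical category with probability \code{same_category_bias}, otherwise
#' uniformly among residues of other categories, so the realized
#' within-category fraction matches the bias. Substitutions are injected only
#' where they preserve tryptic boundaries and are visible to mass-based
#' calling (no K/R/P or H on the origin side, no K/R/P destinations, no
#' mass-silent I/L interchange); see the methods vignette. A ledger records
#' every injected substitution.
#'
#' @param config A [simConfig()] object.
#' @param rng RNG handle from [newRng()]; defaults to a fresh handle seeded
#'   from \code{config$seed}.
#' @return list with \code{human} and \code{mouse} protein record
#'   data.frames, \code{ortholog_map} (named vector), and \code{ledger}
#'   data.frame (gene, position, from, to, same_category).
#' @export
simulateOrthologProteomes <- function(config, rng = newRng(config$seed)) {
    stopifnot(inherits(config, "saav_sim_config"))
    freqs <- .residueFreqs()
    aas <- names(freqs)
    cats <- biochemCategories()
    # Injected substitutions are restricted to tryptic-context-preserving,
    # mass-visible variants: K/R/P on either side would change cleavage
    # boundaries (so the variant peptide no longer pairs with its cognate),
    # H's only category partners are K/R, and I<->L swaps carry no mass
    # shift. Excluding these keeps catalog selection independent of the
    # biochemical category, so the configured bias propagates unchanged.
    blocked <- c("K", "R", "P")
    subst_origins <- setdiff(aas, c(blocked, "H"))
    same_cat_opts <- lapply(stats::setNames(subst_origins, subst_origins),
                            function(a) {
        opts <- setdiff(aas[cats[aas] == cats[[a]]], c(a, blocked))
        if (a %in% c("I", "L")) opts <- setdiff(opts, c("I", "L"))
        opts
    })
    diff_cat_opts <- lapply(stats::setNames(subst_origins, subst_origins),
                            function(a) {
        setdiff(aas[cats[aas] != cats[[a]]], blocked)
    })
    withRng(rng, {
        n <- config$n_genes
        lens <- pmax(30L, as.integer(round(stats::rnorm(
            n, config$protein_length_mean, config$protein_length_sd))))
        hsym <- sprintf("GENE%04d", seq_len(n))
        msym <- paste0("Gene", sprintf("%04d", seq_len(n)))
        human_seq <- character(n)
        mouse_seq <- character(n)
        ledger <- vector("list", n)
        for (g in seq_len(n)) {
            res <- sample(aas, lens[g], replace = TRUE, prob = freqs)
            mres <- res
            hit <- which(stats::runif(lens[g]) < config$saav_rate &
                             res %in% subst_origins)
            if (length(hit)) {
                same <- stats::runif(length(hit)) < config$same_category_bias
                dest <- character(length(hit))
                for (k in seq_along(hit)) {
                    opts <- if (same[k]) same_cat_opts[[res[hit[k]]]] else
                        diff_cat_opts[[res[hit[k]]]]
                    dest[k] <- opts[sample.int(length(opts), 1L)]
                }
                mres[hit] <- dest
                ledger[[g]] <- data.frame(
                    gene = hsym[g], position = hit, from = res[hit],
                    to = dest, same_category = same, stringsAsFactors = FALSE
                )
            }
            human_seq[g] <- paste(res, collapse = "")
            mouse_seq[g] <- paste(mres, collapse = "")
        }
        ledger <- do.call(rbind, ledger)
        if (is.null(ledger)) {
            ledger <- data.frame(gene = character(0), position = integer(0),
                                 from = character(0), to = character(0),
                                 same_category = logical(0))
        }
        list(
            human = data.frame(
                accession = paste0("HUM_", hsym), gene_symbol = hsym,
                species = "human", sequence = human_seq, digestible = TRUE,
                stringsAsFactors = FALSE),
            mouse = data.frame(
                accession = paste0("MUS_", msym), gene_symbol = msym,
                species = "mouse", sequence = mouse_seq, digestible = TRUE,
                stringsAsFactors = FALSE),
            ortholog_map = stats::setNames(msym, hsym),
            ledger = ledger
        )
    })
}

#' Simulate closed-search PSM tables for two imperfect tools
#'
#' Each sample receives \code{n_psms_per_sample} spectra: a spectrum is
#' assigned a catalog mouse peptide (one cognate pair drawn uniformly) with
#' probability \code{mouse_psm_fraction}, otherwise a uniform human peptide.
#' Every PSM is reported by both tools with probability \code{tool_overlap},
#' else by exactly one (uniformly). Truth labels mark the mouse-SAAV gold
#' PSMs and their true substitution.
#'
#' @param pairs A [CognatePairSet-class] (non-empty).
#' @param peptide_index Peptide index from [digestProteome()] (for the human
#'   background peptide pool).
#' @param config A [simConfig()] object.
#' @param rng RNG handle.
#' @return list with per-tool PSM data.frames \code{psms_a}, \code{psms_b}
#'   (normalized schema) and a \code{truth} data.frame.
#' @export
simulateClosedSearchPsms <- function(pairs, peptide_index, config,
                                     rng = newRng(config$seed)) {
    pt <- pairsTable(pairs)
    if (nrow(pt) == 0L) stop("empty cognate catalog")
    human_pool <- unique(
        peptide_index$peptide[peptide_index$species == "human"])
    withRng(rng, {
        per_sample <- lapply(seq_len(config$n_samples), function(s) {
            sid <- sprintf("S%02d", s)
            n <- config$n_psms_per_sample
            is_mouse <- stats::runif(n) < config$mouse_psm_fraction
            pair_idx <- ifelse(is_mouse,
                               sample.int(nrow(pt), n, replace = TRUE),
                               NA_integer_)
            peptide <- ifelse(is_mouse, pt$mouse_peptide[pair_idx],
                              sample(human_pool, n, replace = TRUE))
            both <- stats::runif(n) < config$tool_overlap
            in_a <- both | stats::runif(n) < 0.5
            in_b <- both | !in_a
            data.frame(
                sample_id = sid, spectrum_id = sprintf("sp%06d", seq_len(n)),
                peptide = peptide, species = ifelse(is_mouse, "mouse",
                                                    "human"),
                is_gold = is_mouse, pair_idx = pair_idx,
                in_tool_a = in_a, in_tool_b = in_b,
                score = round(stats::runif(n, 10, 100), 3),
                stringsAsFactors = FALSE
            )
        })
        truth <- do.call(rbind, per_sample)
        truth$human_peptide <- ifelse(truth$is_gold,
                                      pt$human_peptide[truth$pair_idx], NA)
        truth$site <- ifelse(truth$is_gold, pt$site[truth$pair_idx], NA)
        truth$from_aa <- ifelse(truth$is_gold, pt$from_aa[truth$pair_idx],
                                NA)
        truth$to_aa <- ifelse(truth$is_gold, pt$to_aa[truth$pair_idx], NA)
        truth$delta_mass <- ifelse(truth$is_gold,
                                   pt$delta_mass[truth$pair_idx], NA)
        as_psms <- function(keep, tool) {
            d <- truth[keep, c("sample_id", "spectrum_id", "peptide",
                               "score"), drop = FALSE]
            d$tool <- tool
            rownames(d) <- NULL
            d[, c("sample_id", "spectrum_id", "tool", "peptide", "score")]
        }
        list(
            psms_a = as_psms(truth$in_tool_a, "tool_a"),
            psms_b = as_psms(truth$in_tool_b, "tool_b"),
            truth = truth
        )
    })
}

#' Simulate open-search candidate PSMs with controlled error modes
#'
#' Every gold PSM is detected with probability \code{detection_rate}; a
#' detected PSM is emitted with the human cognate as base peptide, the true
#' SAAV mass shift and the true site, then corrupted: with probability
#' \code{misloc_rate} the site moves to a uniformly chosen other position,
#' and with probability \code{wrong_shift_rate} the shift is offset by a
#' uniform 0.2-2.0 Da error of random sign. Each human-only PSM additionally
#' spawns a spurious candidate with probability \code{background_rate}
#' (uniform site, mass shift of a uniformly chosen SAAV whose origin matches
#' the residue there). Labels record ground truth per emitted row.
#'
#' @param truth Truth table from [simulateClosedSearchPsms()].
#' @param config A [simConfig()] object.
#' @param rng RNG handle.
#' @param tool Tool label for the emitted rows.
#' @param mass_table Residue mass table.
#' @return list: \code{psms} (normalized candidate-side PSM table),
#'   \code{labels} (row-parallel: \code{origin} gold/background,
#'   \code{corruption}, \code{correct}, \code{true_peptide}), and
#'   \code{realized} counts (n_gold, n_detected, n_correct).
#' @export
simulateOpenSearchPsms <- function(truth, config, rng = newRng(config$seed),
                                   tool = "open", mass_table = aaMassTable()) {
    universe <- saavShiftTable(mass_table)
    by_origin <- split(seq_len(nrow(universe)), universe$from_aa)
    withRng(rng, {
        gold <- truth[truth$is_gold, , drop = FALSE]
        detected <- stats::runif(nrow(gold)) < config$detection_rate
        g <- gold[detected, , drop = FALSE]
        ng <- nrow(g)
        site <- g$site
        dm <- g$delta_mass
        misloc <- stats::runif(ng) < config$misloc_rate
        wrong <- stats::runif(ng) < config$wrong_shift_rate
        len <- nchar(g$human_peptide)
        for (i in which(misloc)) {
            others <- setdiff(seq_len(len[i]), g$site[i])
            site[i] <- others[sample.int(length(others), 1L)]
        }
        dm[wrong] <- dm[wrong] +
            sample(c(-1, 1), sum(wrong), replace = TRUE) *
            stats::runif(sum(wrong), 0.2, 2.0)
        gold_rows <- data.frame(
            sample_id = g$sample_id, spectrum_id = g$spectrum_id,
            tool = rep(tool, ng), peptide = g$human_peptide,
            charge = rep(2L, ng), delta_mass = dm, site = site,
            site_probability = round(stats::runif(ng, 0.6, 1), 4),
            retention_time = rep(NA_real_, ng),
            score = round(stats::runif(ng, 10, 100), 3),
            preassigned_from = rep(NA_character_, ng),
            preassigned_to = rep(NA_character_, ng),
            preassigned = rep(FALSE, ng), stringsAsFactors = FALSE
        )
        gold_labels <- data.frame(
            sample_id = g$sample_id, spectrum_id = g$spectrum_id,
            origin = rep("gold", ng),
            corruption = ifelse(misloc & wrong, "both",
                                ifelse(misloc, "misloc",
                                       ifelse(wrong, "wrong_shift", "none"))),
            correct = !misloc & !wrong,
            true_peptide = g$peptide, stringsAsFactors = FALSE
        )
        hum <- truth[!truth$is_gold, , drop = FALSE]
        spawn <- stats::runif(nrow(hum)) < config$background_rate
        h <- hum[spawn, , drop = FALSE]
        nh <- nrow(h)
        bsite <- integer(nh)
        bfrom <- character(nh)
        bto <- character(nh)
        bdm <- numeric(nh)
        keep <- logical(nh)
        for (i in seq_len(nh)) {
            li <- nchar(h$peptide[i])
            bsite[i] <- sample.int(li, 1L)
            bfrom[i] <- substr(h$peptide[i], bsite[i], bsite[i])
            opts <- by_origin[[bfrom[i]]]
            if (is.null(opts)) next
            pick <- opts[sample.int(length(opts), 1L)]
            bto[i] <- universe$to_aa[pick]
            bdm[i] <- universe$delta_mass[pick]
            keep[i] <- TRUE
        }
        nk <- sum(keep)
        bg_rows <- data.frame(
            sample_id = h$sample_id[keep], spectrum_id = h$spectrum_id[keep],
            tool = rep(tool, nk), peptide = h$peptide[keep],
            charge = rep(2L, nk), delta_mass = bdm[keep], site = bsite[keep],
            site_probability = round(stats::runif(nk, 0.6, 1), 4),
            retention_time = rep(NA_real_, nk),
            score = round(stats::runif(nk, 10, 100), 3),
            preassigned_from = rep(NA_character_, nk),
            preassigned_to = rep(NA_character_, nk),
            preassigned = rep(FALSE, nk), stringsAsFactors = FALSE
        )
        bg_labels <- data.frame(
            sample_id = h$sample_id[keep], spectrum_id = h$spectrum_id[keep],
            origin = rep("background", nk), corruption = rep("spurious", nk),
            correct = rep(FALSE, nk), true_peptide = h$peptide[keep],
            stringsAsFactors = FALSE
        )
        list(
            psms = rbind(gold_rows, bg_rows),
            labels = rbind(gold_labels, bg_labels),
            realized = list(
                n_gold = nrow(gold), n_detected = ng,
                n_correct = sum(gold_labels$correct)
            )
        )
    })
}

#' Attach simulated retention times and stick spectra to candidate rows
#'
#' Predicted values derive from the called variant peptide; observed values
#' follow the true peptide (plus noise/jitter). For incorrect candidates the
#' two disagree, creating the separation the quality metrics must detect.
#'
#' @param candidates Accepted candidate rows from [assignSaav()] (needs
#'   \code{variant_peptide}).
#' @param labels Label table from [simulateOpenSearchPsms()] providing
#'   \code{true_peptide} per (sample, spectrum).
#' @param config A [simConfig()] object.
#' @param rng RNG handle.
#' @param keep_spectra Keep the Spectrum objects in list columns.
#' @return \code{candidates} with added columns \code{retention_time},
#'   \code{rt_predicted}, \code{rt_delta}, \code{spectral_angle} (and
#'   optionally \code{exp_spectrum}, \code{pred_spectrum}).
#' @export
simulateRtAndSpectra <- function(candidates, labels, config,
                                 rng = newRng(config$seed),
                                 keep_spectra = FALSE) {
    key <- function(d) paste(d$sample_id, d$spectrum_id, sep = "\r")
    idx <- match(key(candidates), key(labels))
    if (anyNA(idx)) stop("candidate rows without labels")
    true_pep <- labels$true_peptide[idx]
    # observed RT follows the true (mouse) peptide for gold spectra
    true_rt_pep <- ifelse(labels$origin[idx] == "gold", true_pep,
                          candidates$peptide)
    withRng(rng, {
        n <- nrow(candidates)
        rt_pred <- predictRetentionTime(candidates$variant_peptide,
                                        config$rt_a, config$rt_b)
        rt_obs <- predictRetentionTime(true_rt_pep, config$rt_a,
                                       config$rt_b) +
            stats::rnorm(n, 0, config$rt_noise_sd)
        sa <- numeric(n)
        exp_sp <- vector("list", n)
        pred_sp <- vector("list", n)
        for (i in seq_len(n)) {
            es <- predictFragmentMz(true_rt_pep[i])
            jit <- abs(1 + stats::rnorm(length(es),
                                        0, config$intensity_jitter_sd))
            es <- Spectrum(peaks(es)$mz, peaks(es)$intensity * jit)
            ps <- predictFragmentMz(candidates$variant_peptide[i])
            sa[i] <- spectralAngle(es, ps)
            if (keep_spectra) {
                exp_sp[[i]] <- es
                pred_sp[[i]] <- ps
            }
        }
        out <- candidates
        out$retention_time <- rt_obs
        out$rt_predicted <- rt_pred
        out$rt_delta <- rtDelta(rt_obs, rt_pred)
        out$spectral_angle <- sa
        if (keep_spectra) {
            out$exp_spectrum <- exp_sp
            out$pred_spectrum <- pred_sp
        }
        out
    })
}

#' Emulate a closed search with one preset SAAV as a variable modification
#'
#' A closed search told to look only for \code{from > to} (e.g. D>E) has no
#' competing explanation for other variants of near-identical mass shift: for
#' every gold PSM whose true shift lies within \code{tolerance} of the preset
#' shift, it reports the preset substitution at some \code{from} residue of
#' the human base peptide (the true site when the true SAAV is the preset
#' one, otherwise the first \code{from} position — a mislocalized call).
#' Gold PSMs whose base peptide lacks the residue are not identified.
#'
#' @param truth Truth table from [simulateClosedSearchPsms()].
#' @param from_aa,to_aa The preset substitution.
#' @param mass_table Residue mass table.
#' @param tolerance Mass window in Da within which the engine absorbs a
#'   variant into the preset modification (default 0.1).
#' @return Candidate-style data.frame (accepted rows with
#'   \code{variant_peptide}, \code{from_aa}, \code{to_aa}).
#' @export
simulatePresetSearchPsms <- function(truth, from_aa = "D", to_aa = "E",
                                     mass_table = aaMassTable(),
                                     tolerance = 0.1) {
    preset_shift <- saavMassShift(from_aa, to_aa, mass_table)
    gold <- truth[truth$is_gold, , drop = FALSE]
    near <- abs(gold$delta_mass - preset_shift) < tolerance
    g <- gold[near, , drop = FALSE]
    is_preset <- g$from_aa == from_aa &
        (g$to_aa == to_aa |
             (to_aa == "X" & g$to_aa %in% c("I", "L")))
    site <- integer(nrow(g))
    for (i in seq_len(nrow(g))) {
        if (is_preset[i]) {
            site[i] <- g$site[i]
        } else {
            pos <- gregexpr(from_aa, g$human_peptide[i],
                            fixed = TRUE)[[1]]
            site[i] <- if (pos[1] == -1L) NA_integer_ else pos[1]
        }
    }
    ok <- !is.na(site)
    g <- g[ok, , drop = FALSE]
    site <- site[ok]
    data.frame(
        sample_id = g$sample_id, spectrum_id = g$spectrum_id,
        tool = paste0("preset_", from_aa, to_aa),
        peptide = g$human_peptide, delta_mass = preset_shift, site = site,
        from_aa = from_aa, to_aa = to_aa,
        theoretical_shift = preset_shift, delta_delta_mass = 0,
        accepted = TRUE, reject_reason = "",
        variant_peptide = mapply(applySaav, g$human_peptide, site,
                                 to_aa, USE.NAMES = FALSE),
        stringsAsFactors = FALSE
    )
}

#' Write a complete synthetic fixture set for the pipeline
#'
#' Generates proteomes, catalog inputs, per-tool closed-search PSM tables,
#' open-search candidate tables and truth labels, writing them under
#' \code{dir} as FASTA/TSV plus the resolved configuration as JSON.
#'
#' @param config A [simConfig()] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of written file paths.
#' @export
simulateBenchmarkData <- function(config, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    rng <- newRng(config$seed)
    prot <- simulateOrthologProteomes(config, rng)
    idx <- digestProteome(rbind(prot$human, prot$mouse))
    pairs <- findCognatePairs(idx, prot$ortholog_map)
    closed <- simulateClosedSearchPsms(pairs, idx, config, rng)
    open <- simulateOpenSearchPsms(closed$truth, config, rng)
    paths <- c(
        human_fasta = file.path(dir, "human.fasta"),
        mouse_fasta = file.path(dir, "mouse.fasta"),
        ortholog_map = file.path(dir, "ortholog_map.tsv"),
        closed_a = file.path(dir, "closed_tool_a.tsv"),
        closed_b = file.path(dir, "closed_tool_b.tsv"),
        open_psms = file.path(dir, "open_candidates.tsv"),
        truth = file.path(dir, "truth_labels.tsv"),
        config = file.path(dir, "sim_config.json")
    )
    .writeFasta(prot$human, paths[["human_fasta"]])
    .writeFasta(prot$mouse, paths[["mouse_fasta"]])
    writeLines(paste(names(prot$ortholog_map), prot$ortholog_map,
                     sep = "\t"), paths[["ortholog_map"]])
    .writeTsv(closed$psms_a, paths[["closed_a"]])
    .writeTsv(closed$psms_b, paths[["closed_b"]])
    .writeTsv(open$psms, paths[["open_psms"]])
    .writeTsv(cbind(closed$truth["sample_id"],
                    closed$truth[setdiff(colnames(closed$truth),
                                         "sample_id")]),
              paths[["truth"]])
    jsonlite::write_json(unclass(config), paths[["config"]],
                         auto_unbox = TRUE, digits = NA)
    invisible(paths)
}

.writeFasta <- function(records, path) {
    seqs <- Biostrings::AAStringSet(records$sequence)
    names(seqs) <- paste0(records$accession, " GN=", records$gene_symbol)
    Biostrings::writeXStringSet(seqs, path)
}

.writeTsv <- function(df, path, header_comment = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(header_comment)) {
        writeLines(paste0("# ", header_comment), con)
    }
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
}
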