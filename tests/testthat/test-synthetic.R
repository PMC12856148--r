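test_that("simulation is deterministic under a fixed config and seed", {
    cfg <- simConfig(n_genes = 30, n_psms_per_sample = 300, n_samples = 2,
                     seed = 71)
    a <- simulateOrthologProteomes(cfg)
    b <- simulateOrthologProteomes(cfg)
    expect_identical(a, b)

    r1 <- runBenchmark(cfg, quality = FALSE)
    r2 <- runBenchmark(cfg, quality = FALSE)
    expect_identical(r1$summary, r2$summary)
    expect_identical(r1$metrics, r2$metrics)
})

test_that("the simulator leaves the caller's RNG state untouched", {
    set.seed(1234)
    before <- .Random.seed
    invisible(simulateOrthologProteomes(simConfig(n_genes = 10, seed = 5)))
    expect_identical(.Random.seed, before)
})

test_that("degenerate generator settings behave as contracted", {
    cfg0 <- simConfig(n_genes = 20, saav_rate = 0, seed = 72)
    p0 <- simulateOrthologProteomes(cfg0)
    expect_identical(p0$human$sequence, p0$mouse$sequence)
    expect_equal(nrow(p0$ledger), 0L)

    cfg1 <- simConfig(n_genes = 20, same_category_bias = 1, seed = 73)
    p1 <- simulateOrthologProteomes(cfg1)
    expect_true(all(classifySubstitution(p1$ledger$from, p1$ledger$to)))

    expect_error(simConfig(protein_length_mean = 4), "length")
    expect_error(simConfig(detection_rate = 1.5), "\\[0, 1\\]")
})

test_that("closed-search composition follows the configured rates", {
    cfg <- simConfig(n_genes = 60, n_psms_per_sample = 5000, n_samples = 1,
                     mouse_psm_fraction = 0.3, seed = 74)
    prot <- simulateOrthologProteomes(cfg)
    idx <- digestProteome(rbind(prot$human, prot$mouse))
    pairs <- findCognatePairs(idx, prot$ortholog_map)
    closed <- simulateClosedSearchPsms(pairs, idx, cfg)
    expect_true(withinBinomialCI(sum(closed$truth$is_gold),
                                 nrow(closed$truth), 0.3))
    # spectrum ids unique per sample
    expect_false(anyDuplicated(paste(closed$truth$sample_id,
                                     closed$truth$spectrum_id)) > 0)
    # every PSM lands in at least one tool
    expect_true(all(closed$truth$in_tool_a | closed$truth$in_tool_b))
})

test_that("full tool overlap makes intersection and union gold coincide", {
    cfg <- simConfig(n_genes = 40, n_psms_per_sample = 500, n_samples = 1,
                     tool_overlap = 1, seed = 75)
    res <- runBenchmark(cfg, quality = FALSE)
    expect_equal(goldKeys(res$gold$intersection), goldKeys(res$gold$union))
})

test_that("a zero mouse fraction gives empty gold standards downstream", {
    cfg <- simConfig(n_genes = 40, n_psms_per_sample = 300, n_samples = 1,
                     mouse_psm_fraction = 0, seed = 76)
    prot <- simulateOrthologProteomes(cfg)
    idx <- digestProteome(rbind(prot$human, prot$mouse))
    pairs <- findCognatePairs(idx, prot$ortholog_map)
    closed <- simulateClosedSearchPsms(pairs, idx, cfg)
    expect_warning(gs <- buildGoldStandard(closed$psms_a, pairs),
                   "no closed-search PSM")
    expect_equal(length(gs), 0L)
})

test_that("open-search detection matches the configured rate", {
    cfg <- simConfig(n_genes = 60, n_psms_per_sample = 4000, n_samples = 1,
                     detection_rate = 0.5, seed = 77)
    prot <- simulateOrthologProteomes(cfg)
    idx <- digestProteome(rbind(prot$human, prot$mouse))
    pairs <- findCognatePairs(idx, prot$ortholog_map)
    closed <- simulateClosedSearchPsms(pairs, idx, cfg)
    open <- simulateOpenSearchPsms(closed$truth, cfg)
    expect_gte(open$realized$n_gold, 1000)
    expect_true(withinBinomialCI(open$realized$n_detected,
                                 open$realized$n_gold, 0.5))
})

test_that("forced mislocalization never yields a correct accepted call", {
    cfg <- simConfig(n_genes = 40, n_psms_per_sample = 800, n_samples = 1,
                     detection_rate = 1, misloc_rate = 1,
                     background_rate = 0, wrong_shift_rate = 0, seed = 78)
    res <- runBenchmark(cfg, quality = FALSE)
    cand <- res$candidates$open_a
    tp <- matchCandidatesToGold(cand, res$gold$union)
    expect_equal(sum(tp), 0L)
})

test_that("fixture files are written and read back consistently", {
    dir <- withr::local_tempdir()
    cfg <- simConfig(n_genes = 20, n_psms_per_sample = 200, n_samples = 1,
                     seed = 79)
    paths <- simulateBenchmarkData(cfg, dir)
    expect_true(all(file.exists(paths)))

    rec <- readProteomeFasta(paths[["human_fasta"]], "human")
    expect_equal(nrow(rec), 20L)
    expect_false(any(is.na(rec$gene_symbol)))

    map <- loadOrthologMap(paths[["ortholog_map"]])
    expect_length(map, 20L)

    open <- normalizePsmTable(paths[["open_psms"]], "generic")
    expect_true(all(!is.na(open$delta_mass)))
    # round-trip: re-assignment on the written table works
    out <- assignSaav(filterLocalizedPsms(open, "generic"))
    expect_gt(sum(out$accepted), 0)
})
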