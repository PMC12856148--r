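test_that("ortholog map loading keeps first duplicate and validates lines", {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("ALB\tAlb", "TTN\tTtn", "ALB\tAlb2"), f)
    expect_warning(map <- loadOrthologMap(f), "duplicated")
    expect_equal(map[["ALB"]], "Alb")
    expect_length(map, 2L)

    bad <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("ALB\tAlb", "TTNonly"), bad)
    expect_error(loadOrthologMap(bad), "line 2")
})

test_that("SAAV mass shifts match the monoisotopic residue masses", {
    expect_equal(saavMassShift("D", "E"), 14.01565, tolerance = 1e-6)
    expect_equal(saavMassShift("I", "V"), -14.01565, tolerance = 1e-6)
    expect_equal(saavMassShift("N", "D"), 0.98402, tolerance = 1e-5)
    expect_equal(saavMassShift("V", "X"), saavMassShift("V", "L"))
    expect_error(saavMassShift("D", "Z"), "unknown")
})

test_that("mass shifts are antisymmetric over all ordered pairs", {
    aas <- names(aaMassTable())
    g <- expand.grid(a = aas, b = aas, stringsAsFactors = FALSE)
    g <- g[g$a != g$b, ]
    expect_equal(saavMassShift(g$a, g$b), -saavMassShift(g$b, g$a))
})

test_that("the shift universe collapses I/L destinations and drops silent swaps", {
    u <- saavShiftTable()
    expect_false(any(u$to_aa %in% c("I", "L")))
    expect_false(any(u$from_aa == "X"))
    expect_true(all(abs(u$delta_mass) > 1e-6))
    # one X entry per non-I/L origin
    x <- u[u$to_aa == "X", ]
    expect_setequal(x$from_aa, setdiff(names(aaMassTable()), c("I", "L")))
})

test_that("cognate pairing finds Hamming-1 equal-length peptide pairs", {
    pairs <- tinyCatalogFixture()
    pt <- pairsTable(pairs)
    expect_equal(nrow(pt), 1L) # AAAAGGK identical -> no pair
    expect_equal(pt$human_peptide, "VLDELTK")
    expect_equal(pt$mouse_peptide, "ILDELTK")
    expect_equal(pt$site, 1L)
    expect_equal(pt$from_aa, "V")
    expect_equal(pt$to_aa, "I")
    expect_equal(pt$delta_mass, 14.01565, tolerance = 1e-5)

    # Hamming distance 2 is rejected
    idx2 <- data.frame(
        species = c("human", "mouse"), gene_symbol = c("ALB", "Alb"),
        peptide = c("VLDELTK", "ILDEMTK"), missed_cleavages = 0L,
        parents = "x", stringsAsFactors = FALSE
    )
    expect_equal(length(findCognatePairs(idx2, c(ALB = "Alb"))), 0L)
})

test_that("applying the recorded SAAV to the human peptide gives the mouse one", {
    set.seed(21)
    cfg <- simConfig(n_genes = 40, seed = 21)
    prot <- simulateOrthologProteomes(cfg)
    idx <- digestProteome(rbind(prot$human, prot$mouse))
    pt <- pairsTable(findCognatePairs(idx, prot$ortholog_map))
    expect_gt(nrow(pt), 50)
    rebuilt <- mapply(applySaav, pt$human_peptide, pt$site, pt$to_aa,
                      USE.NAMES = FALSE)
    expect_identical(rebuilt, pt$mouse_peptide)
    # pairs pass the digestion length bounds
    expect_true(all(nchar(pt$human_peptide) >= 6 &
                        nchar(pt$human_peptide) <= 61))
})

test_that("SAAV census counts, ranks and classifies substitutions", {
    subs <- data.frame(
        from_aa = c("V", "V", "V", "D"),
        to_aa = c("I", "I", "I", "E"), stringsAsFactors = FALSE
    )
    cen <- saavCensus(subs, top_n = 2)
    expect_equal(cen$from_aa, c("V", "D"))
    expect_equal(cen$count, c(3L, 1L))
    expect_true(all(cen$same_category))

    expect_equal(nrow(saavCensus(data.frame(from_aa = character(0),
                                            to_aa = character(0)))), 0L)

    mixed <- data.frame(from_aa = c("V", "D"), to_aa = c("I", "K"))
    cen2 <- saavCensus(mixed)
    expect_equal(mean(cen2$same_category), 0.5)
    # census conservation under pair_instances weighting
    expect_equal(sum(saavCensus(subs)$count), nrow(subs))
    # unique_types collapses multiplicity
    expect_equal(saavCensus(subs, weighting = "unique_types")$count,
                 c(1L, 1L))
})

test_that("biochemical classification matches the standard scheme", {
    expect_true(classifySubstitution("Y", "F"))
    expect_true(classifySubstitution("M", "L"))
    expect_true(classifySubstitution("V", "X"))
    expect_false(classifySubstitution("D", "K"))
    expect_error(classifySubstitution("D", "Z"), "missing")
})

test_that("census same-category fraction recovers the injected bias", {
    beta <- 0.575
    cfg <- simConfig(n_genes = 250, saav_rate = 0.05,
                     same_category_bias = beta, seed = 31)
    prot <- simulateOrthologProteomes(cfg)
    idx <- digestProteome(rbind(prot$human, prot$mouse))
    pairs <- findCognatePairs(idx, prot$ortholog_map)
    cen <- saavCensus(pairs)
    n <- sum(cen$count)
    expect_gte(n, 2000)
    k <- sum(cen$count[cen$same_category])
    expect_true(withinBinomialCI(k, n, beta))
})
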