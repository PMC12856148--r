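candidateRow <- function(peptide, delta_mass, site) {
    data.frame(sample_id = "s1", spectrum_id = "sp1", tool = "open",
               peptide = peptide, delta_mass = delta_mass, site = site,
               stringsAsFactors = FALSE)
}

test_that("the +CH2 tie family is resolved by the origin residue", {
    # observed +14.0157 ties G>A, S>T, V>X, D>E, N>Q; site 9 is V
    out <- assignSaav(candidateRow("AKHPMDTEVTK", 14.0157, 9L))
    expect_true(out$accepted)
    expect_equal(out$from_aa, "V")
    expect_equal(out$to_aa, "X")
    expect_equal(out$variant_peptide, "AKHPMDTEXTK")

    # same shift at the M site: no tie member starts from M
    out2 <- assignSaav(candidateRow("AKHPMDTEVTK", 14.0157, 5L))
    expect_false(out2$accepted)
    expect_equal(out2$reject_reason, "origin_mismatch")
})

test_that("shifts far from every theoretical pair are rejected", {
    # N site, +0.50: nearest pair N>D at |delta| 0.484 >= 0.1
    out <- assignSaav(candidateRow("AAANAAK", 0.50, 4L))
    expect_false(out$accepted)
    expect_equal(out$reject_reason, "no_pair_within_tolerance")
})

test_that("exact matches are accepted", {
    out <- assignSaav(candidateRow("AAATAAK", -3.99492, 4L))
    expect_true(out$accepted)
    expect_equal(out$from_aa, "T")
    expect_equal(out$to_aa, "P")
    expect_lt(out$delta_delta_mass, 1e-4)
})

test_that("assignment agrees with the exhaustive ordered-pair oracle", {
    set.seed(51)
    n <- 800
    rows <- do.call(rbind, lapply(seq_len(n), function(i) {
        pep <- randomPeptide(sample(7:20, 1))
        # mix exact shifts, perturbed shifts, and uniform noise
        kind <- sample(3, 1)
        u <- saavShiftTable()
        dm <- switch(kind,
                     u$delta_mass[sample(nrow(u), 1)],
                     u$delta_mass[sample(nrow(u), 1)] +
                         stats::runif(1, -0.3, 0.3),
                     stats::runif(1, -90, 90))
        candidateRow(pep, dm, sample(nchar(pep), 1))
    }))
    rows$spectrum_id <- sprintf("sp%04d", seq_len(n))
    got <- assignSaav(rows)
    for (i in seq_len(n)) {
        want <- bruteAssign(rows$peptide[i], rows$delta_mass[i],
                            rows$site[i])
        expect_equal(got$accepted[i], want$accepted)
        if (want$accepted) {
            expect_equal(got$from_aa[i], want$from)
            expect_equal(got$to_aa[i], want$to)
        } else {
            expect_equal(got$reject_reason[i], want$reason)
        }
    }
})

test_that("every catalog SAAV round-trips at its exact theoretical shift", {
    pairs <- pairsTable(tinyCatalogFixture())
    cfg <- simConfig(n_genes = 30, seed = 52)
    prot <- simulateOrthologProteomes(cfg)
    idx <- digestProteome(rbind(prot$human, prot$mouse))
    pairs <- rbind(pairs, pairsTable(findCognatePairs(idx,
                                                      prot$ortholog_map)))
    # Ile/Leu interchanges carry no mass shift and are invisible to
    # mass-based calling; every other substitution must round-trip
    pairs <- pairs[!(pairs$from_aa %in% c("I", "L") &
                         pairs$to_aa %in% c("I", "L")), ]
    rows <- data.frame(
        sample_id = "s1", spectrum_id = sprintf("sp%05d", seq_len(nrow(pairs))),
        tool = "open", peptide = pairs$human_peptide,
        delta_mass = pairs$delta_mass, site = pairs$site,
        stringsAsFactors = FALSE
    )
    out <- assignSaav(rows)
    expect_true(all(out$accepted))
    expect_identical(out$from_aa, pairs$from_aa)
    expect_identical(out$to_aa,
                     ifelse(pairs$to_aa %in% c("I", "L"), "X", pairs$to_aa))
})

test_that("the accepted set grows monotonically with tolerance", {
    set.seed(53)
    rows <- do.call(rbind, lapply(1:200, function(i) {
        pep <- randomPeptide(10)
        candidateRow(pep, stats::runif(1, -60, 60), sample(10, 1))
    }))
    rows$spectrum_id <- sprintf("sp%04d", 1:200)
    acc <- lapply(c(0.02, 0.1, 0.5), function(tol) {
        o <- assignSaav(rows, tolerance = tol)
        o$spectrum_id[o$accepted]
    })
    expect_true(all(acc[[1]] %in% acc[[2]]))
    expect_true(all(acc[[2]] %in% acc[[3]]))
})

test_that("pre-assigned SAAVs bypass the search but keep the origin check", {
    rows <- candidateRow("AKHPMDTEVTK", 14.0157, 9L)
    rows$preassigned_from <- "V"
    rows$preassigned_to <- "I"
    rows$preassigned <- TRUE
    out <- assignSaav(rows)
    expect_true(out$accepted)
    expect_equal(out$to_aa, "X")

    rows$preassigned_from <- "D"
    out2 <- assignSaav(rows)
    expect_false(out2$accepted)
    expect_equal(out2$reject_reason, "origin_mismatch")
})

test_that("PSM table normalization maps dialects and validates columns", {
    f <- withr::local_tempfile(fileext = ".tsv")
    df <- data.frame(
        sample_id = c("s1", "s1", ""), spectrum_id = c("sp1", "sp2", "sp3"),
        tool = "open", peptide = c("AAAAAAK", "CCCCCCK", "DDDDDDK"),
        delta_mass = c(14.0157, NA, 1), site = c(3L, 5L, 1L),
        site_probability = c(0.9, 0.4, 0.8), stringsAsFactors = FALSE
    )
    write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_message(got <- normalizePsmTable(f, "generic"), "1 row")
    expect_equal(nrow(got), 2L) # empty sample_id row dropped
    expect_true(all(c("preassigned", "retention_time") %in% colnames(got)))

    expect_error(normalizePsmTable(f, "no_such_engine"), "available")

    f2 <- withr::local_tempfile(fileext = ".tsv")
    write.table(df[, -1], f2, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(normalizePsmTable(f2, "generic"), "sample_id")
})

test_that("localization filtering enforces the strict probability cutoff", {
    p <- data.frame(
        sample_id = "s1", spectrum_id = c("a", "b", "c"), tool = "t",
        peptide = "AAAAAAK", site = c(3L, 3L, NA),
        site_probability = c(0.51, 0.50, 0.9), stringsAsFactors = FALSE
    )
    kept <- filterLocalizedPsms(p, "maxquant_dp")
    expect_equal(kept$spectrum_id, "a") # 0.50 dropped: strictly greater
    expect_equal(nrow(filterLocalizedPsms(p, "generic")), 2L)

    p$ambiguous <- c(FALSE, TRUE, FALSE)
    expect_equal(filterLocalizedPsms(p, "msfragger")$spectrum_id, "a")
})
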