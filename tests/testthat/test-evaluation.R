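cand <- function(sample, spectrum, variant, from = "V", to = "X") {
    data.frame(sample_id = sample, spectrum_id = spectrum,
               variant_peptide = variant, from_aa = from, to_aa = to,
               accepted = TRUE, stringsAsFactors = FALSE)
}

gold1 <- GoldStandard(data.frame(sample_id = "s1", spectrum_id = "sp7",
                                 peptide = "AKHPMDTEITK"), "t")

test_that("candidate-gold matching is PSM-level with I/L ambiguity", {
    expect_true(matchCandidatesToGold(cand("s1", "sp7", "AKHPMDTEXTK"),
                                      gold1))
    expect_false(matchCandidatesToGold(cand("s1", "sp7", "AKHPMDTEKTK"),
                                       gold1))
    expect_false(matchCandidatesToGold(cand("s1", "sp8", "AKHPMDTEXTK"),
                                       gold1))
})

test_that("the F1 score is the harmonic mean with a 0/0 convention", {
    expect_equal(f1Score(0.5, 0.5), 0.5)
    expect_equal(f1Score(1, 0), 0)
    expect_equal(f1Score(0, 0), 0)
    expect_equal(f1Score(0.692, 0.483), 0.5689, tolerance = 1e-4)
    expect_error(f1Score(1.2, 0.5), "0, 1")
})

test_that("precision and sensitivity count overlaps against their own gold", {
    gold <- GoldStandard(data.frame(sample_id = "s1",
                                    spectrum_id = c("k1", "k2", "k3"),
                                    peptide = "AKHPMDTEITK"), "t")
    cands <- rbind(cand("s1", "k1", "AKHPMDTEXTK"),
                   cand("s1", "x1", "AAAAAAK"),
                   cand("s1", "x2", "CCCCCCK"))
    m <- computeMetrics(cands, gold, gold, "s1")
    expect_equal(m$precision, 1 / 3)
    expect_equal(m$sensitivity, 1 / 3)
    expect_equal(m$f1, 1 / 3)
    expect_equal(m$gold_mode, "single")

    perfect <- cand("s1", c("k1", "k2", "k3"), "AKHPMDTEXTK")
    mp <- computeMetrics(perfect, gold, gold, "s1")
    expect_equal(c(mp$precision, mp$sensitivity, mp$f1), c(1, 1, 1))

    none <- computeMetrics(cands[0, ], gold, gold, "s1")
    expect_true(is.na(none$precision))
    expect_equal(none$sensitivity, 0)
})

test_that("metrics are invariant under candidate duplication", {
    gold <- GoldStandard(data.frame(sample_id = "s1",
                                    spectrum_id = c("k1", "k2"),
                                    peptide = "AKHPMDTEITK"), "t")
    cands <- rbind(cand("s1", "k1", "AKHPMDTEXTK"),
                   cand("s1", "x1", "AAAAAAK"))
    m1 <- computeMetrics(cands, gold, gold, "s1")
    m2 <- computeMetrics(cands[c(1, 1, 2, 2, 1), ], gold, gold, "s1")
    expect_equal(m2$precision, m1$precision)
    expect_equal(m2$sensitivity, m1$sensitivity)
})

test_that("per-SAAV stratification partitions the true positives", {
    pairs <- tinyCatalogFixture() # V>I at site 1 of VLDELTK
    gold <- GoldStandard(data.frame(sample_id = "s1",
                                    spectrum_id = c("k1", "k2"),
                                    peptide = "ILDELTK"), "t")
    cands <- rbind(cand("s1", "k1", "XLDELTK", "V", "X"),
                   cand("s1", "k2", "VLDELTA", "K", "A"))
    strat <- stratifyBySaav(cands, gold, pairs)
    vx <- strat[strat$saav == "V>X", ]
    expect_equal(vx$precision, 1)
    expect_equal(vx$sensitivity, 0.5)
    ka <- strat[strat$saav == "K>A", ]
    expect_equal(ka$precision, 0)
    # partition: per-type TPs sum to overall TPs
    expect_equal(sum(strat$n_true_positive),
                 sum(matchCandidatesToGold(cands, gold)))
})

test_that("tool combination keys on sample, spectrum and I/L-free variant", {
    a <- cand("s1", c("k1", "k2"), c("AAAAXAK", "CCCCXCK"))
    b <- rbind(cand("s1", "k2", "CCCCICK"), # same variant up to I/L
               cand("s1", "k3", "DDDDXDK"))
    uni <- combineToolCandidates(list(A = a, B = b), "union")
    expect_equal(nrow(uni), 3L)
    inter <- combineToolCandidates(list(A = a, B = b), "intersection")
    expect_equal(inter$spectrum_id, "k2")
    expect_equal(inter$tools, "A,B")

    # same spectrum, genuinely different variants: not in the intersection
    b2 <- cand("s1", "k1", "AAAAWAK")
    expect_equal(nrow(combineToolCandidates(list(A = a[1, ], B = b2),
                                            "intersection")), 0L)
})

test_that("misassignment census reports shift differences per called/true cell", {
    truth <- data.frame(
        sample_id = "s1", spectrum_id = c("k1", "k2", "k3"),
        from_aa = c("V", "N", "V"), to_aa = c("I", "Q", "I"),
        site = c(2L, 3L, 4L), stringsAsFactors = FALSE
    )
    false_cands <- data.frame(
        sample_id = "s1", spectrum_id = c("k1", "k2", "k3"),
        from_aa = "D", to_aa = "E", site = 9L, stringsAsFactors = FALSE
    )
    cen <- misassignmentCensus(false_cands, truth)
    expect_setequal(cen$true_saav, c("V>X", "N>Q"))
    expect_equal(cen$count[cen$true_saav == "V>X"], 2L)
    expect_true(all(abs(cen$delta_shift) < 1e-5))

    empty <- misassignmentCensus(false_cands[0, ], truth)
    expect_equal(nrow(empty), 0L)
})

test_that("mixed-gold sensitivity uses the strict set and precision the union", {
    inter <- GoldStandard(data.frame(sample_id = "s1", spectrum_id = "k1",
                                     peptide = "AKHPMDTEITK"), "intersection")
    uni <- GoldStandard(data.frame(sample_id = "s1",
                                   spectrum_id = c("k1", "k2"),
                                   peptide = "AKHPMDTEITK"), "union")
    cands <- rbind(cand("s1", "k1", "AKHPMDTEXTK"),
                   cand("s1", "k2", "AKHPMDTEXTK"))
    m <- computeMetrics(cands, inter, uni, "s1")
    expect_equal(m$gold_mode, "mixed")
    expect_equal(m$sensitivity, 1) # 1 of 1 intersection keys
    expect_equal(m$precision, 1)  # both candidates in the union
    # against the union as sensitivity denominator the value can only drop
    m_union <- computeMetrics(cands, uni, uni, "s1")
    expect_lte(m_union$sensitivity, 1)
})
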