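test_that("generators are deterministic per seed and leave global RNG alone", {
    a <- simulateApms(nBackground = 30, nTrue = 2, seed = 9)
    b <- simulateApms(nBackground = 30, nTrue = 2, seed = 9)
    expect_identical(assay(a$experiment, "psm"), assay(b$experiment, "psm"))
    expect_identical(a$truth, b$truth)
    expect_false(identical(
        assay(simulateApms(nBackground = 30, nTrue = 2, seed = 10)$experiment,
              "psm"),
        assay(a$experiment, "psm")))
    e1 <- simulateExpression(nGenes = 10, nSamples = 20, seed = 4)
    e2 <- simulateExpression(nGenes = 10, nSamples = 20, seed = 4)
    expect_identical(assay(e1), assay(e2))
    d1 <- simulateDeTable(nGenes = 50, seed = 2)
    expect_identical(d1, simulateDeTable(nGenes = 50, seed = 2))
    o1 <- simulateOntology(overlapFracs = c(0.3, 0.1), seed = 6)
    expect_identical(o1, simulateOntology(overlapFracs = c(0.3, 0.1),
                                          seed = 6))
    # explicit seed is mandatory; global state untouched
    expect_error(simulateApms(nBackground = 5, nTrue = 1), "seed")
    withr::with_seed(123, {
        before <- .Random.seed
        invisible(simulateApms(nBackground = 5, nTrue = 1, seed = 1))
        expect_identical(.Random.seed, before)
    })
})

test_that("planted interactors are always recovered; stray calls come from background", {
    # pilot-derived guarantee of the strong-enrichment regime: perfect
    # sensitivity; rare extra calls are background proteins that happened
    # to match the weak-interactor signature
    for (s in 1:25) {
        sim <- simulateApms(seed = s)
        called <- calledPartners(callInteractors(sim$experiment,
                                                 bait = "DYRK1A"))
        expect_true(all(sim$truth$true_interactors %in% called),
                    info = paste("seed", s))
        expect_true(all(setdiff(called, sim$truth$true_interactors) %in%
                            sim$truth$background))
    }
})

test_that("a null experiment under strong background suppression yields no calls", {
    for (s in 1:10) {
        sim <- simulateApms(nTrue = 0, backgroundMean = 0.1, seed = s)
        expect_length(
            calledPartners(callInteractors(sim$experiment, bait = "DYRK1A")),
            0)
    }
})

test_that("planted expression correlations are realized", {
    # exact at the degenerate ends
    se <- simulateExpression(nGenes = 5, nSamples = 50,
                             plantedCorr = c(P1 = 1), noiseSd = 0, seed = 3)
    expect_equal(unname(correlateWithBait(se, "DYRK1A", "P1")), 1)
    # rho 0.8 within +/-0.05 at n = 500
    for (s in 1:5) {
        se <- simulateExpression(nGenes = 5, nSamples = 500,
                                 plantedCorr = c(P1 = 0.8), seed = s)
        expect_lt(abs(correlateWithBait(se, "DYRK1A", "P1") - 0.8), 0.05)
    }
    # null correlation within 3/sqrt(n)
    for (s in 1:5) {
        se <- simulateExpression(nGenes = 5, nSamples = 400,
                                 plantedCorr = c(P1 = 0), seed = s)
        expect_lt(abs(correlateWithBait(se, "DYRK1A", "P1")),
                  3 / sqrt(400))
    }
    # sample metadata is present, BrainSpan-like
    expect_true(all(c("stage", "structure") %in%
                        names(colData(simulateExpression(
                            nGenes = 4, nSamples = 12, seed = 1)))))
})

test_that("planted DE signatures are recovered with the right direction", {
    genes <- sprintf("SIG%03d", 1:200)
    sim <- simulateDeTable(
        nGenes = 2000,
        sets = list(list(name = "up", genes = genes, pUp = 0.91)), seed = 8)
    d <- setDirectionality(sim$table, genes)
    expect_equal(d$n_in_table, 200)
    # within 3 binomial standard deviations of the planted probability
    expect_lt(abs(d$frac_up - 0.91), 3 * sqrt(0.91 * 0.09 / 200))
    # p_up 0 -> all down (continuous magnitudes: no ties)
    sim0 <- simulateDeTable(
        nGenes = 300,
        sets = list(list(name = "dn", genes = genes[1:54], pUp = 0)),
        seed = 9)
    expect_equal(setDirectionality(sim0$table, genes[1:54])$frac_down, 1)
    # two disjoint sets with opposite p_up separate cleanly
    sim2 <- simulateDeTable(
        nGenes = 500,
        sets = list(list(name = "A", genes = genes[1:100], pUp = 0.9),
                    list(name = "B", genes = sprintf("B%03d", 1:100),
                         pUp = 0.1)), seed = 10)
    expect_gt(setDirectionality(sim2$table, genes[1:100])$frac_up, 0.5)
    expect_lt(setDirectionality(sim2$table,
                                sprintf("B%03d", 1:100))$frac_up, 0.5)
    # planted significance fraction shows up in DEG calling
    expect_equal(callDegs(sim$table)$n_deg, 100)  # 0.05 * 2000
})

test_that("simulated ontologies hit their overlap fractions exactly", {
    o <- simulateOntology(nTermsBait = 10, overlapFracs = c(0.3, 0.3),
                          seed = 2)
    ov <- phenotypeOverlap(o$bait_terms, o$disease_terms)
    expect_equal(unname(ov$per_disease_fraction), c(0.3, 0.3))
    # disjoint slices add up
    expect_equal(ov$covered_fraction, 0.6)
    o2 <- simulateOntology(nTermsBait = 73, overlapFracs = c(1, 0),
                           seed = 2)
    ov2 <- phenotypeOverlap(o2$bait_terms, o2$disease_terms)
    expect_equal(unname(ov2$per_disease_fraction), c(1, 0))
    expect_equal(ov2$covered_fraction, 1)
})
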