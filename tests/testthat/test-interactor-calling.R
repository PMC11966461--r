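test_that("calls match the brute-force oracle on 50 random small tables", {
    for (seed in 101:150) {
        sce <- randomExperiment(seed, nProteins = 20)
        calls <- callInteractors(sce)
        oracle <- bruteForceCalls(sce)
        expect_identical(calls$called_Cter, unname(oracle[, "Cter"]),
                         info = paste("seed", seed))
        expect_identical(calls$called_Nter, unname(oracle[, "Nter"]),
                         info = paste("seed", seed))
    }
})

test_that("support classes follow the per-antibody calls", {
    # planted profiles: both antibodies / Cter only / Nter only / none
    sce <- toyExperiment(list(
        BOTH = c(9L, 9L, 9L, 9L, 9L, 9L, rep(0L, 9)),
        CT   = c(9L, 9L, 9L, 0L, 0L, 0L, rep(0L, 9)),
        NT   = c(0L, 0L, 0L, 9L, 9L, 9L, rep(0L, 9)),
        BG   = rep(2L, 15)))
    calls <- callInteractors(sce)
    expect_equal(calls$support_class,
                 c("both", "Cter-only", "Nter-only", "none"))
    expect_setequal(calledPartners(calls), c("BOTH", "CT", "NT"))
})

test_that("identical counts in bait and controls yield zero calls", {
    sce <- toyExperiment(list(A = rep(3L, 15), B = rep(7L, 15)))
    expect_length(calledPartners(callInteractors(sce)), 0)
})

test_that("the bait protein is reported but never counted as a partner", {
    sce <- toyExperiment(list(
        DYRK1A = c(rep(30L, 6), rep(0L, 9)),
        DCAF7  = c(rep(10L, 6), rep(0L, 9))))
    expect_warning(calls <- callInteractors(sce, bait = "DYRK1A"),
                   "all-zero")  # empty mock IPs are flagged, not fatal
    expect_true(calls$called_Cter[calls$symbol == "DYRK1A"])
    expect_equal(calledPartners(calls), "DCAF7")
})

test_that("monotonicity: more bait counts never un-call; more control counts never add", {
    for (seed in 201:210) {
        sce <- randomExperiment(seed)
        before <- callInteractors(sce)
        called <- which(before$called_Cter)
        if (length(called)) {
            # bump a called protein's bait counts
            i <- called[1]
            m <- assay(sce, "psm")
            m[i, colData(sce)$condition == "Cter"] <-
                m[i, colData(sce)$condition == "Cter"] + 10L
            sce2 <- SpectralCountExperiment(
                m, lengths = rowData(sce)$length_aa,
                condition = colData(sce)$condition,
                replicate = colData(sce)$replicate,
                role = colData(sce)$role)
            expect_true(callInteractors(sce2)$called_Cter[i])
        }
        # bump every protein's control counts: call set never grows
        m <- assay(sce, "psm")
        m[, colData(sce)$role == "control"] <-
            m[, colData(sce)$role == "control"] + 3L
        sce3 <- SpectralCountExperiment(
            m, lengths = rowData(sce)$length_aa,
            condition = colData(sce)$condition,
            replicate = colData(sce)$replicate,
            role = colData(sce)$role)
        after <- callInteractors(sce3)
        expect_true(all(calledPartners(after) %in% calledPartners(before)))
    }
})

test_that("with slack thresholds the call set collapses to criterion 2", {
    for (seed in 301:305) {
        sce <- randomExperiment(seed)
        calls <- callInteractors(sce, controlPsmBound = Inf,
                                 nsafRatioMin = 0)
        m <- assay(sce, "psm")
        for (b in c("Cter", "Nter")) {
            crit2 <- apply(m[, colData(sce)$condition == b, drop = FALSE],
                           1, function(r) sum(r) >= 5 && all(r > 0))
            expect_identical(calls[[paste0("called_", b)]], unname(crit2))
        }
    }
})

test_that("sum-level annotation tables are refused with a pointer to countSummary", {
    expect_error(callInteractors(dyrk1aPartners()), "countSummary")
})
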