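test_that("NSAF matches the hand-computed three-protein example", {
    # counts 10, 5, 5; lengths 100, 100, 200 -> SAF 0.1, 0.05, 0.025
    # -> NSAF 4/7, 2/7, 1/7
    sce <- SpectralCountExperiment(
        matrix(c(10L, 5L, 5L, 0L, 0L, 0L), nrow = 3,
               dimnames = list(c("A", "B", "C"), NULL)),
        lengths = c(100L, 100L, 200L),
        condition = c("Cter", "Beads"), replicate = c(1L, 1L),
        baits = "Cter")
    suppressWarnings(nsaf <- computeNSAF(sce))
    expect_equal(unname(nsaf[, "Cter"]), c(4, 2, 1) / 7)
})

test_that("NSAF normalizes to 1 and handles degenerate scopes", {
    # single protein with nonzero count
    one <- SpectralCountExperiment(
        matrix(c(7L, 0L), 1, dimnames = list("A", NULL)), lengths = 120L,
        condition = c("Cter", "Beads"), replicate = c(1L, 1L),
        baits = "Cter")
    suppressWarnings(n1 <- computeNSAF(one))
    expect_equal(unname(n1[, "Cter"]), 1)
    # equal counts, equal lengths -> symmetric split
    two <- toyExperiment(list(A = rep(2L, 15), B = rep(2L, 15)))
    expect_equal(unname(computeNSAF(two)[, "Cter"]), c(0.5, 0.5))
    # all-zero scope: zero NSAF with a warning
    expect_warning(nz <- computeNSAF(one), "all-zero")
    expect_equal(unname(nz[, "Beads"]), 0)
    # random tables: per-scope sums are 1 within 1e-9 (both scopes)
    for (seed in 21:25) {
        sce <- randomExperiment(seed)
        for (scope in c("condition", "run")) {
            nsaf <- suppressWarnings(computeNSAF(sce, scope))
            m <- if (scope == "condition") conditionSums(sce)
                 else assay(sce, "psm")
            nonzero <- colSums(m) > 0
            expect_true(all(abs(colSums(nsaf)[nonzero] - 1) < 1e-9))
        }
    }
})

test_that("control-clean criterion uses strict per-condition sums", {
    expect_true(criterionControlClean(c(Beads = 0, MAR = 0, RAM = 0)))
    # sum exactly 5 is not 'inferior to 5'
    expect_false(criterionControlClean(c(Beads = 5, MAR = 0, RAM = 0)))
    expect_true(criterionControlClean(c(Beads = 3, MAR = 0, RAM = 4)))
    # grand-sum variant is weaker
    expect_false(criterionControlClean(c(Beads = 3, MAR = 3),
                                       perCondition = FALSE))
    expect_error(criterionControlClean(numeric()), "control")
})

test_that("test-support criterion needs sum >= 5 and all replicates positive", {
    expect_true(criterionTestSupported(c(2, 2, 1)))   # sum exactly 5
    expect_false(criterionTestSupported(c(5, 0, 0)))  # zero replicate
    expect_false(criterionTestSupported(c(1, 1, 2)))  # sum 4
    expect_error(criterionTestSupported(numeric()), "replicate")
})

test_that("NSAF-enrichment criterion is inclusive with Inf zero-control rule", {
    r <- criterionNsafEnriched(0.03, c(0.01, 0, 0))
    expect_true(r$pass)
    expect_equal(r$ratio, 3)
    expect_false(criterionNsafEnriched(0, c(0, 0, 0))$pass)
    r2 <- criterionNsafEnriched(0.014, c(0.01, 0.01, 0.01))
    expect_false(r2$pass)
    expect_equal(r2$ratio, 1.4)
    # ratio exactly at the threshold passes
    expect_true(criterionNsafEnriched(0.015, c(0.01, 0, 0))$pass)
    # zero controls, positive test -> Inf, pass
    r3 <- criterionNsafEnriched(0.001, c(0, 0, 0))
    expect_true(r3$pass)
    expect_equal(r3$ratio, Inf)
    expect_error(criterionNsafEnriched(-0.1, 0.1), "non-negative")
    # alternative control references
    expect_equal(criterionNsafEnriched(0.03, c(0.01, 0.02, 0),
                                       controlRef = "mean")$ratio, 3)
    expect_equal(criterionNsafEnriched(0.03, c(0.01, 0.02, 0),
                                       controlRef = "sum")$ratio, 1)
})
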