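# Shared fixtures and the independent brute-force oracle for the
# three-criterion interactor filter.

suppressPackageStartupMessages({
    library(SummarizedExperiment)
})

# Small deterministic experiment: 2 bait conditions x 3 reps, 3 control
# conditions x 3 reps, counts supplied per protein as a 15-vector.
toyExperiment <- function(counts, lengths = NULL) {
    counts <- do.call(rbind, counts)
    if (is.null(lengths)) lengths <- rep(500L, nrow(counts))
    SpectralCountExperiment(
        counts, lengths = lengths,
        condition = rep(c("Cter", "Nter", "Beads", "MAR", "RAM"), each = 3),
        replicate = rep(1:3, 5),
        baits = c("Cter", "Nter"))
}

# Random table for property tests: nProteins x (2 bait + 3 control) x reps
randomExperiment <- function(seed, nProteins = 12, reps = 3) {
    withr::with_seed(seed, {
        n <- sample(2:nProteins, 1)
        counts <- matrix(stats::rpois(n * 5 * reps, lambda = 3), nrow = n,
                         dimnames = list(sprintf("P%02d", seq_len(n)), NULL))
        # sprinkle zeros and occasional spikes to hit branch boundaries
        counts[sample(length(counts), length(counts) %/% 3)] <- 0L
        counts[sample(length(counts), 2)] <- 25L
        SpectralCountExperiment(
            counts, lengths = sample(100:2000, n, replace = TRUE),
            condition = rep(c("Cter", "Nter", "Beads", "MAR", "RAM"),
                            each = reps),
            replicate = rep(seq_len(reps), 5),
            baits = c("Cter", "Nter"))
    })
}

# Independent straight-line re-evaluation of the three criteria, written
# from the rules directly (explicit loops, own NSAF arithmetic); kept free
# of package internals beyond raw accessors.
bruteForceCalls <- function(sce, controlBound = 5, testMin = 5,
                            ratioMin = 1.5) {
    m <- assay(sce, "psm")
    cd <- as.data.frame(colData(sce))
    lens <- rowData(sce)$length_aa
    baits <- unique(cd$condition[cd$role == "bait"])
    ctrls <- unique(cd$condition[cd$role == "control"])
    condSum <- function(i, cond) sum(m[i, cd$condition == cond])
    nsafOf <- function(i, cond) {
        saf <- sapply(seq_len(nrow(m)), function(j) condSum(j, cond) / lens[j])
        if (sum(saf) == 0) 0 else saf[i] / sum(saf)
    }
    out <- matrix(FALSE, nrow(m), length(baits),
                  dimnames = list(rownames(m), baits))
    for (i in seq_len(nrow(m))) {
        c1 <- TRUE
        for (ct in ctrls) if (!(condSum(i, ct) < controlBound)) c1 <- FALSE
        for (b in baits) {
            reps <- m[i, cd$condition == b]
            c2 <- sum(reps) >= testMin && all(reps > 0)
            tn <- nsafOf(i, b)
            cn <- max(sapply(ctrls, function(ct) nsafOf(i, ct)))
            c3 <- if (cn == 0) tn > 0 else (tn / cn) >= ratioMin
            out[i, b] <- c1 && c2 && c3
        }
    }
    out
}

apcSet <- c("CDC27", "ANAPC4", "CDC23", "CDC16", "ANAPC7")
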