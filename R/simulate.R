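#' Simulate a bait AP-MS spectral-count experiment with known truth
#'
#' Generates a [SpectralCountExperiment-class] mimicking the design of an
#' endogenous-bait IP-MS screen: two bait antibodies (`Cter`, `Nter`) and
#' three mock controls (`Beads`, `MAR`, `RAM`), each run in triplicate.
#' Each background (sticky/contaminant) protein gets its own abundance
#' drawn from a gamma distribution with mean `backgroundMean` — stickiness
#' is a protein property — and draws overdispersed (negative-binomial)
#' counts around that same abundance in every condition, bait and control
#' alike. Planted true interactors draw bait counts at `baitMean` per
#' replicate and near-zero control counts. The bait protein itself is
#' included with high bait-condition counts.
#' Protein lengths are uniform over `lengthRange`. Deterministic per
#' `seed`; no global random state is touched.
#'
#' @param nBackground number of background (sticky/contaminant) proteins.
#' @param nTrue number of planted true interactors.
#' @param baitMean per-replicate mean bait-condition count of a true
#'   interactor (default 30).
#' @param backgroundMean mean, over proteins, of the per-replicate
#'   background abundance; each protein's own abundance is
#'   gamma-distributed around it (shape `backgroundShape`) and constant
#'   across conditions (default 0.5).
#' @param backgroundShape gamma shape of the protein-to-protein abundance
#'   spread (default 1, an exponential spread: most proteins rare, a few
#'   very sticky).
#' @param trueControlMean per-replicate mean control count of a true
#'   interactor (default 0.02, near zero).
#' @param dispersion negative-binomial size parameter (default 4, a
#'   moderate overdispersion typical of protein-level spectral counts;
#'   smaller = more overdispersed).
#' @param replicates replicates per condition (default 3).
#' @param lengthRange protein length range in amino acids.
#' @param bait symbol given to the bait protein row.
#' @param seed integer seed, required.
#' @return List with `experiment` (a `SpectralCountExperiment`) and
#'   `truth` (list: `true_interactors`, `background`, `bait`, `seed`).
#' @examples
#' sim <- simulateApms(nBackground = 100, nTrue = 5, seed = 7)
#' sim$truth$true_interactors
#' @export
simulateApms <- function(nBackground = 200, nTrue = 5, baitMean = 30,
                         backgroundMean = 0.5, backgroundShape = 1,
                         trueControlMean = 0.02,
                         dispersion = 4, replicates = 3,
                         lengthRange = c(100L, 2000L), bait = "DYRK1A",
                         seed) {
    stopifnot(nBackground >= 0, nTrue >= 0, nBackground + nTrue >= 1,
              baitMean > 0, backgroundMean > 0, replicates >= 1)
    if (missing(seed)) stop("an explicit seed is required")
    conditions <- c(Cter = "bait", Nter = "bait", Beads = "control",
                    MAR = "control", RAM = "control")
    withr::with_seed(seed, {
        trueSyms <- sprintf("TRUE%03d", seq_len(nTrue))
        bgSyms <- sprintf("BG%04d", seq_len(nBackground))
        syms <- c(bait, trueSyms, bgSyms)
        n <- length(syms)
        lens <- sample(lengthRange[1]:lengthRange[2], n, replace = TRUE)
        condition <- rep(names(conditions), each = replicates)
        replicate <- rep(seq_len(replicates), times = length(conditions))
        role <- rep(unname(conditions), each = replicates)
        stickiness <- stats::rgamma(n, shape = backgroundShape,
                                    rate = backgroundShape / backgroundMean)
        mu <- matrix(stickiness, n, length(condition))
        isTrue <- syms %in% trueSyms
        mu[isTrue, role == "bait"] <- baitMean
        mu[isTrue, role == "control"] <- trueControlMean
        mu[syms == bait, role == "bait"] <- baitMean * 2
        mu[syms == bait, role == "control"] <- trueControlMean
        counts <- matrix(stats::rnbinom(length(mu), size = dispersion,
                                        mu = mu), n,
                         dimnames = list(syms, NULL))
        sce <- SpectralCountExperiment(counts, lengths = lens,
                                       condition = condition,
                                       replicate = replicate, role = role)
        list(experiment = sce,
             truth = list(true_interactors = trueSyms, background = bgSyms,
                          bait = bait, seed = seed))
    })
}

#' Simulate a developmental expression matrix with planted correlations
#'
#' Builds a gene x sample expression matrix shaped like a developmental
#' brain transcriptome (samples labelled by stage and structure) in which
#' chosen genes correlate with the bait's profile at planted levels: a
#' planted gene's profile is
#' `rho * z_bait + sqrt(1 - rho^2) * eps` with `eps` independent noise of
#' standard deviation `noiseSd` and `z_bait` the standardized bait
#' profile, so at the default `noiseSd = 1` the realized Pearson
#' correlation converges to `rho` as samples grow. Unplanted genes are
#' independent noise.
#'
#' @param nGenes total genes including the bait and planted genes.
#' @param nSamples number of samples (stage x structure pseudo-design).
#' @param bait bait gene symbol.
#' @param plantedCorr named numeric vector of target correlations in
#'   \[-1, 1\] per planted gene.
#' @param noiseSd standard deviation of the independent component
#'   (default 1, at which planted correlations are attained).
#' @param seed integer seed, required.
#' @return A `SummarizedExperiment` (assay `"expr"`, `colData` columns
#'   `stage` and `structure`) with `metadata(x)$truth` carrying the
#'   planted correlations and seed.
#' @export
simulateExpression <- function(nGenes = 100, nSamples = 30,
                               bait = "DYRK1A", plantedCorr = numeric(),
                               noiseSd = 1, seed) {
    stopifnot(all(abs(plantedCorr) <= 1), nSamples >= 3)
    if (missing(seed)) stop("an explicit seed is required")
    withr::with_seed(seed, {
        planted <- names(plantedCorr)
        nOther <- nGenes - 1L - length(planted)
        if (nOther < 0) stop("nGenes too small for planted genes")
        others <- sprintf("GENE%04d", seq_len(nOther))
        zBait <- as.numeric(scale(stats::rnorm(nSamples)))
        rows <- list()
        rows[[bait]] <- zBait
        for (g in planted) {
            rho <- plantedCorr[[g]]
            eps <- stats::rnorm(nSamples, sd = noiseSd)
            rows[[g]] <- rho * zBait + sqrt(1 - rho^2) * eps
        }
        for (g in others) rows[[g]] <- stats::rnorm(nSamples)
        mat <- do.call(rbind, rows)
        stages <- c("pcw08", "pcw12", "pcw16", "pcw21", "pcw37", "infant",
                    "child", "adult")
        structures <- c("DFC", "HIP", "AMY", "STR", "MD", "CBC")
        cd <- DataFrame(
            stage = rep_len(stages, nSamples),
            structure = rep_len(rep(structures, each = length(stages)),
                                nSamples),
            row.names = sprintf("S%03d", seq_len(nSamples)))
        se <- SummarizedExperiment(assays = list(expr = mat), colData = cd)
        S4Vectors::metadata(se)$truth <- list(planted_corr = plantedCorr,
                                              bait = bait, seed = seed)
        se
    })
}

#' Simulate a differential-expression result table with planted signatures
#'
#' Generates a DESeq-like result table in which members of supplied gene
#' sets receive a positive log2 fold change with a planted probability
#' (and magnitude around `effectSize`), background genes are centred
#' noise, and a configured fraction of genes receives an adjusted p-value
#' below `alpha`.
#'
#' @param nGenes total genes (background genes are named `DEG0001`...).
#' @param sets list of lists, each with `name`, `genes` (character) and
#'   `pUp` (probability of a positive log2fc); optional `effectSize`
#'   (default 1).
#' @param degFraction fraction of genes with padj below `alpha`
#'   (default 0.05).
#' @param alpha padj threshold used to plant significance (default 0.1).
#' @param seed integer seed, required.
#' @return List with `table` (`data.frame`: `gene`, `log2fc`, `pvalue`,
#'   `padj`) and `truth` (planted sets and seed).
#' @export
simulateDeTable <- function(nGenes = 2000, sets = list(),
                            degFraction = 0.05, alpha = 0.1, seed) {
    if (missing(seed)) stop("an explicit seed is required")
    setGenes <- unlist(lapply(sets, `[[`, "genes"))
    if (anyDuplicated(setGenes))
        stop("planted gene sets must be disjoint")
    nBg <- nGenes - length(setGenes)
    if (nBg < 0) stop("nGenes smaller than the planted sets")
    withr::with_seed(seed, {
        genes <- c(setGenes, sprintf("DEG%04d", seq_len(nBg)))
        log2fc <- stats::rnorm(nGenes, 0, 0.5)
        names(log2fc) <- genes
        for (s in sets) {
            es <- s$effectSize %||% 1
            sign <- ifelse(stats::runif(length(s$genes)) < s$pUp, 1, -1)
            log2fc[s$genes] <- sign * abs(stats::rnorm(length(s$genes),
                                                       es, es / 4))
        }
        pvalue <- stats::runif(nGenes)
        padj <- stats::runif(nGenes, alpha, 1)
        nSig <- round(degFraction * nGenes)
        sig <- sample(genes, nSig)
        padj[match(sig, genes)] <- stats::runif(nSig, 0, alpha)
        list(table = data.frame(gene = genes, log2fc = unname(log2fc),
                                pvalue = pvalue, padj = padj,
                                stringsAsFactors = FALSE),
             truth = list(sets = sets, significant = sig, seed = seed))
    })
}

#' Simulate a bait syndrome and partner-disease term sets
#'
#' Builds a bait phenotype-term set of `nTermsBait` identifiers and one
#' term set per disease intersecting the bait set in exactly
#' `round(overlap * nTermsBait)` terms. Bait terms are allocated to
#' diseases in consecutive, maximally disjoint slices (cycling once the
#' bait set is exhausted), so disjoint overlap fractions add up in the
#' covered fraction. Each disease also carries `nExtraTerms` terms outside
#' the bait set.
#'
#' @param nTermsBait size of the bait syndrome term set.
#' @param overlapFracs numeric vector in \[0, 1\], one entry per disease.
#' @param nExtraTerms non-bait terms per disease (default 5).
#' @param seed integer seed, required.
#' @return List with `bait_terms` (character) and `disease_terms` (named
#'   list of character vectors).
#' @export
simulateOntology <- function(nTermsBait = 73, overlapFracs,
                             nExtraTerms = 5, seed) {
    stopifnot(all(overlapFracs >= 0 & overlapFracs <= 1), nTermsBait >= 1)
    if (missing(seed)) stop("an explicit seed is required")
    withr::with_seed(seed, {
        baitTerms <- sprintf("HP:%07d", seq_len(nTermsBait))
        nextTerm <- nTermsBait
        pos <- 0L
        diseases <- list()
        for (i in seq_along(overlapFracs)) {
            k <- round(overlapFracs[i] * nTermsBait)
            idx <- if (k > 0)
                ((pos + seq_len(k) - 1L) %% nTermsBait) + 1L else integer()
            pos <- pos + k
            extra <- sprintf("HP:%07d", nextTerm + seq_len(nExtraTerms))
            nextTerm <- nextTerm + nExtraTerms
            diseases[[sprintf("DISEASE%02d", i)]] <-
                c(baitTerms[idx], extra)
        }
        list(bait_terms = baitTerms, disease_terms = diseases)
    })
}
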