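#' Normalized spectral abundance factor (NSAF)
#'
#' For each protein i with spectral count SpC_i and length L_i (amino
#' acids), NSAF_i = (SpC_i / L_i) / sum_j (SpC_j / L_j), the length-
#' normalized share of the spectral counts in a run. NSAF values sum to 1
#' within each scope whenever any count is nonzero; a scope with all-zero
#' counts yields all-zero NSAF with a warning.
#'
#' @param x a [SpectralCountExperiment-class]
#' @param scope `"condition"` (default) computes NSAF on replicate-summed
#'   counts, one column per condition — the aggregation the interactor
#'   filter uses; `"run"` computes it per individual run.
#' @return Numeric matrix of NSAF values, proteins x scopes.
#' @examples
#' counts <- matrix(c(10L, 5L, 5L, 0L, 0L, 1L), nrow = 3,
#'                  dimnames = list(c("A", "B", "C"), NULL))
#' sce <- SpectralCountExperiment(counts, lengths = c(100L, 100L, 200L),
#'                                condition = c("Cter", "Beads"),
#'                                replicate = c(1L, 1L), baits = "Cter")
#' computeNSAF(sce)  # Cter column: 4/7, 2/7, 1/7
#' @export
setGeneric("computeNSAF", function(x, scope = c("condition", "run"))
    standardGeneric("computeNSAF"))

#' @rdname computeNSAF
#' @export
setMethod("computeNSAF", "SpectralCountExperiment", function(x, scope) {
    scope <- match.arg(scope, c("condition", "run"))
    lens <- rowData(x)$length_aa
    if (any(lens <= 0)) stop("zero or negative protein length")
    m <- if (scope == "condition") conditionSums(x) else assay(x, "psm")
    saf <- m / lens
    totals <- colSums(saf)
    if (any(totals == 0))
        warning("all-zero counts in scope(s): ",
                paste(colnames(m)[totals == 0], collapse = ", "),
                "; NSAF set to 0 there")
    nsaf <- sweep(saf, 2, ifelse(totals == 0, 1, totals), "/")
    dimnames(nsaf) <- dimnames(m)
    nsaf
})

#' Filter criterion: clean control conditions
#'
#' TRUE iff for every named control condition, the sum of its replicate PSM
#' counts is strictly below `bound` (default 5). A control sum of exactly 5
#' therefore fails. With `perCondition = FALSE` the single grand sum across
#' all control runs is compared to the bound instead — a weaker reading
#' kept selectable.
#'
#' @param controlSums named numeric vector of per-condition control PSM
#'   sums for one protein.
#' @param bound exclusive upper bound on each control sum (default 5).
#' @param perCondition compare per-condition sums (default) or their total.
#' @return Logical scalar.
#' @seealso [callInteractors()] which applies all three criteria.
#' @export
criterionControlClean <- function(controlSums, bound = 5,
                                  perCondition = TRUE) {
    if (length(controlSums) == 0L) stop("no control conditions given")
    if (perCondition) all(controlSums < bound) else sum(controlSums) < bound
}

#' Filter criterion: supported in the test condition
#'
#' TRUE iff the replicate PSM counts of a bait-IP condition sum to at least
#' `minSum` (default 5) and every replicate is positive, i.e. the protein
#' was seen in each injection.
#'
#' @param replicateCounts integer vector of per-replicate PSM counts.
#' @param minSum inclusive lower bound on the replicate sum (default 5).
#' @return Logical scalar.
#' @export
criterionTestSupported <- function(replicateCounts, minSum = 5) {
    if (length(replicateCounts) < 1L) stop("need at least one replicate")
    sum(replicateCounts) >= minSum && all(replicateCounts > 0)
}

#' Filter criterion: NSAF enrichment over controls
#'
#' Computes the enrichment ratio test NSAF / reference control NSAF and
#' compares it to `threshold` (default 1.5, inclusive). The control
#' reference is by default the maximum NSAF over control conditions (the
#' most conservative choice); `"mean"` and `"sum"` are selectable. A zero
#' control reference with positive test NSAF gives ratio `Inf` (pass);
#' zero test NSAF never passes.
#'
#' @param testNsaf NSAF of the protein in the bait condition (>= 0).
#' @param controlNsafs NSAF values across control conditions (each >= 0).
#' @param threshold inclusive ratio threshold (default 1.5).
#' @param controlRef how to collapse `controlNsafs`: `"max"` (default),
#'   `"mean"` or `"sum"`.
#' @return List with `pass` (logical) and `ratio` (numeric, possibly
#'   `Inf`; `NaN` only when both sides are zero, which fails).
#' @export
criterionNsafEnriched <- function(testNsaf, controlNsafs, threshold = 1.5,
                                  controlRef = c("max", "mean", "sum")) {
    controlRef <- match.arg(controlRef)
    if (testNsaf < 0 || any(controlNsafs < 0))
        stop("NSAF values must be non-negative")
    ref <- switch(controlRef, max = max(controlNsafs),
                  mean = mean(controlNsafs), sum = sum(controlNsafs))
    if (ref == 0) {
        if (testNsaf > 0) return(list(pass = TRUE, ratio = Inf))
        return(list(pass = FALSE, ratio = NaN))
    }
    ratio <- testNsaf / ref
    list(pass = ratio >= threshold, ratio = ratio)
}
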