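#' Call candidate interactors from spectral counts
#'
#' Applies the three-criterion candidate-interactor filter per bait
#' antibody:
#' \enumerate{
#'   \item every control condition has a replicate PSM sum strictly below
#'     `controlPsmBound` ([criterionControlClean()]);
#'   \item the bait condition's replicate PSM sum is at least `testPsmMin`
#'     with a positive count in every replicate
#'     ([criterionTestSupported()]);
#'   \item the NSAF ratio of the bait condition over the control reference
#'     is at least `nsafRatioMin` ([criterionNsafEnriched()]).
#' }
#' A protein is called for an antibody iff all three pass. Dual-antibody
#' support is classified from the per-antibody calls (`"both"`,
#' `"<condition>-only"`, `"none"`). The bait protein itself, when named,
#' is reported with `is_bait = TRUE` and never counted as a partner.
#'
#' @param x a [SpectralCountExperiment-class] with per-replicate counts.
#'   Annotation tables carrying only per-antibody sums (e.g.
#'   [dyrk1aPartners()]) are refused — use [countSummary()] for those.
#' @param bait optional symbol of the bait protein present in the table.
#' @param controlPsmBound exclusive bound on each control-condition PSM
#'   sum (default 5).
#' @param testPsmMin inclusive minimum bait-condition PSM sum (default 5).
#' @param nsafRatioMin inclusive NSAF enrichment ratio threshold
#'   (default 1.5).
#' @param controlScope `"per-condition"` (default) applies the control
#'   bound to each control condition's sum; `"total"` to the grand sum.
#' @param controlRef collapse rule for control NSAFs in criterion 3:
#'   `"max"` (default), `"mean"` or `"sum"`.
#' @return A `data.frame` with one row per protein: `symbol`, `is_bait`,
#'   `crit1`, per bait condition `crit2_*`, `crit3_*`, `ratio_*` and
#'   `called_*` columns, and `support_class`.
#' @examples
#' sim <- simulateApms(nBackground = 50, nTrue = 3, seed = 1)
#' calls <- callInteractors(sim$experiment, bait = "DYRK1A")
#' table(calls$support_class)
#' @export
setGeneric("callInteractors", function(x, ...)
    standardGeneric("callInteractors"))

#' @rdname callInteractors
#' @param ... passed to methods.
#' @export
setMethod("callInteractors", "data.frame", function(x, ...) {
    stop("this table carries per-antibody PSM sums, not replicate-level ",
         "counts; use countSummary() for published annotation tables")
})

#' @rdname callInteractors
#' @export
setMethod("callInteractors", "SpectralCountExperiment",
    function(x, bait = NULL, controlPsmBound = 5, testPsmMin = 5,
             nsafRatioMin = 1.5, controlScope = c("per-condition", "total"),
             controlRef = c("max", "mean", "sum")) {
    controlScope <- match.arg(controlScope)
    controlRef <- match.arg(controlRef)
    baits <- baitConditions(x)
    controls <- controlConditions(x)
    cd <- colData(x)
    m <- assay(x, "psm")
    sums <- conditionSums(x)
    nsaf <- computeNSAF(x, scope = "condition")
    syms <- rowData(x)$symbol

    crit1 <- apply(sums[, controls, drop = FALSE], 1, criterionControlClean,
                   bound = controlPsmBound,
                   perCondition = controlScope == "per-condition")
    is_bait <- if (is.null(bait)) rep(FALSE, length(syms)) else syms == bait
    out <- data.frame(symbol = syms, is_bait = is_bait,
                      crit1 = crit1, row.names = NULL)
    called <- matrix(FALSE, nrow(x), length(baits),
                     dimnames = list(NULL, baits))
    for (b in baits) {
        reps <- m[, cd$condition == b, drop = FALSE]
        crit2 <- apply(reps, 1, criterionTestSupported, minSum = testPsmMin)
        c3 <- lapply(seq_len(nrow(x)), function(i)
            criterionNsafEnriched(nsaf[i, b], nsaf[i, controls],
                                  threshold = nsafRatioMin,
                                  controlRef = controlRef))
        crit3 <- vapply(c3, `[[`, logical(1), "pass")
        ratio <- vapply(c3, `[[`, numeric(1), "ratio")
        called[, b] <- crit1 & crit2 & crit3
        out[[paste0("crit2_", b)]] <- crit2
        out[[paste0("crit3_", b)]] <- crit3
        out[[paste0("ratio_", b)]] <- ratio
        out[[paste0("called_", b)]] <- called[, b]
    }
    n_called <- rowSums(called)
    out$support_class <- ifelse(
        n_called == length(baits), "both",
        ifelse(n_called == 0L, "none",
               paste0(apply(called, 1, function(z) paste(baits[z],
                     collapse = "+")), "-only")))
    out
})

#' Called partners from an interactor-call table
#'
#' Convenience filter: symbols called for at least one antibody, excluding
#' the bait.
#'
#' @param calls output of [callInteractors()]
#' @return Character vector of partner symbols.
#' @export
calledPartners <- function(calls) {
    calls$symbol[calls$support_class != "none" & !calls$is_bait]
}

#' Summary counts over a partner-annotation table
#'
#' Computes the headline counts of an interactome screen from a
#' partner-annotation table carrying per-antibody PSM sums (the layout of
#' [dyrk1aPartners()]): number of partners, dual-antibody detections,
#' known vs. novel partners, disease- and NDD-linked partners, partners
#' co-expressed with the bait, phospho-bearing partners, and membership in
#' a named gene set.
#'
#' Dual-antibody support on sum-level tables uses "both per-antibody PSM
#' sums >= `psmMin`" as the detection proxy, since replicate-level counts
#' are not published. The bait row is always excluded. Partners with
#' missing correlation are never counted as co-expressed (nor as
#' not-co-expressed); the co-expression fraction's denominator is all
#' partners.
#'
#' @param annotations a `data.frame` as returned by [dyrk1aPartners()] or
#'   [readPartnerAnnotations()].
#' @param corrThreshold inclusive co-expression threshold on the Pearson
#'   correlation (default 0.58).
#' @param psmMin per-antibody detection bound for dual support (default 5).
#' @param geneSet optional named list of one character vector, or character
#'   vector, of symbols (aliases are matched too) to count membership of.
#' @return Named list of counts: `n_partners`, `n_both_antibodies`,
#'   `n_known`, `n_novel`, `n_disease`, `n_ndd`, `n_coexpressed`,
#'   `n_phospho_partners`, and when `geneSet` is given `n_in_set` and
#'   `n_in_set_novel`.
#' @examples
#' countSummary(dyrk1aPartners())[c("n_partners", "n_both_antibodies")]
#' @export
countSummary <- function(annotations, corrThreshold = 0.58, psmMin = 5,
                         geneSet = NULL) {
    p <- annotations[!annotations$is_bait, , drop = FALSE]
    known <- p$known_partner == "yes"
    res <- list(
        n_partners = nrow(p),
        n_both_antibodies = sum(p$psm_cter >= psmMin & p$psm_nter >= psmMin),
        n_known = sum(known),
        n_novel = sum(!known),
        n_disease = sum(p$disease_class != "none"),
        n_ndd = sum(p$disease_class == "NDD"),
        n_coexpressed = sum(!is.na(p$correlation) &
                                p$correlation >= corrThreshold),
        n_phospho_partners = sum(!is.na(p$phospho) & nzchar(p$phospho)))
    if (!is.null(geneSet)) {
        genes <- if (is.list(geneSet)) geneSet[[1]] else geneSet
        alias <- if ("alias" %in% names(p)) p$alias else NA_character_
        in_set <- p$symbol %in% genes | (!is.na(alias) & alias %in% genes)
        res$n_in_set <- sum(in_set)
        res$n_in_set_novel <- sum(in_set & !known)
    }
    res
}
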