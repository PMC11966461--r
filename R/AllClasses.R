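#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData
NULL

#' SpectralCountExperiment: per-protein PSM counts across IP conditions
#'
#' Container for protein-level peptide-spectrum-match (PSM) counts from an
#' affinity-purification mass-spectrometry experiment, one column per
#' (condition, replicate) run. Extends
#' \linkS4class{SummarizedExperiment}: the single assay \code{"psm"} holds
#' non-negative integer counts; \code{rowData} carries \code{accession},
#' \code{symbol} and the protein length \code{length_aa} (amino acids,
#' required by NSAF); \code{colData} carries \code{condition},
#' \code{replicate} and \code{role} (\code{"bait"} or \code{"control"}).
#'
#' Validity requires integer counts >= 0, positive lengths, non-empty
#' symbols, unique (condition, replicate) pairs, and at least one bait and
#' one control condition.
#'
#' @seealso [SpectralCountExperiment()] the constructor,
#'   [computeNSAF()], [callInteractors()]
#' @name SpectralCountExperiment-class
#' @aliases SpectralCountExperiment-class
#' @exportClass SpectralCountExperiment
setClass("SpectralCountExperiment", contains = "SummarizedExperiment")

.validSpectralCountExperiment <- function(object) {
    msg <- NULL
    if (!"psm" %in% names(assays(object)))
        return("assay 'psm' is required")
    m <- assay(object, "psm")
    if (any(is.na(m)))
        msg <- c(msg, "PSM counts must not contain NA")
    else {
        if (any(m < 0))
            msg <- c(msg, sprintf("negative PSM count at row %d",
                                  which(apply(m < 0, 1, any))[1]))
        if (any(m != round(m)))
            msg <- c(msg, sprintf("non-integer PSM count at row %d",
                                  which(apply(m != round(m), 1, any))[1]))
    }
    rd <- rowData(object)
    for (col in c("accession", "symbol", "length_aa"))
        if (!col %in% names(rd))
            msg <- c(msg, sprintf("rowData column '%s' is required", col))
    if ("length_aa" %in% names(rd) &&
        (any(is.na(rd$length_aa)) || any(rd$length_aa <= 0)))
        msg <- c(msg, "protein lengths (length_aa) must be positive")
    if ("symbol" %in% names(rd) && any(!nzchar(rd$symbol)))
        msg <- c(msg, "protein symbols must be non-empty")
    cd <- colData(object)
    for (col in c("condition", "replicate", "role"))
        if (!col %in% names(cd))
            msg <- c(msg, sprintf("colData column '%s' is required", col))
    if (all(c("condition", "replicate", "role") %in% names(cd))) {
        if (anyDuplicated(paste(cd$condition, cd$replicate)))
            msg <- c(msg, "(condition, replicate) pairs must be unique")
        if (!any(cd$role == "bait") || !any(cd$role == "control"))
            msg <- c(msg, "need at least one bait and one control condition")
        if (!all(cd$role %in% c("bait", "control")))
            msg <- c(msg, "role must be 'bait' or 'control'")
    }
    if (is.null(msg)) TRUE else msg
}

setValidity("SpectralCountExperiment", .validSpectralCountExperiment)

#' Construct a SpectralCountExperiment
#'
#' @param counts integer matrix of PSM counts, proteins x runs. Column order
#'   must match `condition`/`replicate`.
#' @param lengths positive integer vector of protein lengths in amino acids.
#' @param condition character vector, one condition label per column of
#'   `counts` (e.g. `"Cter"`, `"Beads"`).
#' @param replicate integer vector, replicate index per column.
#' @param role `"bait"` or `"control"` per column; defaults to `"bait"` for
#'   conditions named in `baits` and `"control"` otherwise.
#' @param accession,symbol per-protein identifiers; `symbol` defaults to
#'   rownames of `counts`.
#' @param baits condition labels to mark as bait when `role` is missing.
#'
#' @return A [SpectralCountExperiment-class] object.
#' @examples
#' counts <- matrix(c(10L, 0L, 2L, 1L), nrow = 2,
#'                  dimnames = list(c("DYRK1A", "KRT1"), NULL))
#' sce <- SpectralCountExperiment(counts, lengths = c(753L, 644L),
#'                                condition = c("Cter", "Beads"),
#'                                replicate = c(1L, 1L), baits = "Cter")
#' sce
#' @export
SpectralCountExperiment <- function(counts, lengths, condition, replicate,
                                    role = NULL, accession = NULL,
                                    symbol = NULL, baits = NULL) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    if (is.null(symbol)) symbol <- rownames(counts)
    if (is.null(symbol))
        stop("provide 'symbol' or rownames on 'counts'")
    if (is.null(accession)) accession <- symbol
    if (is.null(role)) {
        if (is.null(baits))
            stop("provide 'role' per column or the bait condition labels in 'baits'")
        role <- ifelse(condition %in% baits, "bait", "control")
    }
    colnames(counts) <- paste(condition, replicate, sep = "_")
    rownames(counts) <- symbol
    se <- SummarizedExperiment(
        assays = list(psm = counts),
        rowData = DataFrame(accession = accession, symbol = symbol,
                            length_aa = as.integer(lengths),
                            row.names = symbol),
        colData = DataFrame(condition = as.character(condition),
                            replicate = as.integer(replicate),
                            role = as.character(role),
                            row.names = colnames(counts)))
    new("SpectralCountExperiment", se)
}

#' @describeIn SpectralCountExperiment Compact display of dimensions,
#'   conditions and replicate structure.
#' @param object a `SpectralCountExperiment`
#' @export
setMethod("show", "SpectralCountExperiment", function(object) {
    cd <- colData(object)
    cat("SpectralCountExperiment with", nrow(object), "proteins,",
        ncol(object), "runs\n")
    for (cond in unique(cd$condition)) {
        sel <- cd$condition == cond
        cat(sprintf("  %-8s %s  %d replicate(s)\n", cond,
                    unique(cd$role[sel]), sum(sel)))
    }
    invisible(NULL)
})

#' Condition labels of an experiment
#'
#' Accessors for the condition structure of a
#' [SpectralCountExperiment-class]: all condition labels, the bait
#' (test-IP) conditions and the control (mock-IP) conditions.
#'
#' @param x a `SpectralCountExperiment`
#' @return Character vector of condition labels.
#' @export
conditionLabels <- function(x) unique(colData(x)$condition)

#' @rdname conditionLabels
#' @export
baitConditions <- function(x) {
    cd <- colData(x)
    unique(cd$condition[cd$role == "bait"])
}

#' @rdname conditionLabels
#' @export
controlConditions <- function(x) {
    cd <- colData(x)
    unique(cd$condition[cd$role == "control"])
}

#' @rdname conditionLabels
#' @return `proteinLengths`: named integer vector of protein lengths (aa).
#' @export
proteinLengths <- function(x) {
    stats::setNames(rowData(x)$length_aa, rowData(x)$symbol)
}

#' Per-condition replicate count sums
#'
#' Sums PSM counts over the replicates of each condition, returning a
#' proteins x conditions matrix. This is the aggregation level at which the
#' control-PSM and NSAF-ratio filter criteria operate.
#'
#' @param x a [SpectralCountExperiment-class]
#' @param conditions conditions to keep (default all)
#' @return Integer matrix, proteins x conditions.
#' @export
conditionSums <- function(x, conditions = conditionLabels(x)) {
    cd <- colData(x)
    m <- assay(x, "psm")
    out <- vapply(conditions, function(cond) {
        cols <- which(cd$condition == cond)
        if (length(cols) == 0L)
            stop("unknown condition label: ", cond)
        rowSums(m[, cols, drop = FALSE])
    }, numeric(nrow(x)))
    out <- matrix(as.integer(out), nrow = nrow(x),
                  dimnames = list(rownames(x), conditions))
    out
}
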