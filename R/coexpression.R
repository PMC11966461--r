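#' Correlate partner expression profiles with the bait
#'
#' Pearson correlation, across samples, between each partner gene's
#' expression profile and the bait's — the developmental co-expression
#' measure used to prioritize partners. Partners absent from the matrix,
#' profiles with fewer than 3 samples of data, and zero-variance profiles
#' yield `NA` (never 0); the latter two warn.
#'
#' @param mat numeric matrix, genes x samples, with gene symbols as
#'   rownames; or a `SummarizedExperiment` whose first assay is such a
#'   matrix (sample metadata such as developmental stage and brain
#'   structure may sit in `colData` but is not used — the correlation runs
#'   over whatever sample columns are provided).
#' @param bait symbol of the bait gene; must be present.
#' @param partners character vector of partner symbols.
#' @return Named numeric vector of correlations in \[-1, 1\], `NA` where
#'   undefined.
#' @examples
#' m <- rbind(DYRK1A = c(1, 2, 3, 4), X = c(2, 4, 5, 9))
#' correlateWithBait(m, "DYRK1A", "X")
#' @export
correlateWithBait <- function(mat, bait, partners) {
    if (is(mat, "SummarizedExperiment")) mat <- assay(mat)
    if (!bait %in% rownames(mat))
        stop("bait '", bait, "' not found in expression matrix")
    if (!all(is.finite(mat)))
        stop("expression values must be finite")
    baitProfile <- mat[bait, ]
    if (length(baitProfile) < 3L)
        stop("need at least 3 samples for correlation")
    vapply(partners, function(g) {
        if (!g %in% rownames(mat)) return(NA_real_)
        prof <- mat[g, ]
        ok <- is.finite(prof) & is.finite(baitProfile)
        if (sum(ok) < 3L) {
            warning("fewer than 3 overlapping samples for ", g)
            return(NA_real_)
        }
        if (stats::sd(prof[ok]) == 0 || stats::sd(baitProfile[ok]) == 0) {
            warning("zero-variance profile for ", g, " or bait")
            return(NA_real_)
        }
        stats::cor(baitProfile[ok], prof[ok])
    }, numeric(1))
}

#' Classify a bait co-expression correlation
#'
#' Bins a Pearson correlation into `"coexpressed"` (rho at or above the
#' threshold), `"not-coexpressed"`, or `"unknown"` for missing values.
#' The default threshold 0.58 (inclusive) marks the moderate-to-high
#' positive band used for partner prioritization; it reproduces the
#' published 11/35 co-expressed partners on the packaged table.
#'
#' @param rho numeric vector of correlations, `NA` allowed.
#' @param threshold inclusive lower bound for co-expression (default 0.58).
#' @return Character vector over \{coexpressed, not-coexpressed, unknown\}.
#' @export
classifyCorrelation <- function(rho, threshold = 0.58) {
    ifelse(is.na(rho), "unknown",
           ifelse(rho >= threshold, "coexpressed", "not-coexpressed"))
}
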