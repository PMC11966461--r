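#' Call differentially expressed genes from a DE result table
#'
#' Applies the DEG rule to an upstream differential-expression result
#' (DESeq-style): a gene is a DEG iff its adjusted p-value is strictly
#' below `alpha` (default 0.1). DEGs are tiered `"strong"` (padj <
#' `strongAlpha`, default 0.05) or `"moderate"` (in between); all others
#' `"none"`. Genes with missing padj are never called. Multiple-testing
#' correction is consumed as provided, never recomputed.
#'
#' @param table `data.frame` with columns `gene`, `log2fc`, `pvalue`,
#'   `padj` (see [readDETable()] for DESeq column-name mapping).
#' @param alpha DEG threshold on padj, exclusive (default 0.1).
#' @param strongAlpha strong-tier threshold, exclusive (default 0.05);
#'   must not exceed `alpha`.
#' @return List: `deg` (character vector of DEG genes), `n_deg`, `n_up`
#'   (DEGs with log2fc > 0), `n_down` (log2fc < 0), `n_zero` (log2fc
#'   exactly 0, counted in neither direction), and `tier` (named character
#'   vector over all genes).
#' @examples
#' de <- data.frame(gene = paste0("g", 1:6), log2fc = c(1, -1, 2, -2, 1, -1),
#'                  pvalue = 0.01, padj = c(0.01, 0.07, 0.2, 0.09, 0.5, 0.04))
#' callDegs(de)$n_deg  # 4
#' @export
callDegs <- function(table, alpha = 0.1, strongAlpha = 0.05) {
    stopifnot(alpha > 0, alpha < 1, strongAlpha <= alpha)
    padj <- table$padj
    if (any(!is.na(padj) & (padj < 0 | padj > 1)))
        stop("padj outside [0,1]")
    isDeg <- !is.na(padj) & padj < alpha
    tier <- ifelse(!isDeg, "none",
                   ifelse(padj < strongAlpha, "strong", "moderate"))
    deg <- table$gene[isDeg]
    fc <- table$log2fc[isDeg]
    list(deg = deg,
         n_deg = length(deg),
         n_up = sum(fc > 0),
         n_down = sum(fc < 0),
         n_zero = sum(fc == 0),
         tier = stats::setNames(tier, table$gene))
}

#' Directionality of a gene set in a DE table
#'
#' Restricted to set members present in the table, counts genes with
#' positive and negative log2 fold change and their fractions — with no
#' significance filter, since signature-level directionality (e.g. "91% of
#' a 200-gene signature overexpressed") is assessed over all set members,
#' not only significant ones. log2fc exactly 0 counts in neither
#' direction.
#'
#' @param table DE `data.frame` (columns `gene`, `log2fc`).
#' @param geneSet character vector of symbols, or a single-element named
#'   list as produced by [readGeneSets()].
#' @return List: `n_in_table`, `n_up`, `n_down`, `n_zero`, `frac_up`,
#'   `frac_down` (fractions `NA` when the intersection is empty).
#' @export
setDirectionality <- function(table, geneSet) {
    genes <- if (is.list(geneSet)) geneSet[[1]] else geneSet
    fc <- table$log2fc[table$gene %in% genes]
    n <- length(fc)
    list(n_in_table = n,
         n_up = sum(fc > 0),
         n_down = sum(fc < 0),
         n_zero = sum(fc == 0),
         frac_up = if (n) sum(fc > 0) / n else NA_real_,
         frac_down = if (n) sum(fc < 0) / n else NA_real_)
}

#' Read a differential-expression result table
#'
#' Reads a tab-separated DE result with DESeq-style column names
#' (`log2FoldChange`, `pvalue`, `padj` and a gene column), remapping to
#' the internal `gene`/`log2fc`/`pvalue`/`padj` layout. Alternative column
#' names can be supplied via `schema`.
#'
#' @param path path to a TSV with a header row.
#' @param schema optional named list mapping internal names (`gene`,
#'   `log2fc`, `pvalue`, `padj`) to file column names.
#' @return A `data.frame` with columns `gene`, `log2fc`, `pvalue`, `padj`;
#'   duplicate gene symbols are an error.
#' @export
readDETable <- function(path, schema = NULL) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    map <- list(gene = "gene", log2fc = "log2FoldChange",
                pvalue = "pvalue", padj = "padj")
    map[names(schema)] <- schema
    for (nm in names(map))
        if (!map[[nm]] %in% names(df))
            stop("DE table lacks column '", map[[nm]], "'")
    out <- data.frame(gene = df[[map$gene]], log2fc = df[[map$log2fc]],
                      pvalue = df[[map$pvalue]], padj = df[[map$padj]],
                      stringsAsFactors = FALSE)
    if (anyDuplicated(out$gene))
        stop("duplicate gene symbols in DE table")
    out
}

#' Read gene sets in GMT format
#'
#' Thin wrapper over `fgsea::gmtPathways()` returning a named list of
#' symbol vectors.
#'
#' @param path path to a GMT file.
#' @return Named list of character vectors.
#' @export
readGeneSets <- function(path) {
    fgsea::gmtPathways(path)
}
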