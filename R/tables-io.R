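#' Read a protein-level spectral-count table
#'
#' Reads a tab-separated protein export (one row per protein, one column per
#' (condition, replicate) run) into a [SpectralCountExperiment-class].
#' The expected dialect is the flat table a search engine's protein-level
#' export reduces to: identifier columns plus integer PSM counts.
#'
#' Run columns are named `<condition>_<replicate>` (e.g. `Cter_1`); by
#' default every column matching that pattern is treated as a run and all
#' other columns are looked up in `schema`. A `schema` list can override
#' the column mapping: fields `accession`, `symbol`, `length` name the
#' identifier columns, `runs` is a named character vector mapping run
#' columns to `<condition>_<replicate>` slots, and `baits` names the bait
#' conditions.
#'
#' @param path path to a tab-separated file with a header row.
#' @param schema optional list overriding column mapping (see Details).
#' @param baits character vector of bait condition labels; ignored when
#'   `schema$baits` is set.
#' @return A validated [SpectralCountExperiment-class]. Non-integer or
#'   negative counts and a missing length column are hard errors.
#' @seealso [writeSpectralCounts()] for the inverse operation.
#' @export
readSpectralCounts <- function(path, schema = NULL, baits = NULL) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    schema <- schema %||% list()
    acc_col <- schema$accession %||% "accession"
    sym_col <- schema$symbol %||% "symbol"
    len_col <- schema$length %||% "length_aa"
    baits <- schema$baits %||% baits
    if (!len_col %in% names(df))
        stop("missing protein length column '", len_col,
             "' (required for NSAF)")
    if (!sym_col %in% names(df))
        stop("missing symbol column '", sym_col, "'")
    if (!is.null(schema$runs)) {
        run_cols <- names(schema$runs)
        run_ids <- unname(schema$runs)
    } else {
        run_cols <- setdiff(grep("^.+_[0-9]+$", names(df), value = TRUE),
                            c(acc_col, sym_col, len_col))
        run_ids <- run_cols
    }
    if (length(run_cols) == 0L)
        stop("no run columns found (expected names like 'Cter_1')")
    counts <- as.matrix(df[, run_cols, drop = FALSE])
    bad <- which(apply(is.na(counts) | counts < 0 | counts != round(counts),
                       1, any))
    if (length(bad))
        stop("invalid PSM count (negative, missing or non-integer) in row ",
             bad[1])
    condition <- sub("_[0-9]+$", "", run_ids)
    replicate <- as.integer(sub("^.*_", "", run_ids))
    SpectralCountExperiment(
        counts, lengths = df[[len_col]],
        condition = condition, replicate = replicate,
        accession = if (acc_col %in% names(df)) df[[acc_col]] else NULL,
        symbol = df[[sym_col]], baits = baits)
}

#' Write a spectral-count table to TSV
#'
#' Writes the `<condition>_<replicate>` dialect read by
#' [readSpectralCounts()]; writing then re-reading reproduces the object.
#'
#' @param x a [SpectralCountExperiment-class]
#' @param path output file path
#' @return `path`, invisibly.
#' @export
writeSpectralCounts <- function(x, path) {
    rd <- rowData(x)
    cd <- colData(x)
    df <- data.frame(accession = rd$accession, symbol = rd$symbol,
                     length_aa = rd$length_aa, check.names = FALSE)
    m <- assay(x, "psm")
    colnames(m) <- paste(cd$condition, cd$replicate, sep = "_")
    df <- cbind(df, as.data.frame(m, check.names = FALSE))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' The published DYRK1A partner table (human neural stem cells)
#'
#' Returns the packaged list of DYRK1A interactors identified by IP-MS in
#' human neural stem cells: the bait row plus 35 partners, with per-antibody
#' PSM sums (C-terminal and N-terminal antibodies), phosphosite calls,
#' known-partner status with literature source tags, disease involvement
#' (`none`, `NDD`, `other`), gnomAD pLI and the Pearson correlation of each
#' gene's developmental brain-expression profile with the bait's.
#'
#' Replicate-level counts were not published, so this table carries
#' per-antibody sums only; operations that need per-replicate counts
#' (e.g. [callInteractors()]) refuse it — use [countSummary()] instead.
#' Missing values (pLI for SMC3 and IGHA1, correlation for AGO1) are `NA`,
#' never 0.
#'
#' @param includeBait keep the bait row (default `TRUE`); summary
#'   operations exclude it regardless via the `is_bait` flag.
#' @return A `data.frame` with columns `symbol`, `alias`, `is_bait`,
#'   `psm_cter`, `psm_nter`, `phospho`, `known_partner`, `known_sources`,
#'   `disease_printed`, `disease_class`, `pli`, `correlation`.
#' @examples
#' partners <- dyrk1aPartners()
#' sum(!partners$is_bait)  # 35 partners
#' @export
dyrk1aPartners <- function(includeBait = TRUE) {
    path <- system.file("extdata", "dyrk1a_partner_table.tsv",
                        package = "neurointeract", mustWork = TRUE)
    df <- readPartnerAnnotations(path)
    if (!includeBait) df <- df[!df$is_bait, , drop = FALSE]
    df
}

#' Read a partner-annotation table
#'
#' Reads a tab-separated annotation table in the layout of
#' [dyrk1aPartners()] and validates its ranges: pLI in \[0, 1\] and
#' correlation in \[-1, 1\] where present.
#'
#' @param path path to a tab-separated annotation file.
#' @return A validated `data.frame` (see [dyrk1aPartners()] for columns).
#' @export
readPartnerAnnotations <- function(path) {
    df <- utils::read.delim(path, na.strings = c("NA", ""),
                            stringsAsFactors = FALSE)
    need <- c("symbol", "is_bait", "psm_cter", "psm_nter", "known_partner",
              "disease_class", "pli", "correlation")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("annotation table lacks column(s): ",
             paste(miss, collapse = ", "))
    if (!"phospho" %in% names(df)) df$phospho <- NA_character_
    df$is_bait <- as.logical(df$is_bait)
    ok_pli <- is.na(df$pli) | (df$pli >= 0 & df$pli <= 1)
    if (!all(ok_pli))
        stop("pLI outside [0,1] for ",
             paste(df$symbol[!ok_pli], collapse = ", "))
    ok_corr <- is.na(df$correlation) |
        (df$correlation >= -1 & df$correlation <= 1)
    if (!all(ok_corr))
        stop("correlation outside [-1,1] for ",
             paste(df$symbol[!ok_corr], collapse = ", "))
    if (!all(df$disease_class %in% c("none", "NDD", "other")))
        stop("disease_class must be one of none/NDD/other")
    df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
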