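#' Default pipeline thresholds
#'
#' The filter and prioritization thresholds used throughout: control PSM
#' bound 5 (exclusive), test PSM minimum 5 (inclusive, all replicates
#' positive), NSAF ratio 1.5 (inclusive), co-expression correlation 0.58
#' (inclusive), pLI 0.9 (exclusive), DEG adjusted-p 0.1 and strong tier
#' 0.05 (both exclusive).
#'
#' @return Named list of thresholds.
#' @export
defaultThresholds <- function() {
    list(control_psm_bound = 5, test_psm_min = 5, nsaf_ratio = 1.5,
         corr_threshold = 0.58, pli_threshold = 0.9, deg_alpha = 0.1,
         deg_strong_alpha = 0.05)
}

#' Read a pipeline configuration file
#'
#' YAML key-value config with optional `thresholds` (merged over
#' [defaultThresholds()]), `inputs` (paths: `counts`, `annotations`,
#' `expression`, `de`, `gene_sets`, `bait_terms`, `term_links`), `bait`
#' and `seed`.
#'
#' @param path path to a YAML file.
#' @return Config list as accepted by [runPipeline()].
#' @export
readPipelineConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    cfg$thresholds <- utils::modifyList(defaultThresholds(),
                                        cfg$thresholds %||% list())
    cfg
}

.asDiseaseTerms <- function(x) if (is.character(x)) readTermLinks(x) else x

#' Run the full interactome analysis pipeline
#'
#' Orchestrates every stage for which the config provides an input, and
#' consolidates one report:
#' \itemize{
#'   \item `counts` (path or [SpectralCountExperiment-class]):
#'     three-criterion interactor calling ([callInteractors()]);
#'   \item `annotations` (path or `data.frame`): summary counts
#'     ([countSummary()]) and NDD-candidate flags ([flagCandidates()]);
#'   \item `expression` (path, matrix or `SummarizedExperiment`): bait
#'     co-expression for called or annotated partners
#'     ([correlateWithBait()]);
#'   \item `de` (path or `data.frame`): DEG calling ([callDegs()]) and,
#'     with `gene_sets` (GMT path or named list), per-set directionality
#'     ([setDirectionality()]);
#'   \item `bait_terms` + `term_links`: phenotype-term overlap
#'     ([phenotypeOverlap()]).
#' }
#' The report embeds the exact config used (thresholds merged over
#' [defaultThresholds()]) and a per-stage log with records in/out of each
#' filter, and is deterministic given config + inputs.
#'
#' @param config list with elements `inputs` (named list of paths or
#'   in-memory objects as above), optional `thresholds`, `bait` (bait
#'   symbol, default `"DYRK1A"`), `gene_set` (named list: partner gene set
#'   to count membership of, e.g. the APC subunits) and `seed`.
#' @return Report list with elements `config`, `log`, and per-stage
#'   results (`calls`, `summary`, `candidates`, `correlations`, `deg`,
#'   `directionality`, `phenotype_overlap`).
#' @examples
#' report <- runPipeline(list(
#'     inputs = list(annotations = dyrk1aPartners()),
#'     gene_set = list(APC = c("CDC27", "ANAPC4", "CDC23", "CDC16",
#'                             "ANAPC7"))))
#' unlist(report$summary)
#' @export
runPipeline <- function(config) {
    th <- utils::modifyList(defaultThresholds(),
                            config$thresholds %||% list())
    config$thresholds <- th
    bait <- config$bait %||% "DYRK1A"
    inputs <- config$inputs %||% list()
    report <- list(config = config[c("thresholds", "bait", "seed")],
                   log = character())
    note <- function(...) {
        report$log <<- c(report$log, sprintf(...))
        invisible(NULL)
    }

    if (!is.null(inputs$counts)) {
        sce <- inputs$counts
        if (is.character(sce)) sce <- readSpectralCounts(sce, baits = config$baits)
        calls <- callInteractors(sce, bait = bait,
                                 controlPsmBound = th$control_psm_bound,
                                 testPsmMin = th$test_psm_min,
                                 nsafRatioMin = th$nsaf_ratio)
        note("interactor calling: %d proteins in, %d pass criterion 1, %d called",
             nrow(calls), sum(calls$crit1), length(calledPartners(calls)))
        report$calls <- calls
        report$called_partners <- calledPartners(calls)
    }

    if (!is.null(inputs$annotations)) {
        ann <- inputs$annotations
        if (is.character(ann)) ann <- readPartnerAnnotations(ann)
        report$summary <- countSummary(ann,
                                       corrThreshold = th$corr_threshold,
                                       psmMin = th$test_psm_min,
                                       geneSet = config$gene_set)
        flags <- flagCandidates(ann, pliThreshold = th$pli_threshold,
                                corrThreshold = th$corr_threshold)
        note("annotation summary: %d partners, %d NDD candidates",
             report$summary$n_partners, sum(flags$is_candidate))
        report$candidates <- flags
    }

    if (!is.null(inputs$expression)) {
        expr <- inputs$expression
        if (is.character(expr))
            expr <- as.matrix(utils::read.delim(expr, row.names = 1))
        genes <- report$called_partners %||%
            setdiff(rownames(if (is(expr, "SummarizedExperiment"))
                assay(expr) else expr), bait)
        rho <- correlateWithBait(expr, bait, genes)
        note("co-expression: %d genes correlated, %d coexpressed at %.2f",
             length(rho), sum(classifyCorrelation(rho,
                 th$corr_threshold) == "coexpressed"), th$corr_threshold)
        report$correlations <- rho
        report$correlation_class <- classifyCorrelation(rho,
                                                        th$corr_threshold)
    }

    if (!is.null(inputs$de)) {
        de <- inputs$de
        if (is.character(de)) de <- readDETable(de)
        deg <- callDegs(de, alpha = th$deg_alpha,
                        strongAlpha = th$deg_strong_alpha)
        note("DEG calling: %d genes in, %d DEGs (%d up, %d down)",
             nrow(de), deg$n_deg, deg$n_up, deg$n_down)
        report$deg <- deg[c("deg", "n_deg", "n_up", "n_down", "n_zero")]
        if (!is.null(inputs$gene_sets)) {
            sets <- inputs$gene_sets
            if (is.character(sets)) sets <- readGeneSets(sets)
            report$directionality <- lapply(sets, function(g)
                setDirectionality(de, g))
            note("directionality computed for %d gene set(s)", length(sets))
        }
    }

    if (!is.null(inputs$bait_terms) && !is.null(inputs$term_links)) {
        bt <- inputs$bait_terms
        if (is.character(bt) && length(bt) == 1L && file.exists(bt))
            bt <- utils::read.delim(bt, stringsAsFactors = FALSE)$term_id
        dt <- .asDiseaseTerms(inputs$term_links)
        report$phenotype_overlap <- phenotypeOverlap(bt, dt)
        note("phenotype overlap: %.1f%% of %d bait terms covered",
             100 * report$phenotype_overlap$covered_fraction, length(bt))
    }
    report
}

#' Write a pipeline report
#'
#' Serializes a [runPipeline()] report to JSON (config included, so the
#' report is self-describing) and, optionally, its tabular stages to TSV
#' files alongside.
#'
#' @param report a report list from [runPipeline()].
#' @param path output JSON path.
#' @param tsvDir optional directory for `calls.tsv` / `candidates.tsv`.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path, tsvDir = NULL) {
    if (!is.null(tsvDir)) {
        dir.create(tsvDir, showWarnings = FALSE, recursive = TRUE)
        for (nm in c("calls", "candidates"))
            if (!is.null(report[[nm]]))
                utils::write.table(report[[nm]],
                                   file.path(tsvDir, paste0(nm, ".tsv")),
                                   sep = "\t", quote = FALSE,
                                   row.names = FALSE)
    }
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    invisible(path)
}
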