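#' Phenotype-term overlap between a bait syndrome and partner diseases
#'
#' Given the set of clinical-sign terms (e.g. HPO identifiers) of the bait
#' syndrome and term sets of diseases linked to the bait's partners,
#' computes the fraction of bait terms also described in any partner
#' disease and the per-disease fractions. Overlap is exact identifier
#' matching — no propagation through the ontology graph.
#'
#' @param baitTerms non-empty character vector of phenotype-term ids.
#' @param diseaseTerms named list of character vectors, one per disease.
#' @return List with `covered_fraction` (share of bait terms found in the
#'   union of disease sets) and `per_disease_fraction` (named numeric).
#' @examples
#' phenotypeOverlap(paste0("HP:", 1:10),
#'                  list(A = paste0("HP:", 1:4), B = paste0("HP:", 3:6)))
#' @export
phenotypeOverlap <- function(baitTerms, diseaseTerms) {
    baitTerms <- unique(baitTerms)
    if (length(baitTerms) == 0L) stop("bait term set must be non-empty")
    perDisease <- vapply(diseaseTerms, function(terms)
        length(intersect(baitTerms, terms)) / length(baitTerms), numeric(1))
    covered <- length(intersect(baitTerms, unique(unlist(diseaseTerms)))) /
        length(baitTerms)
    list(covered_fraction = covered, per_disease_fraction = perDisease)
}

#' Read disease-to-term links
#'
#' Reads a two-column tab-separated file (`disease_id`, `term_id`) into the
#' named list of term sets consumed by [phenotypeOverlap()].
#'
#' @param path path to a TSV with a header row.
#' @return Named list of character vectors.
#' @export
readTermLinks <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("disease_id", "term_id") %in% names(df)))
        stop("term-link file needs columns disease_id, term_id")
    lapply(split(df$term_id, df$disease_id), unique)
}

#' Flag partners as NDD candidate genes
#'
#' A partner is flagged as a neurodevelopmental-disorder candidate iff it
#' is not yet linked to a human disease, is highly intolerant to
#' loss-of-function (pLI strictly above `pliThreshold`), and its
#' developmental expression profile correlates with the bait's at or above
#' `corrThreshold`. Missing pLI or correlation disqualifies (conservative).
#'
#' @param annotations partner-annotation `data.frame` (see
#'   [dyrk1aPartners()]); the bait row is ignored.
#' @param pliThreshold exclusive pLI lower bound (default 0.9).
#' @param corrThreshold inclusive correlation lower bound (default 0.58).
#' @return A `data.frame` with `symbol`, `is_candidate` and logical reason
#'   columns `no_known_disease`, `pli_high`, `coexpressed`;
#'   `is_candidate` is their conjunction.
#' @examples
#' flags <- flagCandidates(dyrk1aPartners())
#' flags$symbol[flags$is_candidate]
#' @export
flagCandidates <- function(annotations, pliThreshold = 0.9,
                           corrThreshold = 0.58) {
    p <- annotations[!annotations$is_bait, , drop = FALSE]
    noDisease <- p$disease_class == "none"
    pliHigh <- !is.na(p$pli) & p$pli > pliThreshold
    coexpr <- !is.na(p$correlation) & p$correlation >= corrThreshold
    data.frame(symbol = p$symbol,
               no_known_disease = noDisease,
               pli_high = pliHigh,
               coexpressed = coexpr,
               is_candidate = noDisease & pliHigh & coexpr,
               row.names = NULL)
}
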