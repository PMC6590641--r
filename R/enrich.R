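#' Hypergeometric over-representation test
#'
#' Exact upper-tail probability `P(X >= overlap)` of drawing at least
#' the observed overlap between a study set and a term's gene set when
#' sampling `|study|` genes without replacement from a universe of size
#' `N` containing `K` term genes. The study and term sets are
#' intersected with the universe first.
#'
#' @param study Character vector: the gene set under test.
#' @param term Character vector: the term's member genes.
#' @param universe Character vector: the background gene universe
#'   (non-empty).
#' @return A single probability.
#' @export
ora_test <- function(study, term, universe) {
  universe <- unique(canon_symbol(universe))
  assert_that(length(universe) > 0, "universe must be non-empty")
  study <- intersect(unique(canon_symbol(study)), universe)
  term <- intersect(unique(canon_symbol(term)), universe)
  k <- length(intersect(study, term))
  stats::phyper(k - 1, m = length(term), n = length(universe) - length(term),
                k = length(study), lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard false-discovery-rate step-up, capped at 1 and monotone over
#' the sorted order. Thin wrapper over [stats::p.adjust()] so the
#' pipeline's adjustment is a named, testable step.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  assert_that(all(pvals >= 0 & pvals <= 1), "p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Over-representation analysis of a study set against a GMT catalog
#'
#' One hypergeometric test per term with at least `min_term` genes in
#' the universe, BH adjustment across the tested terms, and a
#' significance call at `q < q_max`. Rows are sorted by ascending p,
#' ties broken by term id, so output is independent of catalog order.
#'
#' @param study Character vector: the gene set under test.
#' @param catalog GMT-style named list (see [read_gmt()]).
#' @param universe Character vector: background universe.
#' @param q_max Adjusted-p significance cutoff (default 0.05).
#' @param min_term Minimum term size within the universe (default 3).
#' @return Data frame with columns `term_id`, `name`, `K` (term genes in
#'   universe), `n` (study genes in universe), `overlap`, `p`, `q`,
#'   `significant`.
#' @export
enrich_catalog <- function(study, catalog, universe, q_max = 0.05,
                           min_term = 3) {
  assert_that(length(catalog) > 0, "catalog must be non-empty")
  universe <- unique(canon_symbol(universe))
  assert_that(length(universe) > 0, "universe must be non-empty")
  study <- intersect(unique(canon_symbol(study)), universe)
  desc <- attr(catalog, "descriptions") %||%
    stats::setNames(names(catalog), names(catalog))
  term_in_u <- lapply(catalog, function(g) {
    intersect(unique(canon_symbol(g)), universe)
  })
  keep <- lengths(term_in_u) >= min_term
  ids <- names(catalog)[keep]
  term_in_u <- term_in_u[keep]
  K <- lengths(term_in_u)
  overlap <- vapply(term_in_u, function(g) length(intersect(study, g)), 1L)
  p <- stats::phyper(overlap - 1, m = K, n = length(universe) - K,
                     k = length(study), lower.tail = FALSE)
  q <- bh_adjust(p)
  df <- data.frame(term_id = ids, name = unname(desc[ids]),
                   K = unname(K), n = length(study),
                   overlap = unname(overlap), p = unname(p), q = unname(q),
                   significant = unname(q < q_max),
                   stringsAsFactors = FALSE)
  df <- df[order(df$p, df$term_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Terms significant in both diseases
#'
#' The intersection of the significant term ids of two enrichment
#' tables — the shared biological process / pathway call.
#'
#' @param tableA,tableB Data frames from [enrich_catalog()] computed
#'   against catalogs sharing term ids.
#' @return Sorted character vector of shared significant term ids
#'   (possibly empty).
#' @export
shared_significant_terms <- function(tableA, tableB) {
  sort(intersect(tableA$term_id[tableA$significant],
                 tableB$term_id[tableB$significant]))
}
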