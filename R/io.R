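#' Construct an expression matrix container
#'
#' Bundles a genes-by-samples matrix of log2 expression values with a
#' two-group sample labelling. This is the unit of input for
#' [fit_gene_stats()].
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). Values are on the log2
#'   scale.
#' @param groups Named character vector mapping every sample id to
#'   `"case"` or `"control"`.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` and `groups`.
#' @examples
#' m <- matrix(rnorm(20), 5, 4,
#'   dimnames = list(paste0("G", 1:5), paste0("S", 1:4)))
#' em <- expression_matrix(m, setNames(rep(c("case", "control"), each = 2),
#'   colnames(m)))
#' @export
expression_matrix <- function(values, groups) {
  assert_that(is.matrix(values) && is.numeric(values),
              "values must be a numeric matrix")
  assert_that(!is.null(rownames(values)) && !is.null(colnames(values)),
              "values must carry gene rownames and sample colnames")
  assert_that(!anyDuplicated(rownames(values)), "duplicate gene ids")
  assert_that(!anyDuplicated(colnames(values)), "duplicate sample ids")
  groups <- groups[colnames(values)]
  assert_that(!anyNA(groups), "every sample needs a group label")
  assert_that(all(groups %in% c("case", "control")),
              "group labels must be 'case' or 'control'")
  assert_that(all(c("case", "control") %in% groups),
              "both groups must be non-empty")
  structure(list(values = values, groups = groups),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%d case, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$groups == "case"), sum(x$groups == "control")))
  invisible(x)
}

#' Write / read an expression matrix as TSV
#'
#' The expression file has gene ids in the first column (`gene`) and one
#' column per sample; the companion group file has columns `sample` and
#' `group`.
#'
#' @param em An [expression_matrix()].
#' @param path Path for the expression TSV.
#' @param groups_path Path for the sample-to-group TSV.
#' @return `write_expression_tsv` returns `path` invisibly;
#'   `read_expression_tsv` returns an `expression_matrix`.
#' @export
write_expression_tsv <- function(em, path, groups_path) {
  df <- data.frame(gene = rownames(em$values), em$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  gdf <- data.frame(sample = names(em$groups), group = unname(em$groups))
  utils::write.table(gdf, groups_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path, groups_path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  assert_that(names(df)[1] == "gene", "expression TSV must start with 'gene'")
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$gene
  gdf <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
  expression_matrix(values, stats::setNames(gdf$group, gdf$sample))
}

#' Write / read a plain gene list (one symbol per line)
#'
#' @param genes Character vector of gene symbols.
#' @param path File path.
#' @return `write_gene_list` returns `path` invisibly; `read_gene_list`
#'   returns a sorted character vector of upper-cased symbols.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(sort(unique(canon_symbol(genes))), path)
  invisible(path)
}

#' @rdname write_gene_list
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  sort(unique(canon_symbol(x[nzchar(trimws(x))])))
}

#' Read and write GMT term catalogs
#'
#' GMT ("gene matrix transposed") holds one term per line: term id,
#' description, then member genes, all tab-separated. The catalog is
#' represented as a named list of character vectors of gene symbols, with
#' term descriptions in a `"descriptions"` attribute (named character
#' vector). Hand-rolled rather than delegated so the description column
#' survives a round trip.
#'
#' @param path File path.
#' @param catalog Named list of character vectors (term id -> genes).
#' @param descriptions Optional named character vector of term
#'   descriptions; defaults to the term ids.
#' @return `read_gmt` returns the catalog list; `write_gmt` returns
#'   `path` invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(structure(list(), descriptions = character(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) {
    stopf("malformed GMT line %d: fewer than 3 fields", bad[1])
  }
  ids <- vapply(parts, `[[`, "", 1L)
  assert_that(!anyDuplicated(ids), "duplicate term ids in GMT")
  desc <- stats::setNames(vapply(parts, `[[`, "", 2L), ids)
  genes <- lapply(parts, function(p) unique(canon_symbol(p[-(1:2)])))
  structure(stats::setNames(genes, ids), descriptions = desc)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(catalog, path, descriptions = NULL) {
  descriptions <- descriptions %||% attr(catalog, "descriptions") %||%
    stats::setNames(names(catalog), names(catalog))
  lines <- vapply(names(catalog), function(id) {
    paste(c(id, unname(descriptions[id]), catalog[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
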