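#' Weighted protein-protein interaction network
#'
#' An undirected simple graph over upper-cased gene symbols. Each edge
#' carries a combined association score (CAS) in \[0, 1\] expressing
#' confidence in the interaction. Self-loops are dropped (with a logged
#' count) and duplicate pairs are collapsed keeping the maximum CAS, so
#' the invariants "simple, undirected, CAS in \[0,1\]" hold by
#' construction. Edges are stored canonically (`from < to`, rows sorted),
#' which makes identical networks byte-identical on disk regardless of
#' input order.
#'
#' @param edges Data frame with columns `from`, `to`, `cas` (or the first
#'   three columns in that order). May have zero rows.
#' @param nodes Optional character vector of node symbols to retain even
#'   when isolated; endpoints of `edges` are always included.
#' @param provenance Label recording where the network came from
#'   (e.g. `"diseaseA"`, `"diseaseB"`, `"merged"`).
#' @return An object of class `ppi_network`: list with `nodes` (sorted
#'   character), `edges` (data frame `from`, `to`, `cas`), `provenance`,
#'   and optionally `node_origin` (named character, set by
#'   [merge_networks()]).
#' @seealso [read_string_edges()], [induce_network()], [merge_networks()]
#' @export
ppi_network <- function(edges = NULL, nodes = NULL, provenance = "network") {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(0), to = character(0),
                        cas = numeric(0), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = canon_symbol(edges[[1]]),
                        to = canon_symbol(edges[[2]]),
                        cas = as.numeric(edges[[3]]),
                        stringsAsFactors = FALSE)
    assert_that(!anyNA(edges$cas), "missing CAS values")
    assert_that(all(edges$cas >= 0 & edges$cas <= 1),
                "CAS values must lie in [0, 1]")
    loops <- edges$from == edges$to
    if (any(loops)) {
      log_info("dropping %d self-loop(s)", sum(loops))
      edges <- edges[!loops, , drop = FALSE]
    }
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    # collapse duplicates keeping the maximum CAS
    key <- paste(edges$from, edges$to, sep = "\r")
    if (anyDuplicated(key)) {
      cas <- tapply(edges$cas, key, max)
      pairs <- do.call(rbind, strsplit(names(cas), "\r", fixed = TRUE))
      edges <- data.frame(from = pairs[, 1], to = pairs[, 2],
                          cas = as.numeric(cas), stringsAsFactors = FALSE)
    }
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  nodes <- sort(unique(c(canon_symbol(nodes %||% character(0)),
                         edges$from, edges$to)))
  nodes <- nodes[nzchar(nodes)]
  structure(list(nodes = nodes, edges = edges, provenance = provenance),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network '%s': %d nodes, %d edges\n",
              x$provenance, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read a STRING-dialect weighted edge table
#'
#' Expects a tab- or space-separated file with header
#' `protein1 protein2 combined_score`. Scores may be STRING-style
#' integers on 0-1000 (divided by 1000 on read) or reals already on
#' \[0, 1\]. Edges below `score_min` are dropped; duplicates keep the
#' maximum score; self-loops are dropped with a logged count.
#'
#' @param path Edge table path.
#' @param score_min Minimum CAS retained (default 0.4, the conventional
#'   "medium confidence" cut).
#' @param provenance Provenance label for the resulting network.
#' @return A [ppi_network()].
#' @export
read_string_edges <- function(path, score_min = 0.4,
                              provenance = basename(path)) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          comment.char = "")
  assert_that(ncol(df) >= 3, "edge table needs 3 columns")
  assert_that(all(c("protein1", "protein2", "combined_score") %in% names(df)),
              "edge table header must be 'protein1 protein2 combined_score'")
  score <- suppressWarnings(as.numeric(df$combined_score))
  bad <- which(is.na(score))
  if (length(bad)) {
    stopf("malformed combined_score at data line %d of %s", bad[1], path)
  }
  if (length(score) && any(score > 1)) score <- score / 1000
  out_of_range <- which(score < 0 | score > 1)
  if (length(out_of_range)) {
    stopf("combined_score out of range at data line %d of %s",
          out_of_range[1], path)
  }
  keep <- score >= score_min
  log_info("read %d edges from %s; %d pass CAS >= %g",
           length(score), path, sum(keep), score_min)
  ppi_network(data.frame(from = df$protein1[keep], to = df$protein2[keep],
                         cas = score[keep], stringsAsFactors = FALSE),
              provenance = provenance)
}

#' Write a network as a STRING-dialect edge table
#'
#' Scores are written as integers on 0-1000, the STRING convention.
#' Because CAS values are held to three decimals throughout, a
#' write-read cycle is an identity.
#'
#' @param net A [ppi_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_string_edges <- function(net, path) {
  df <- data.frame(protein1 = net$edges$from, protein2 = net$edges$to,
                   combined_score = as.integer(round(net$edges$cas * 1000)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Induce a disease network on a gene set
#'
#' Keeps exactly the query genes as nodes (members without any retained
#' interaction stay as isolated, degree-0 nodes, so node counts are
#' well-defined) and the edges with both endpoints in the query set.
#'
#' @param net A [ppi_network()].
#' @param genes Character vector of gene symbols.
#' @param provenance Provenance label for the induced network.
#' @return A [ppi_network()] whose node set is exactly `genes`.
#' @export
induce_network <- function(net, genes, provenance = net$provenance) {
  genes <- unique(canon_symbol(genes))
  keep <- net$edges$from %in% genes & net$edges$to %in% genes
  sub <- ppi_network(net$edges[keep, , drop = FALSE], nodes = genes,
                     provenance = provenance)
  n_iso <- sum(!genes %in% c(sub$edges$from, sub$edges$to))
  log_info("induced '%s': %d nodes (%d isolated), %d edges",
           provenance, length(sub$nodes), n_iso, nrow(sub$edges))
  sub
}

#' Per-node degree and weighted degree (comscore) table
#'
#' @param net A [ppi_network()].
#' @return Data frame with columns `gene`, `degree`, `comscore`, sorted
#'   by descending degree, then descending comscore, then symbol.
#' @export
node_degrees <- function(net) {
  deg <- stats::setNames(integer(length(net$nodes)), net$nodes)
  cnt <- table(c(net$edges$from, net$edges$to))
  deg[names(cnt)] <- as.integer(cnt)
  cs <- comscore(net)
  df <- data.frame(gene = net$nodes, degree = unname(deg),
                   comscore = unname(cs[net$nodes]),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$degree, -df$comscore, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Top hub genes by degree
#'
#' Ranks nodes by descending unweighted degree; ties are broken by
#' descending comscore (weighted degree), then lexicographically by
#' symbol.
#'
#' @param net A [ppi_network()].
#' @param n Number of hubs to return (default 20).
#' @return Character vector of at most `n` gene symbols, best first.
#' @export
top_hubs <- function(net, n = 20) {
  assert_that(n >= 1, "n must be >= 1")
  utils::head(node_degrees(net)$gene, n)
}

#' First-neighbor subnetwork of a gene
#'
#' The induced subgraph on a gene together with its direct interaction
#' partners (the "hub subnetwork").
#'
#' @param net A [ppi_network()].
#' @param gene A node symbol.
#' @return A [ppi_network()].
#' @export
hub_subnetwork <- function(net, gene) {
  gene <- canon_symbol(gene)
  assert_that(gene %in% net$nodes, "gene '%s' is not a node", gene)
  nb <- c(net$edges$to[net$edges$from == gene],
          net$edges$from[net$edges$to == gene])
  induce_network(net, c(gene, nb),
                 provenance = paste0(net$provenance, ":", gene))
}

#' Merge two disease networks
#'
#' Node and edge union; an edge present in both keeps the maximum CAS.
#' Each node's origin is recorded as `"A_only"`, `"B_only"` or `"both"`
#' in the `node_origin` field of the result.
#'
#' @param a,b [ppi_network()] objects over the same symbol convention.
#' @param provenance Label for the merged network.
#' @return A [ppi_network()] with a `node_origin` element.
#' @export
merge_networks <- function(a, b, provenance = "merged") {
  merged <- ppi_network(rbind(a$edges, b$edges),
                        nodes = c(a$nodes, b$nodes),
                        provenance = provenance)
  origin <- ifelse(merged$nodes %in% a$nodes & merged$nodes %in% b$nodes,
                   "both",
                   ifelse(merged$nodes %in% a$nodes, "A_only", "B_only"))
  merged$node_origin <- stats::setNames(origin, merged$nodes)
  merged
}

#' Cross-talk genes between two diseases
#'
#' The genes shared by one disease's differential-expression set and the
#' other disease's curated gene catalog: the exact set intersection.
#'
#' @param degs Character vector of differentially expressed genes.
#' @param disease_genes Character vector from the curated catalog.
#' @return Sorted character vector of shared symbols.
#' @export
cross_talk_genes <- function(degs, disease_genes) {
  sort(intersect(unique(canon_symbol(degs)),
                 unique(canon_symbol(disease_genes))))
}

#' Convert to igraph / export GraphML
#'
#' `as_igraph` returns the network as an [igraph::graph_from_data_frame()]
#' object with a `cas` edge attribute and (when present) an `origin` node
#' attribute. `write_graphml` exports it, which is how module and
#' subnetwork figures are meant to be drawn downstream.
#'
#' @param net A [ppi_network()].
#' @param origin Optional named character vector of per-node origin
#'   labels overriding `net$node_origin`.
#' @param path GraphML output path.
#' @return `as_igraph`: an igraph object. `write_graphml`: `path`,
#'   invisibly.
#' @export
as_igraph <- function(net, origin = NULL) {
  origin <- origin %||% net$node_origin
  verts <- data.frame(name = net$nodes, stringsAsFactors = FALSE)
  if (!is.null(origin)) {
    verts$origin <- unname(origin[net$nodes])
  }
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = verts)
}

#' @rdname as_igraph
#' @export
write_graphml <- function(net, path, origin = NULL) {
  igraph::write_graph(as_igraph(net, origin), path, format = "graphml")
  invisible(path)
}

#' Topology summary of a network
#'
#' @param net A [ppi_network()].
#' @return A one-row data frame: `nodes`, `edges`, `degree_min`,
#'   `degree_median`, `degree_max`, `isolated`.
#' @export
summarize_topology <- function(net) {
  if (length(net$nodes) == 0L) {
    return(data.frame(nodes = 0L, edges = 0L, degree_min = 0L,
                      degree_median = 0, degree_max = 0L, isolated = 0L))
  }
  deg <- node_degrees(net)$degree
  data.frame(nodes = length(net$nodes), edges = nrow(net$edges),
             degree_min = min(deg), degree_median = stats::median(deg),
             degree_max = max(deg), isolated = sum(deg == 0L))
}
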