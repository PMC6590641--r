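# adjacency list (named list of neighbor vectors) for a ppi_network
adjacency_list <- function(net) {
  adj <- stats::setNames(vector("list", length(net$nodes)), net$nodes)
  for (v in net$nodes) adj[[v]] <- character(0)
  if (nrow(net$edges)) {
    nb <- split(c(net$edges$to, net$edges$from),
                c(net$edges$from, net$edges$to))
    adj[names(nb)] <- lapply(nb, function(x) sort(unique(x)))
  }
  adj
}

# restrict an adjacency list to a node subset
restrict_adj <- function(adj, nodes) {
  lapply(adj[nodes], intersect, nodes)
}

edge_count <- function(adj) sum(lengths(adj)) / 2

graph_density <- function(adj) {
  n <- length(adj)
  if (n < 2) return(0)
  2 * edge_count(adj) / (n * (n - 1))
}

# highest non-empty k-core of an adjacency list, by minimum-degree
# peeling (classic core decomposition)
highest_kcore_adj <- function(adj) {
  n <- length(adj)
  if (n == 0) return(list(k = 0L, core = character(0)))
  coreness <- stats::setNames(integer(n), names(adj))
  deg <- lengths(adj)
  alive <- stats::setNames(rep(TRUE, n), names(adj))
  k_cur <- 0L
  for (step in seq_len(n)) {
    cand <- names(deg)[alive]
    v <- cand[which.min(deg[cand])]   # ties: first in (sorted) node order
    k_cur <- max(k_cur, as.integer(deg[v]))
    coreness[v] <- k_cur
    alive[v] <- FALSE
    nb <- adj[[v]]
    nb <- nb[alive[nb]]
    deg[nb] <- deg[nb] - 1L
  }
  k_max <- max(coreness)
  list(k = k_max, core = sort(names(coreness)[coreness == k_max]))
}

#' Highest k-core of a network
#'
#' The maximum `k` for which the k-core (maximal subgraph with all
#' within-subgraph degrees >= k) is non-empty, found by iterative
#' minimum-degree peeling, together with that core's node set.
#'
#' @param net A [ppi_network()].
#' @return List with `k` (integer, 0 for an empty graph) and `core`
#'   (sorted character vector of node symbols).
#' @export
highest_kcore <- function(net) {
  highest_kcore_adj(adjacency_list(net))
}

# vertex weights for all nodes at once
mcode_vertex_weights <- function(net) {
  adj <- adjacency_list(net)
  w <- stats::setNames(numeric(length(adj)), names(adj))
  for (v in names(adj)) {
    nbhd <- c(v, adj[[v]])
    sub <- restrict_adj(adj, nbhd)
    kc <- highest_kcore_adj(sub)
    if (kc$k == 0L || length(kc$core) < 2) next
    core_adj <- restrict_adj(sub, kc$core)
    w[v] <- kc$k * graph_density(core_adj)
  }
  w
}

#' MCODE vertex weight of a gene
#'
#' The local density weighting of the Molecular Complex Detection
#' scheme: the highest k-core of the node's closed neighborhood is
#' found, and the weight is that core's `k` multiplied by the core's
#' edge density `2E / (n (n - 1))`. Isolated nodes weigh 0. Edge scores
#' are ignored: the weighting is purely topological.
#'
#' @param net A [ppi_network()].
#' @param v A node symbol.
#' @return A single numeric weight.
#' @export
mcode_vertex_weight <- function(net, v) {
  v <- canon_symbol(v)
  assert_that(v %in% net$nodes, "gene '%s' is not a node", v)
  adj <- adjacency_list(net)
  nbhd <- c(v, adj[[v]])
  sub <- restrict_adj(adj, nbhd)
  kc <- highest_kcore_adj(sub)
  if (kc$k == 0L || length(kc$core) < 2) return(0)
  kc$k * graph_density(restrict_adj(sub, kc$core))
}

haircut_members <- function(adj, members) {
  repeat {
    sub <- restrict_adj(adj, members)
    deg <- lengths(sub)
    drop <- names(deg)[deg < 2]
    if (!length(drop) || !length(members)) break
    members <- setdiff(members, drop)
    if (length(members) == 0) break
  }
  members
}

#' Detect dense molecular complexes (MCODE-style)
#'
#' Seeded graph clustering on topology alone. All nodes are weighted by
#' [mcode_vertex_weight()]; seeds are taken in descending weight order
#' (ties broken lexicographically by symbol); from each still-unused
#' seed, neighbors are included breadth-first while their weight is at
#' least `(1 - vwp)` times the seed weight, and every node can belong
#' to at most one complex. Post-processing: `haircut` iteratively
#' removes members with fewer than two within-complex interactions;
#' `fluff` (off by default) then adds boundary neighbors whose
#' closed-neighborhood density exceeds `fluff_density` (fluffed members
#' may be shared between complexes). Complexes with fewer than two
#' members are discarded. Each complex is scored density x size of its
#' induced subgraph, and the list is returned in descending score order.
#'
#' @param net A [ppi_network()].
#' @param vwp Vertex weight percentage, the expansion tolerance in
#'   \[0, 1) (default 0.2).
#' @param haircut Remove singly-connected members (default `TRUE`).
#' @param fluff Add dense boundary neighbors (default `FALSE`).
#' @param fluff_density Density threshold for fluff (default 0.5).
#' @return List of `complex_module` objects: each a list with `members`
#'   (sorted character), `seed`, `size`, `density`, `score`.
#' @export
mcode_complexes <- function(net, vwp = 0.2, haircut = TRUE, fluff = FALSE,
                            fluff_density = 0.5) {
  assert_that(vwp >= 0 && vwp < 1, "vwp must lie in [0, 1)")
  adj <- adjacency_list(net)
  w <- mcode_vertex_weights(net)
  seeds <- names(w)[order(-w, names(w))]
  used <- stats::setNames(rep(FALSE, length(w)), names(w))
  out <- list()
  for (s in seeds) {
    if (used[s] || w[s] <= 0) next
    thresh <- (1 - vwp) * w[s]
    members <- s
    used[s] <- TRUE
    frontier <- s
    while (length(frontier)) {
      nxt <- character(0)
      for (v in frontier) {
        for (u in adj[[v]]) {
          if (!used[u] && w[u] >= thresh) {
            used[u] <- TRUE
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
    }
    if (haircut) members <- haircut_members(adj, members)
    if (fluff && length(members)) {
      boundary <- setdiff(sort(unique(unlist(adj[members]))), members)
      add <- boundary[vapply(boundary, function(u) {
        nbhd <- c(u, adj[[u]])
        graph_density(restrict_adj(adj, nbhd)) > fluff_density
      }, TRUE)]
      members <- c(members, add)
    }
    if (length(members) < 2) next
    if (!s %in% members) {
      # haircut removed the original seed: re-seed with the
      # heaviest remaining member so seed %in% members always holds
      s <- members[order(-w[members], members)][1]
    }
    sub <- restrict_adj(adj, members)
    dens <- graph_density(sub)
    out[[length(out) + 1]] <- structure(
      list(members = sort(members), seed = s, size = length(members),
           density = dens, score = dens * length(members)),
      class = "complex_module")
  }
  scores <- vapply(out, function(m) m$score, 0)
  seeds_of <- vapply(out, function(m) m$seed, "")
  out[order(-scores, seeds_of)]
}

#' @export
print.complex_module <- function(x, ...) {
  cat(sprintf("complex_module: %d members, density %.3f, score %.3f (seed %s)\n",
              x$size, x$density, x$score, x$seed))
  invisible(x)
}

#' Annotate module members by disease origin
#'
#' Labels every member of a complex as `common`, `diseaseA_only` or
#' `diseaseB_only`. The three sets must be pairwise disjoint and
#' together cover the module.
#'
#' @param module A `complex_module` from [mcode_complexes()].
#' @param common Genes present in both disease networks.
#' @param onlyA Genes only in the disease-A network.
#' @param onlyB Genes only in the disease-B network.
#' @return The module, augmented with `node_origin` (named character)
#'   and `origin_counts` (named integer: common / diseaseA_only /
#'   diseaseB_only).
#' @export
annotate_module <- function(module, common, onlyA, onlyB) {
  common <- unique(canon_symbol(common))
  onlyA <- unique(canon_symbol(onlyA))
  onlyB <- unique(canon_symbol(onlyB))
  all3 <- c(common, onlyA, onlyB)
  assert_that(!anyDuplicated(all3),
              "origin sets must be pairwise disjoint")
  missing <- setdiff(module$members, all3)
  assert_that(length(missing) == 0,
              "member(s) not covered by any origin set: %s",
              paste(missing, collapse = ", "))
  origin <- ifelse(module$members %in% common, "common",
                   ifelse(module$members %in% onlyA, "diseaseA_only",
                          "diseaseB_only"))
  module$node_origin <- stats::setNames(origin, module$members)
  module$origin_counts <- c(
    common = sum(origin == "common"),
    diseaseA_only = sum(origin == "diseaseA_only"),
    diseaseB_only = sum(origin == "diseaseB_only"))
  module
}

#' Write detected modules as a TSV and per-module GraphML files
#'
#' @param modules List of (annotated) `complex_module` objects.
#' @param net The network the modules were detected in.
#' @param path TSV path (module_id, rank, score, size, density, seed,
#'   origin counts, members).
#' @param graphml_dir Optional directory for one GraphML per module,
#'   with an `origin` node attribute when modules are annotated.
#' @return `path`, invisibly.
#' @export
write_modules <- function(modules, net, path, graphml_dir = NULL) {
  rows <- lapply(seq_along(modules), function(i) {
    m <- modules[[i]]
    oc <- m$origin_counts %||% c(common = NA_integer_,
                                 diseaseA_only = NA_integer_,
                                 diseaseB_only = NA_integer_)
    data.frame(module_id = sprintf("M%02d", i), rank = i,
               score = m$score, size = m$size, density = m$density,
               seed = m$seed, n_common = oc[["common"]],
               n_diseaseA_only = oc[["diseaseA_only"]],
               n_diseaseB_only = oc[["diseaseB_only"]],
               members = paste(m$members, collapse = ","),
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(module_id = character(0), rank = integer(0),
               score = numeric(0), size = integer(0), density = numeric(0),
               seed = character(0), n_common = integer(0),
               n_diseaseA_only = integer(0), n_diseaseB_only = integer(0),
               members = character(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(graphml_dir) && length(modules)) {
    dir.create(graphml_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(modules)) {
      m <- modules[[i]]
      sub <- induce_network(net, m$members,
                            provenance = sprintf("module_%02d", i))
      write_graphml(sub, file.path(graphml_dir, sprintf("module_%02d.graphml", i)),
                    origin = m$node_origin)
    }
  }
  invisible(path)
}
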