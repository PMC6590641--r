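#' Pipeline configuration
#'
#' Collects the input paths and tuning thresholds of a full cross-disease
#' run. The design is asymmetric by construction: disease A enters as one
#' or more two-group expression datasets (screened to a DEG set), disease
#' B as a curated gene list.
#'
#' @param expression Character vector of expression TSV paths (one or
#'   more datasets for disease A).
#' @param groups Character vector of sample-to-group TSV paths, parallel
#'   to `expression`.
#' @param disease_genes Path to the disease-B gene list (one symbol per
#'   line).
#' @param edges Path to the STRING-dialect weighted edge table.
#' @param catalog Named character vector of GMT paths (names label the
#'   catalogs, e.g. `c(BP = "go_bp.gmt", pathway = "kegg.gmt")`); a bare
#'   path is accepted and labelled `"terms"`.
#' @param out_dir Output directory for the report bundle.
#' @param p_max,lfc_min DEG screen thresholds (strict p, inclusive
#'   |logFC|); defaults 0.05 and 1.
#' @param moderation Use empirical-Bayes variance moderation in the
#'   per-gene test (default `TRUE`).
#' @param score_min Minimum CAS kept when reading the edge table
#'   (default 0.4).
#' @param q_max,min_term Enrichment significance cutoff and minimum term
#'   size (defaults 0.05 and 3).
#' @param disease_universe Background for the disease-list enrichment:
#'   `"measured"` (the expression universe, the default) or `"catalog"`
#'   (all catalog genes plus the disease list).
#' @param k Number of comscore classes (default 5).
#' @param alpha Tukey-Kramer significance level (default 0.01).
#' @param top_n_hubs Hub list length (default 20).
#' @param vwp MCODE vertex weight percentage (default 0.2).
#' @param haircut,fluff,fluff_density MCODE post-processing options.
#' @param top_k_modules How many top-scoring modules to keep and
#'   annotate (default 3; `Inf` keeps all).
#' @param seed Integer seed recorded in the manifest (the analysis
#'   itself is deterministic; the seed matters only when the config is
#'   used to regenerate synthetic inputs).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, groups, disease_genes, edges,
                            catalog, out_dir,
                            p_max = 0.05, lfc_min = 1, moderation = TRUE,
                            score_min = 0.4, q_max = 0.05, min_term = 3,
                            disease_universe = c("measured", "catalog"),
                            k = 5, alpha = 0.01, top_n_hubs = 20,
                            vwp = 0.2, haircut = TRUE, fluff = FALSE,
                            fluff_density = 0.5, top_k_modules = 3,
                            seed = 1) {
  assert_that(length(expression) >= 1, "need at least one expression dataset")
  assert_that(length(groups) == length(expression),
              "groups paths must parallel expression paths")
  if (is.null(names(catalog))) {
    names(catalog) <- if (length(catalog) == 1) "terms" else
      sprintf("catalog%d", seq_along(catalog))
  }
  assert_that(p_max > 0 && p_max <= 1, "p_max must lie in (0, 1]")
  assert_that(lfc_min >= 0, "lfc_min must be >= 0")
  assert_that(score_min >= 0 && score_min <= 1, "score_min must lie in [0, 1]")
  assert_that(q_max > 0 && q_max <= 1, "q_max must lie in (0, 1]")
  assert_that(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  assert_that(k >= 2, "k must be >= 2")
  assert_that(vwp >= 0 && vwp < 1, "vwp must lie in [0, 1)")
  structure(list(expression = expression, groups = groups,
                 disease_genes = disease_genes, edges = edges,
                 catalog = catalog, out_dir = out_dir,
                 p_max = p_max, lfc_min = lfc_min, moderation = moderation,
                 score_min = score_min, q_max = q_max, min_term = min_term,
                 disease_universe = match.arg(disease_universe),
                 k = k, alpha = alpha, top_n_hubs = top_n_hubs,
                 vwp = vwp, haircut = haircut, fluff = fluff,
                 fluff_density = fluff_density,
                 top_k_modules = top_k_modules, seed = seed),
            class = "pipeline_config")
}

write_manifest <- function(config, path, status, extra = list()) {
  scalar_keys <- c("p_max", "lfc_min", "moderation", "score_min", "q_max",
                   "min_term", "disease_universe", "k", "alpha",
                   "top_n_hubs", "vwp", "haircut", "fluff", "fluff_density",
                   "top_k_modules", "seed")
  lines <- c(sprintf("status=%s", status),
             sprintf("expression=%s", paste(config$expression, collapse = ",")),
             sprintf("groups=%s", paste(config$groups, collapse = ",")),
             sprintf("disease_genes=%s", config$disease_genes),
             sprintf("edges=%s", config$edges),
             sprintf("catalog=%s",
                     paste(sprintf("%s:%s", names(config$catalog),
                                   config$catalog), collapse = ",")),
             vapply(scalar_keys, function(k2) {
               sprintf("%s=%s", k2, format(config[[k2]]))
             }, ""),
             vapply(names(extra), function(k2) {
               sprintf("%s=%s", k2, format(extra[[k2]]))
             }, character(1)))
  writeLines(lines, path)
}

#' Run the full cross-disease linkage pipeline
#'
#' Executes the stages in order — per-dataset differential expression
#' and the DEG screen/union; over-representation analysis of the DEG
#' set and of the disease gene list against every term catalog, with
#' shared-term detection; construction of the two disease networks from
#' the weighted edge table with topology summaries, hub ranking and
#' shared hubs; comscore classification with Tukey-Kramer specific-class
#' analysis and leader genes per network, plus shared leaders; network
#' merging and cross-talk gene extraction; and MCODE-style module
#' detection on the merged network with per-node origin annotation.
#' Every intermediate result is written to `config$out_dir`, and the run
#' is a pure function of the inputs and configuration (re-running
#' produces byte-identical files). A stage failure writes a manifest
#' marking the run incomplete, names the failed stage, and keeps the
#' partial outputs.
#'
#' @param config A [pipeline_config()].
#' @return The report bundle, invisibly: a list with elements
#'   `deg_tables`, `deg_sets`, `deg_union`, `enrichment` (per catalog,
#'   sides `A` and `B`), `shared_terms` (per catalog), `net_A`, `net_B`,
#'   `merged`, `topology`, `hubs`, `shared_hubs`, `partitions`,
#'   `leaders`, `shared_leaders`, `cross_talk`, `modules`.
#' @export
run_pipeline <- function(config) {
  for (p in c(config$expression, config$groups, config$disease_genes,
              config$edges, unname(config$catalog))) {
    assert_that(file.exists(p), "input file does not exist: %s", p)
  }
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- "setup"
  op <- function(f) file.path(out, f)
  bundle <- list()
  run <- function() {
    # --- differential expression ------------------------------------
    stage <<- "dge"
    ems <- Map(read_expression_tsv, config$expression, config$groups)
    tables <- lapply(ems, fit_gene_stats, moderation = config$moderation)
    sets <- lapply(tables, screen_degs, p_max = config$p_max,
                   lfc_min = config$lfc_min)
    for (i in seq_along(tables)) {
      write_deg_table(tables[[i]], op(sprintf("deg_table_%d.tsv", i)),
                      p_max = config$p_max, lfc_min = config$lfc_min)
    }
    deg_union <- union_degs(sets, tables)
    write_gene_list(deg_union, op("deg_union.txt"))
    universe_A <- sort(unique(unlist(lapply(ems, function(e)
      canon_symbol(rownames(e$values))))))
    disease <- read_gene_list(config$disease_genes)

    # --- enrichment ---------------------------------------------------
    stage <<- "enrich"
    catalogs <- lapply(config$catalog, read_gmt)
    universe_B <- if (config$disease_universe == "catalog") {
      sort(unique(c(unlist(lapply(catalogs, function(ct)
        unique(canon_symbol(unlist(ct))))), disease)))
    } else universe_A
    enrichment <- list()
    shared_terms <- list()
    for (nm in names(catalogs)) {
      eA <- enrich_catalog(deg_union, catalogs[[nm]], universe_A,
                           q_max = config$q_max, min_term = config$min_term)
      eB <- enrich_catalog(disease, catalogs[[nm]], universe_B,
                           q_max = config$q_max, min_term = config$min_term)
      utils::write.table(eA, op(sprintf("enrichment_%s_A.tsv", nm)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(eB, op(sprintf("enrichment_%s_B.tsv", nm)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      enrichment[[nm]] <- list(A = eA, B = eB)
      shared_terms[[nm]] <- shared_significant_terms(eA, eB)
      writeLines(shared_terms[[nm]], op(sprintf("shared_terms_%s.txt", nm)))
    }

    # --- networks -----------------------------------------------------
    stage <<- "netcore"
    ppi <- read_string_edges(config$edges, score_min = config$score_min,
                             provenance = "interactome")
    net_A <- induce_network(ppi, deg_union, provenance = "diseaseA")
    net_B <- induce_network(ppi, disease, provenance = "diseaseB")
    topology <- rbind(cbind(network = "diseaseA", summarize_topology(net_A)),
                      cbind(network = "diseaseB", summarize_topology(net_B)))
    write_string_edges(net_A, op("network_A.tsv"))
    write_string_edges(net_B, op("network_B.tsv"))
    write_graphml(net_A, op("network_A.graphml"))
    write_graphml(net_B, op("network_B.graphml"))
    hubs <- list(A = top_hubs(net_A, config$top_n_hubs),
                 B = top_hubs(net_B, config$top_n_hubs))
    shared_hubs <- sort(intersect(hubs$A, hubs$B))
    writeLines(hubs$A, op("hubs_A.txt"))
    writeLines(hubs$B, op("hubs_B.txt"))
    writeLines(shared_hubs, op("shared_hubs.txt"))
    for (h in shared_hubs) {
      write_graphml(hub_subnetwork(net_A, h),
                    op(sprintf("hub_subnetwork_A_%s.graphml", h)))
      write_graphml(hub_subnetwork(net_B, h),
                    op(sprintf("hub_subnetwork_B_%s.graphml", h)))
    }

    # --- leader genes -------------------------------------------------
    stage <<- "leadr"
    classify_or_empty <- function(net, label) {
      cs <- comscore(net)
      if (length(unique(cs)) < config$k) {
        log_info("network %s: fewer than k = %d distinct comscores; %s",
                 label, config$k, "leader analysis skipped")
        return(NULL)
      }
      tukey_kramer(kmeans_1d(cs, k = config$k), alpha = config$alpha)
    }
    partitions <- list(A = classify_or_empty(net_A, "A"),
                       B = classify_or_empty(net_B, "B"))
    leaders <- lapply(partitions, function(pt) {
      if (is.null(pt)) character(0) else
        leader_class(pt, alpha = config$alpha)$genes
    })
    for (side in c("A", "B")) {
      if (!is.null(partitions[[side]])) {
        write_class_table(partitions[[side]],
                          op(sprintf("classes_%s.tsv", side)),
                          op(sprintf("class_summary_%s.tsv", side)))
      }
      writeLines(leaders[[side]], op(sprintf("leaders_%s.txt", side)))
    }
    shared_leaders <- shared_leader_genes(leaders$A, leaders$B)
    writeLines(shared_leaders, op("shared_leaders.txt"))

    # --- merge and cross-talk ------------------------------------------
    stage <<- "crosstalk"
    merged <- merge_networks(net_A, net_B)
    write_string_edges(merged, op("network_merged.tsv"))
    write_graphml(merged, op("network_merged.graphml"))
    cross_talk <- cross_talk_genes(deg_union, disease)
    write_gene_list(cross_talk, op("cross_talk.txt"))
    topology <- rbind(topology,
                      cbind(network = "merged", summarize_topology(merged)))
    utils::write.table(topology, op("topology.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    # --- module detection ----------------------------------------------
    stage <<- "mcmod"
    modules <- mcode_complexes(merged, vwp = config$vwp,
                               haircut = config$haircut,
                               fluff = config$fluff,
                               fluff_density = config$fluff_density)
    if (is.finite(config$top_k_modules)) {
      modules <- utils::head(modules, config$top_k_modules)
    }
    origin <- merged$node_origin
    modules <- lapply(modules, function(m) {
      annotate_module(m,
                      common = names(origin)[origin == "both"],
                      onlyA = names(origin)[origin == "A_only"],
                      onlyB = names(origin)[origin == "B_only"])
    })
    write_modules(modules, merged, op("modules.tsv"),
                  graphml_dir = op("modules"))

    list(deg_tables = tables, deg_sets = sets, deg_union = deg_union,
         enrichment = enrichment, shared_terms = shared_terms,
         net_A = net_A, net_B = net_B, merged = merged,
         topology = topology, hubs = hubs, shared_hubs = shared_hubs,
         partitions = partitions, leaders = leaders,
         shared_leaders = shared_leaders, cross_talk = cross_talk,
         modules = modules)
  }
  bundle <- tryCatch(run(), error = function(e) {
    write_manifest(config, op("MANIFEST.txt"), status = "incomplete",
                   extra = list(failed_stage = stage,
                                error = conditionMessage(e)))
    stopf("pipeline failed in stage '%s': %s", stage, conditionMessage(e))
  })
  write_manifest(config, op("MANIFEST.txt"), status = "complete",
                 extra = list(
                   n_deg_union = length(bundle$deg_union),
                   n_cross_talk = length(bundle$cross_talk),
                   n_modules = length(bundle$modules),
                   n_shared_hubs = length(bundle$shared_hubs),
                   n_shared_leaders = length(bundle$shared_leaders)))
  invisible(bundle)
}
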