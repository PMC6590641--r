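#' Simulate a two-group log2 expression matrix with planted DE genes
#'
#' Generates a genes-by-samples matrix on the log2 scale with `case` and
#' `control` groups. A fraction of genes is planted as differentially
#' expressed: their case-group mean is shifted by `effect_lfc` with
#' alternating sign (so the absolute-value screen is exercised in both
#' directions). Per-gene noise is Gaussian with a per-gene standard
#' deviation drawn from a scaled inverse-chi-square spread
#' (`sigma^2 * d0 / chisq(d0)`), the variance structure that
#' empirical-Bayes moderation assumes.
#'
#' @param n_genes Number of genes (>= 1).
#' @param n_per_group Samples per group (>= 2).
#' @param de_fraction Fraction of genes planted as differential, in
#'   \[0, 1\]. Exactly `round(de_fraction * n_genes)` genes are planted.
#' @param effect_lfc Planted shift in log2 units (case minus control).
#' @param sigma Baseline noise scale in log2 units (> 0).
#' @param d0 Prior degrees of freedom of the variance spread (default 8).
#' @param seed Integer seed; the output is a pure function of the
#'   arguments and the seed.
#' @return List with `em` (an [expression_matrix()]) and `truth` (list
#'   with `de_genes`, a sorted character vector, and `de_sign`, a named
#'   vector of planted signs).
#' @examples
#' sim <- simulate_expression(100, 4, de_fraction = 0.1, seed = 1)
#' length(sim$truth$de_genes)  # 10
#' @export
simulate_expression <- function(n_genes, n_per_group, de_fraction = 0.1,
                                effect_lfc = 2, sigma = 0.3, d0 = 8,
                                seed = 1) {
  assert_that(n_genes >= 1, "n_genes must be >= 1")
  assert_that(n_per_group >= 2, "n_per_group must be >= 2")
  assert_that(de_fraction >= 0 && de_fraction <= 1,
              "de_fraction must lie in [0, 1]")
  assert_that(sigma > 0, "sigma must be positive")
  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(n_genes))
  samples <- c(sprintf("CASE%02d", seq_len(n_per_group)),
               sprintf("CTRL%02d", seq_len(n_per_group)))
  groups <- stats::setNames(rep(c("case", "control"), each = n_per_group),
                            samples)
  n_de <- round(de_fraction * n_genes)
  de_idx <- if (n_de > 0) sample.int(n_genes, n_de) else integer(0)
  de_sign <- rep_len(c(1, -1), n_de)

  baseline <- stats::runif(n_genes, 4, 12)
  gene_sd <- sigma * sqrt(d0 / stats::rchisq(n_genes, df = d0))
  shift <- numeric(n_genes)
  shift[de_idx] <- de_sign * effect_lfc

  values <- matrix(stats::rnorm(n_genes * length(samples), sd = gene_sd),
                   nrow = n_genes)
  values <- values + baseline
  values[, seq_len(n_per_group)] <- values[, seq_len(n_per_group)] + shift
  dimnames(values) <- list(genes, samples)

  truth <- list(de_genes = sort(genes[de_idx]),
                de_sign = stats::setNames(de_sign, genes[de_idx]))
  list(em = expression_matrix(values, groups), truth = truth)
}

#' Simulate a weighted interaction edge table with planted dense modules
#'
#' A planted-partition generator emulating a STRING-style edge table.
#' Module members are connected pairwise with probability `p_in`; all
#' remaining pairs appear with probability `p_out`. Combined association
#' scores are uniform on `[cas_low, cas_high]` for background edges and
#' on `[max(cas_low, 0.7), cas_high]` for within-module edges, so
#' planted modules carry a high-confidence signal recoverable by the
#' weighted-degree (comscore) stages. Scores are quantised to three
#' decimals, matching the 0-1000 integer STRING dialect, so file round
#' trips are exact.
#'
#' @param genes Character vector: the gene universe for the network.
#' @param module_spec List of planted modules. Each element is a list
#'   with `size` (member count) and `p_in` (within-module edge
#'   probability), and optionally `members` (explicit gene symbols,
#'   which must be drawn from `genes`; when absent, members are sampled).
#' @param p_out Background edge probability; must be strictly below
#'   every `p_in`.
#' @param cas_low,cas_high CAS bounds, `0 <= cas_low <= cas_high <= 1`.
#' @param seed Integer seed.
#' @return List with `edges` (data frame `protein1`, `protein2`,
#'   `combined_score` on \[0, 1\]) and `truth` (list with
#'   `planted_modules`, a list of sorted character vectors).
#' @export
simulate_ppi <- function(genes, module_spec = list(), p_out = 0.0025,
                         cas_low = 0.4, cas_high = 1, seed = 1) {
  genes <- unique(canon_symbol(genes))
  n <- length(genes)
  sizes <- vapply(module_spec, function(m) as.integer(m$size), 1L)
  p_ins <- vapply(module_spec, function(m) as.numeric(m$p_in), 1)
  assert_that(sum(sizes) <= n, "module sizes exceed the gene universe")
  assert_that(p_out >= 0 && p_out <= 1, "p_out must lie in [0, 1]")
  if (length(p_ins)) {
    assert_that(all(p_ins <= 1) && p_out < min(p_ins),
                "need p_out < min(p_in) <= 1")
  }
  assert_that(cas_low >= 0 && cas_low <= cas_high && cas_high <= 1,
              "need 0 <= cas_low <= cas_high <= 1")
  set.seed(seed)

  # assign module members: explicit members first, the rest sampled
  members <- vector("list", length(module_spec))
  pinned <- unlist(lapply(module_spec, function(m) {
    canon_symbol(m$members %||% character(0))
  }))
  assert_that(!anyDuplicated(pinned), "pinned module members overlap")
  assert_that(all(pinned %in% genes), "pinned members outside gene universe")
  pool <- setdiff(genes, pinned)
  for (i in seq_along(module_spec)) {
    m <- module_spec[[i]]
    if (!is.null(m$members)) {
      mem <- canon_symbol(m$members)
      assert_that(length(mem) == sizes[i],
                  "module %d: members length != size", i)
    } else {
      mem <- sample(pool, sizes[i])
      pool <- setdiff(pool, mem)
    }
    members[[i]] <- mem
  }
  mod_id <- stats::setNames(rep(0L, n), genes)
  for (i in seq_along(members)) mod_id[members[[i]]] <- i

  cas_mod_low <- max(cas_low, 0.7)
  quantise <- function(x, lo, hi) pmin(pmax(round(x, 3), lo), hi)

  ef <- character(0); et <- character(0); ec <- numeric(0)
  for (i in seq_along(members)) {
    mem <- sort(members[[i]])
    if (length(mem) < 2) next
    prs <- utils::combn(mem, 2)
    keep <- stats::runif(ncol(prs)) < p_ins[i]
    if (any(keep)) {
      ef <- c(ef, prs[1, keep]); et <- c(et, prs[2, keep])
      ec <- c(ec, quantise(stats::runif(sum(keep), cas_mod_low, cas_high),
                           cas_mod_low, cas_high))
    }
  }

  # background pairs: enumerate the upper triangle lazily via linear
  # indices k = 1..choose(n,2), ordered (1,2),(1,3),...,(1,n),(2,3),...
  if (n >= 2 && p_out > 0) {
    m_all <- n * (n - 1) / 2
    hit <- which(stats::runif(m_all) < p_out)
    if (length(hit)) {
      cum <- cumsum((n - 1):1)
      i_idx <- findInterval(hit - 1, c(0, cum), rightmost.closed = FALSE)
      j_idx <- hit - c(0, cum)[i_idx] + i_idx
      gi <- genes[i_idx]; gj <- genes[j_idx]
      same_mod <- mod_id[gi] != 0L & mod_id[gi] == mod_id[gj]
      gi <- gi[!same_mod]; gj <- gj[!same_mod]
      if (length(gi)) {
        ef <- c(ef, gi); et <- c(et, gj)
        ec <- c(ec, quantise(stats::runif(length(gi), cas_low, cas_high),
                             cas_low, cas_high))
      }
    }
  }

  edges <- data.frame(protein1 = ef, protein2 = et, combined_score = ec,
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$protein1, edges$protein2), , drop = FALSE]
  rownames(edges) <- NULL
  list(edges = edges,
       truth = list(planted_modules = lapply(members, sort)))
}

#' Simulate a disease gene catalog and a GMT term catalog
#'
#' Builds (a) a curated disease gene list containing exactly
#' `de_overlap` of the planted differential genes (the rest drawn from
#' the non-differential background), and (b) a GMT catalog of random
#' terms in which the first term is planted as enriched in both the
#' differential set and the disease list — the "shared pathway" fixture.
#' The planted term draws roughly a third of its members from the
#' differential-and-disease overlap, a third from differential-only
#' genes, and a third from disease-only genes.
#'
#' @param universe Character vector: all gene symbols.
#' @param n_disease Size of the disease gene list.
#' @param de_overlap How many planted differential genes the disease
#'   list must contain; `de_overlap <= min(n_disease, # planted genes)`.
#' @param truth Truth list carrying `de_genes` (e.g. from
#'   [simulate_expression()]).
#' @param n_terms Number of GMT terms.
#' @param term_size Genes per term.
#' @param seed Integer seed.
#' @return List with `disease_genes` (sorted character), `catalog`
#'   (GMT-style named list, see [read_gmt()]), and `truth` (list with
#'   `disease_genes` and `shared_terms`).
#' @export
simulate_catalogs <- function(universe, n_disease, de_overlap, truth,
                              n_terms = 50, term_size = 40, seed = 1) {
  universe <- unique(canon_symbol(universe))
  de <- intersect(canon_symbol(truth$de_genes), universe)
  assert_that(de_overlap <= min(n_disease, length(de)),
              "de_overlap must be <= min(n_disease, planted DE genes)")
  bg <- setdiff(universe, de)
  assert_that(n_disease - de_overlap <= length(bg),
              "not enough non-differential genes for the disease list")
  set.seed(seed)
  disease <- sort(c(if (de_overlap > 0) sample(de, de_overlap) else character(0),
                    sample(bg, n_disease - de_overlap)))

  overlap_pool <- intersect(de, disease)
  de_only <- setdiff(de, disease)
  dis_only <- setdiff(disease, de)
  third <- floor(term_size / 3)
  take <- function(pool, k) if (k <= 0) character(0) else
    sample(pool, min(k, length(pool)))
  shared <- unique(c(take(overlap_pool, third), take(de_only, third),
                     take(dis_only, third)))
  rest <- setdiff(universe, shared)
  shared <- sort(c(shared, take(rest, term_size - length(shared))))

  ids <- sprintf("TERM%03d", seq_len(n_terms))
  catalog <- vector("list", n_terms)
  catalog[[1]] <- shared
  for (i in seq_len(n_terms)[-1]) {
    catalog[[i]] <- sort(sample(universe, term_size))
  }
  names(catalog) <- ids
  desc <- stats::setNames(c("planted shared term",
                            rep("background term", n_terms - 1)), ids)
  attr(catalog, "descriptions") <- desc
  list(disease_genes = disease, catalog = catalog,
       truth = list(disease_genes = disease, shared_terms = ids[1]))
}

#' The default synthetic study fixture
#'
#' Assembles the complete synthetic input set for an end-to-end run,
#' emulating the structure of a two-disease linkage study: two
#' transcriptome datasets for disease A (2,000 genes, 6 case vs 6
#' control samples each, 6% and 8% of genes planted differential at
#' |log2 fold change| 2 with noise scale 0.3), a curated 300-gene
#' catalog for disease B containing 92 of the planted differential
#' genes, a sparse background interactome (background edge probability
#' 0.0025, about 5,000 edges over 2,000 genes) with planted dense
#' modules, and a 50-term GMT catalog with one planted shared term.
#'
#' Four modules are planted in the interactome as nested density
#' strata, the hierarchical structure real interactomes show. The
#' highest stratum — an 18-gene clique inside the
#' differential-and-disease overlap, the fixture's leader module — is
#' what the comscore leader stage is expected to recover; two
#' intermediate cliques (13 and 8 genes) among differential-only genes
#' occupy the intermediate comscore classes, and a 10-gene module
#' (within-module edge probability 0.9) among disease-only genes gives
#' the disease-B network its own dense complex. All planted modules are
#' dense enough for the module detector to recover.
#'
#' @param seed Integer master seed; per-stream sub-seeds are derived
#'   from it.
#' @return List with `em1`, `em2` (expression matrices), `edges`
#'   (edge table data frame), `disease_genes`, `catalog`, and `truth`
#'   (combined: `de_genes`, `de_genes_1`, `de_genes_2`,
#'   `planted_modules`, `leader_module`, `disease_genes`,
#'   `shared_terms`, `planted_cross_talk`).
#' @export
default_fixture <- function(seed = 1) {
  s1 <- simulate_expression(2000, 6, de_fraction = 0.06, effect_lfc = 2,
                            sigma = 0.3, seed = derive_seed(seed, 1))
  s2 <- simulate_expression(2000, 6, de_fraction = 0.08, effect_lfc = 2,
                            sigma = 0.3, seed = derive_seed(seed, 2))
  universe <- rownames(s1$em$values)
  de_union <- sort(union(s1$truth$de_genes, s2$truth$de_genes))

  cat_sim <- simulate_catalogs(universe, n_disease = 300, de_overlap = 92,
                               truth = list(de_genes = de_union),
                               n_terms = 50, term_size = 40,
                               seed = derive_seed(seed, 3))
  overlap <- intersect(de_union, cat_sim$disease_genes)
  dis_only <- setdiff(cat_sim$disease_genes, de_union)

  set.seed(derive_seed(seed, 4))
  mod_lead <- sample(overlap, 18)
  # distractor strata live among differential-only genes so no planted
  # module pair can co-occur in (and be bridged through) the same
  # induced disease network
  pool <- setdiff(de_union, union(mod_lead, cat_sim$disease_genes))
  mod_mid <- sample(pool, 13)
  pool <- setdiff(pool, mod_mid)
  mod_low <- sample(pool, 8)
  mod_b <- sample(dis_only, 10)
  ppi <- simulate_ppi(universe,
                      module_spec = list(
                        list(size = 18, p_in = 1, members = mod_lead),
                        list(size = 13, p_in = 1, members = mod_mid),
                        list(size = 8, p_in = 1, members = mod_low),
                        list(size = 10, p_in = 0.95, members = mod_b)),
                      p_out = 0.0025, cas_low = 0.4, cas_high = 1,
                      seed = derive_seed(seed, 5))

  truth <- list(de_genes = de_union,
                de_genes_1 = s1$truth$de_genes,
                de_genes_2 = s2$truth$de_genes,
                planted_modules = ppi$truth$planted_modules,
                leader_module = ppi$truth$planted_modules[[1]],
                disease_genes = cat_sim$disease_genes,
                shared_terms = cat_sim$truth$shared_terms,
                planted_cross_talk = overlap)
  list(em1 = s1$em, em2 = s2$em, edges = ppi$edges,
       disease_genes = cat_sim$disease_genes, catalog = cat_sim$catalog,
       truth = truth)
}

#' Write a fixture to disk in the pipeline's input formats
#'
#' Expression matrices and group labels go to TSV, the disease list to a
#' one-symbol-per-line TXT, the edge table to a STRING-dialect TSV
#' (integer scores on 0-1000), and the term catalog to GMT.
#'
#' @param fixture A list as returned by [default_fixture()].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, suitable for [pipeline_config()].
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_expression_tsv(fixture$em1, p("expr1.tsv"), p("groups1.tsv"))
  write_expression_tsv(fixture$em2, p("expr2.tsv"), p("groups2.tsv"))
  df <- data.frame(protein1 = fixture$edges$protein1,
                   protein2 = fixture$edges$protein2,
                   combined_score =
                     as.integer(round(fixture$edges$combined_score * 1000)))
  utils::write.table(df, p("edges.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_gene_list(fixture$disease_genes, p("disease_genes.txt"))
  write_gmt(fixture$catalog, p("terms.gmt"))
  list(expression = c(p("expr1.tsv"), p("expr2.tsv")),
       groups = c(p("groups1.tsv"), p("groups2.tsv")),
       edges = p("edges.tsv"),
       disease_genes = p("disease_genes.txt"),
       catalog = p("terms.gmt"))
}
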