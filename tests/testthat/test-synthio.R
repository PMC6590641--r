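test_that("simulate_expression plants exactly the requested genes and is reproducible", {
  sim <- simulate_expression(200, 4, de_fraction = 0.1, seed = 7)
  expect_s3_class(sim$em, "expression_matrix")
  expect_length(sim$truth$de_genes, 20)
  expect_true(all(sim$truth$de_genes %in% rownames(sim$em$values)))

  # no planted effect
  none <- simulate_expression(50, 3, de_fraction = 0, seed = 1)
  expect_length(none$truth$de_genes, 0)

  # determinism: same seed, bit-identical
  again <- simulate_expression(200, 4, de_fraction = 0.1, seed = 7)
  expect_identical(sim$em$values, again$em$values)
  expect_identical(sim$truth, again$truth)
  other <- simulate_expression(200, 4, de_fraction = 0.1, seed = 8)
  expect_false(identical(sim$em$values, other$em$values))
})

test_that("planted effects land near the requested log fold change", {
  sim <- simulate_expression(2000, 6, de_fraction = 0.1, effect_lfc = 2,
                             sigma = 0.5, seed = 1)
  em <- sim$em
  lfc <- rowMeans(em$values[, em$groups == "case"]) -
    rowMeans(em$values[, em$groups == "control"])
  planted <- lfc[sim$truth$de_genes]
  sgn <- sim$truth$de_sign[sim$truth$de_genes]
  expect_lt(abs(mean(planted * sgn) - 2), 0.1)
  # alternating sign exercises both screen directions
  expect_true(any(sgn > 0) && any(sgn < 0))
})

test_that("simulate_expression rejects invalid parameters", {
  expect_error(simulate_expression(10, 1, seed = 1), "n_per_group")
  expect_error(simulate_expression(10, 4, sigma = 0, seed = 1), "sigma")
  expect_error(simulate_expression(10, 4, de_fraction = 1.2, seed = 1),
               "de_fraction")
})

test_that("simulate_ppi degenerate probabilities give exact edge sets", {
  genes <- sprintf("X%02d", 1:20)
  # p_in = 1, p_out = 0, one module of 5: exactly the 10 clique pairs
  sim <- simulate_ppi(genes, list(list(size = 5, p_in = 1)), p_out = 0,
                      seed = 3)
  expect_identical(nrow(sim$edges), 10L)
  mem <- sim$truth$planted_modules[[1]]
  expect_length(mem, 5)
  expect_true(all(sim$edges$protein1 %in% mem))
  expect_true(all(sim$edges$protein2 %in% mem))
  expect_false(any(sim$edges$protein1 == sim$edges$protein2))
  expect_identical(anyDuplicated(paste(sim$edges$protein1, sim$edges$protein2)), 0L)

  # p_out = 0 and no modules: empty table
  empty <- simulate_ppi(genes, list(), p_out = 0, seed = 1)
  expect_identical(nrow(empty$edges), 0L)

  # p_out = 1 with no modules: the complete graph (checks the linear
  # upper-triangle indexing)
  full <- simulate_ppi(genes[1:8], list(), p_out = 1, seed = 1)
  expect_identical(nrow(full$edges), as.integer(choose(8, 2)))
  key <- paste(full$edges$protein1, full$edges$protein2)
  expect_identical(anyDuplicated(key), 0L)
})

test_that("realized module density sits inside binomial 99% bounds", {
  genes <- sprintf("X%03d", 1:200)
  sim <- simulate_ppi(genes, list(list(size = 40, p_in = 0.9)),
                      p_out = 0.05, seed = 11)
  mem <- sim$truth$planted_modules[[1]]
  within <- sim$edges$protein1 %in% mem & sim$edges$protein2 %in% mem
  n_pairs <- choose(40, 2)
  bounds <- qbinom(c(0.005, 0.995), n_pairs, 0.9)
  expect_gte(sum(within), bounds[1])
  expect_lte(sum(within), bounds[2])
  # module edges carry the high-confidence CAS band
  expect_true(all(sim$edges$combined_score[within] >= 0.7))
})

test_that("simulate_ppi validates parameters and respects CAS bounds", {
  genes <- sprintf("X%02d", 1:10)
  expect_error(simulate_ppi(genes, list(list(size = 4, p_in = 0.3)),
                            p_out = 0.5, seed = 1), "p_out")
  expect_error(simulate_ppi(genes, list(list(size = 11, p_in = 1)),
                            p_out = 0, seed = 1), "module sizes")
  sim <- simulate_ppi(genes, list(), p_out = 1, cas_low = 0.5,
                      cas_high = 0.8, seed = 2)
  expect_true(all(sim$edges$combined_score >= 0.5 &
                  sim$edges$combined_score <= 0.8))
})

test_that("simulate_catalogs plants the requested overlap and a shared term", {
  universe <- sprintf("X%04d", 1:1500)
  de <- sample(universe, 260)
  sim <- simulate_catalogs(universe, n_disease = 1274, de_overlap = 92,
                           truth = list(de_genes = de), seed = 5)
  expect_length(sim$disease_genes, 1274)
  expect_length(intersect(sim$disease_genes, de), 92)
  shared <- sim$catalog[[sim$truth$shared_terms]]
  # the planted term overlaps both study sets heavily
  expect_gte(length(intersect(shared, de)), 20)
  expect_gte(length(intersect(shared, sim$disease_genes)), 20)

  none <- simulate_catalogs(universe, n_disease = 100, de_overlap = 0,
                            truth = list(de_genes = de), seed = 5)
  expect_length(intersect(none$disease_genes, de), 0)

  expect_error(simulate_catalogs(universe, n_disease = 50, de_overlap = 60,
                                 truth = list(de_genes = de), seed = 1),
               "de_overlap")
})

test_that("GMT files round-trip exactly and agree with an independent reader", {
  universe <- sprintf("X%03d", 1:100)
  sim <- simulate_catalogs(universe, 30, 5,
                           truth = list(de_genes = universe[1:20]),
                           n_terms = 8, term_size = 12, seed = 2)
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sim$catalog, path)
  back <- read_gmt(path)
  expect_identical(unclass(back)[names(sim$catalog)],
                   lapply(sim$catalog, identity))
  expect_identical(attr(back, "descriptions"),
                   attr(sim$catalog, "descriptions"))
  skip_if_not_installed("fgsea")
  via_fgsea <- fgsea::gmtPathways(path)
  expect_identical(lapply(via_fgsea, sort), lapply(unclass(back), sort))
})

test_that("fixture files round-trip through the declared dialects", {
  fx <- default_fixture(seed = 2)
  dir <- withr::local_tempdir()
  paths <- write_fixture(fx, dir)
  em <- read_expression_tsv(paths$expression[1], paths$groups[1])
  expect_equal(em$values, fx$em1$values, tolerance = 1e-12)
  expect_identical(em$groups, fx$em1$groups)
  expect_identical(read_gene_list(paths$disease_genes), fx$disease_genes)
  net <- read_string_edges(paths$edges, score_min = 0)
  expect_identical(nrow(net$edges), nrow(fx$edges))
  # three-decimal CAS quantisation makes the 0-1000 dialect lossless
  expect_equal(sort(net$edges$cas), sort(fx$edges$combined_score),
               tolerance = 1e-12)
})

test_that("fixture truth is consistent with the emitted universe", {
  fx <- default_fixture(seed = 4)
  universe <- rownames(fx$em1$values)
  tr <- fx$truth
  expect_true(all(tr$de_genes %in% universe))
  expect_true(all(tr$disease_genes %in% universe))
  expect_true(all(unlist(tr$planted_modules) %in% universe))
  # planted modules pairwise disjoint
  expect_identical(anyDuplicated(unlist(tr$planted_modules)), 0L)
  expect_identical(tr$planted_cross_talk,
                   intersect(tr$de_genes, tr$disease_genes))
  expect_length(tr$planted_cross_talk, 92)
  # bit-exact reproducibility from the master seed
  expect_identical(default_fixture(seed = 4)$truth, tr)
})
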