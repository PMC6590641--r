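test_that("comscore sums incident CAS and obeys the handshake identity", {
  net <- ppi_network(data.frame(from = c("A", "A"), to = c("B", "C"),
                                cas = c(0.5, 0.7)), nodes = "ISO")
  cs <- comscore(net)
  expect_equal(unname(cs["A"]), 1.2)
  expect_equal(unname(cs["ISO"]), 0)
  expect_equal(sum(cs), 2 * sum(net$edges$cas))
  # zero exactly on isolated nodes
  expect_identical(names(cs)[cs == 0], "ISO")
})

test_that("kmeans_1d handles the degenerate class counts", {
  x <- c(4, 1, 9, 2.5)
  pt <- kmeans_1d(x, k = 4)
  expect_equal(pt$sse, 0)
  expect_identical(sort(unname(pt$assignment)), 1:4)
  pt1 <- kmeans_1d(x, k = 1)
  expect_equal(pt1$sse, sum((x - mean(x))^2))
  expect_error(kmeans_1d(c(1, 1, 2), k = 3), "distinct")
})

test_that("kmeans_1d recovers separated blobs and matches the exhaustive optimum", {
  x <- c(0.1, 0.2, 5.0, 5.1, 10.2, 10.3, 15.0, 15.1, 15.2, 20.5, 20.6, 20.7)
  names(x) <- sprintf("g%02d", seq_along(x))
  pt <- kmeans_1d(x, k = 5)
  blobs <- split(names(x), findInterval(x, c(2.5, 7.5, 12.5, 17.5)) + 1)
  for (b in blobs) {
    expect_length(unique(pt$assignment[b]), 1)
  }
  expect_equal(pt$sse, oracle_kmeans_sse(x, 5), tolerance = 1e-12)
})

test_that("kmeans_1d classes are contiguous in sorted order and labelled by mean", {
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(sample(6:40, 1))
    k <- sample(2:5, 1)
    pt <- kmeans_1d(x, k = k)
    cls_sorted <- pt$assignment[order(x)]
    expect_true(all(diff(cls_sorted) >= 0))  # contiguity
    expect_true(all(diff(as.numeric(pt$class_means)) > 0))  # ascending means
    expect_identical(sum(pt$class_sizes), length(x))
  }
})

test_that("scaling all scores leaves the class assignment unchanged", {
  net <- random_net(40, 0.15, seed = 5)
  cs <- comscore(net)
  pt <- kmeans_1d(cs, k = 4)
  scaled <- ppi_network(transform(net$edges, cas = cas / 2), nodes = net$nodes)
  cs2 <- comscore(scaled)
  expect_equal(cs2, cs / 2, tolerance = 1e-12)
  pt2 <- kmeans_1d(cs2, k = 4)
  expect_identical(pt$assignment, pt2$assignment)
})

test_that("class_anova reproduces the hand-computed F and its invariances", {
  # classes {1,2,3} and {7,8,9}: SSB = 54, SSW = 4, F = 54 on (1, 4) df
  x <- c(1, 2, 3, 7, 8, 9)
  pt <- kmeans_1d(x, k = 2)
  an <- class_anova(pt)
  expect_equal(an$F, 54)
  expect_identical(c(an$df1, an$df2), c(1L, 4L))
  expect_equal(an$p, pf(54, 1, 4, lower.tail = FALSE), tolerance = 1e-12)

  # agreement with the standard one-way ANOVA implementation
  ow <- oneway.test(x ~ factor(pt$assignment), var.equal = TRUE)
  expect_equal(an$F, unname(ow$statistic), tolerance = 1e-12)
  expect_equal(an$p, ow$p.value, tolerance = 1e-12)

  # permuting observations leaves F unchanged
  perm <- sample(seq_along(x))
  pt_perm <- pt
  pt_perm$scores <- x[perm]
  pt_perm$assignment <- pt$assignment[perm]
  expect_equal(class_anova(pt_perm)$F, 54)

  # degenerate: zero within-class variance with distinct means
  x0 <- c(1, 1, 1, 5, 5, 5)
  pt0 <- kmeans_1d(x0, k = 2)
  an0 <- suppressMessages(class_anova(pt0))
  expect_equal(an0$p, 0)
  expect_identical(an0$F, Inf)
})

test_that("tukey_kramer reduces to Tukey HSD at equal n and letters are consistent", {
  x <- c(1.1, 1.9, 3.0, 6.8, 7.9, 9.2, 14.5, 15.5, 16.9)
  pt <- kmeans_1d(x, k = 3)
  pt <- tukey_kramer(pt, alpha = 0.01)
  an <- pt$anova
  nj <- pt$class_sizes[1]
  # equal class sizes: the Kramer SE equals the classic sqrt(MSW/n)
  hsd_q <- abs(outer(as.numeric(pt$class_means), as.numeric(pt$class_means),
                     "-")) / sqrt(an$msw / nj)
  for (r in seq_len(nrow(pt$tukey))) {
    expect_equal(pt$tukey$q[r],
                 hsd_q[pt$tukey$class_i[r], pt$tukey$class_j[r]],
                 tolerance = 1e-12)
  }
  # TukeyHSD on the same layout as a second, independent route
  fit <- aov(x ~ factor(pt$assignment))
  hsd <- TukeyHSD(fit)[[1]]
  expect_equal(sort(pt$tukey$p), sort(unname(hsd[, "p adj"])),
               tolerance = 1e-8)
  # fully separated classes carry distinct letters
  expect_identical(anyDuplicated(pt$letters), 0L)
})

test_that("tukey_kramer pairwise p matches the integration oracle on unequal n", {
  x <- c(2.0, 2.4, 2.1, 2.6,            # class 1 (n = 4)
         5.1, 5.6, 4.9,                 # class 2 (n = 3)
         8.9, 9.4, 9.1, 9.8, 9.0, 9.3)  # class 3 (n = 6)
  pt <- tukey_kramer(kmeans_1d(x, k = 3), alpha = 0.01)
  for (r in seq_len(nrow(pt$tukey))) {
    expect_equal(pt$tukey$p[r],
                 oracle_srange_upper(pt$tukey$q[r], k = 3,
                                     df = pt$anova$df2),
                 tolerance = 1e-6)
  }
})

test_that("letter display separates exactly the significant pairs", {
  set.seed(8)
  for (i in 1:10) {
    x <- rnorm(30, mean = rep(sample(1:6, 5), each = 6), sd = 0.8)
    pt <- tukey_kramer(kmeans_1d(x, k = 5), alpha = 0.05)
    tk <- pt$tukey
    share <- function(a, b) {
      any(strsplit(pt$letters[a], "")[[1]] %in%
            strsplit(pt$letters[b], "")[[1]])
    }
    for (r in seq_len(nrow(tk))) {
      expect_identical(share(tk$class_i[r], tk$class_j[r]),
                       tk$p[r] >= pt$alpha)
    }
  }
})

test_that("leader_class demands unique separation of the top class", {
  # five fully separated classes: class 5 and its members are leaders
  set.seed(2)
  x <- setNames(rep(c(0, 10, 20, 30, 40), each = 4) + rnorm(20, 0, 0.2),
                sprintf("g%02d", 1:20))
  pt <- tukey_kramer(kmeans_1d(x, k = 5), alpha = 0.01)
  ld <- leader_class(pt)
  expect_identical(ld$class, 5L)
  expect_identical(ld$genes, sort(names(x)[x > 35]))

  # top two classes indistinguishable: strict rule yields an empty set
  y <- setNames(c(1, 1.2, 0.8, 29, 31.5, 34, 30, 32.5, 35),
                sprintf("h%02d", 1:9))
  pt2 <- tukey_kramer(kmeans_1d(y, k = 3), alpha = 0.01)
  # premise: top pair non-significant at 0.01, bottom pair separated
  expect_gte(pt2$tukey$p[pt2$tukey$class_i == 2 & pt2$tukey$class_j == 3],
             0.01)
  expect_message(leader_class(pt2), "empty leader set")
  ld2 <- suppressMessages(leader_class(pt2))
  expect_identical(ld2$genes, character(0))
  expect_true(is.na(ld2$class))
})

test_that("leader genes recover the top planted high-CAS module", {
  # nested density strata: the highest stratum is the leader module,
  # the lower strata occupy the intermediate comscore classes
  genes <- sprintf("X%03d", 1:400)
  sim <- simulate_ppi(genes, list(list(size = 18, p_in = 1),
                                  list(size = 13, p_in = 1),
                                  list(size = 8, p_in = 1)),
                      p_out = 0.0025, cas_low = 0.4, cas_high = 1, seed = 13)
  net <- ppi_network(sim$edges)
  pt <- classify_comscores(net, k = 5, alpha = 0.01)
  ld <- leader_class(pt)
  planted <- sim$truth$planted_modules[[1]]
  expect_gte(length(intersect(ld$genes, planted)) / length(planted), 0.8)
})

test_that("shared_leader_genes matches the documented intersections", {
  expect_identical(shared_leader_genes(c("P", "S", "W", "X"),
                                       c("P", "S", "W", "Y")),
                   c("P", "S", "W"))
  expect_identical(shared_leader_genes("A", "B"), character(0))
  expect_identical(shared_leader_genes(c("A", "B"), c("A", "B")),
                   c("A", "B"))
})
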