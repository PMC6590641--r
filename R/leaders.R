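#' Weighted degree (comscore) of every node
#'
#' A node's comscore is the sum of the combined association scores of
#' its incident edges — its weighted number of links. Isolated nodes
#' score 0. Summed over all nodes, comscores equal twice the total edge
#' CAS (the weighted handshake identity).
#'
#' @param net A [ppi_network()].
#' @return Named numeric vector over `net$nodes`.
#' @export
comscore <- function(net) {
  cs <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  if (nrow(net$edges)) {
    acc <- tapply(c(net$edges$cas, net$edges$cas),
                  c(net$edges$from, net$edges$to), sum)
    cs[names(acc)] <- as.numeric(acc)
  }
  cs
}

#' Globally optimal one-dimensional K-means by dynamic programming
#'
#' Partitions scores into `k` classes minimising the within-class sum of
#' squares. In one dimension the optimum is a contiguous partition of
#' the sorted values, so it is computed exactly by dynamic programming —
#' no random initialisation, fully reproducible. Classes are labelled in
#' ascending order of class mean (class `k` has the highest mean).
#'
#' @param scores Numeric vector, optionally named by gene.
#' @param k Number of classes (default 5); must not exceed the number
#'   of distinct score values.
#' @return An object of class `class_partition`: list with `assignment`
#'   (integer class per score, named like `scores`), `scores`, `k`,
#'   `class_means`, `class_sizes`, and `sse` (the minimised within-class
#'   sum of squares).
#' @export
kmeans_1d <- function(scores, k = 5) {
  n <- length(scores)
  k <- as.integer(k)
  n_distinct <- length(unique(scores))
  assert_that(k >= 1, "k must be >= 1")
  assert_that(k <= n_distinct,
              "k = %d exceeds the %d distinct score values", k, n_distinct)
  ord <- order(scores)
  x <- scores[ord]
  s1 <- c(0, cumsum(x))
  s2 <- c(0, cumsum(x^2))
  cost <- matrix(Inf, k, n)
  back <- matrix(0L, k, n)
  # one class over x[1..i]
  cost[1, ] <- pmax(0, (s2[2:(n + 1)] - s2[1]) -
                       (s1[2:(n + 1)] - s1[1])^2 / seq_len(n))
  if (k > 1) {
    for (m in 2:k) {
      for (i in m:n) {
        j <- (m - 1):(i - 1)             # last index of previous class
        len <- i - j
        sm <- s1[i + 1] - s1[j + 1]
        cand <- cost[m - 1, j] + pmax(0, (s2[i + 1] - s2[j + 1]) - sm^2 / len)
        best <- which.min(cand)
        cost[m, i] <- cand[best]
        back[m, i] <- j[best]
      }
    }
  }
  # backtrack class boundaries over the sorted order
  cls_sorted <- integer(n)
  hi <- n
  for (m in k:1) {
    lo <- if (m > 1) back[m, hi] + 1L else 1L
    cls_sorted[lo:hi] <- m
    hi <- lo - 1L
  }
  assignment <- integer(n)
  assignment[ord] <- cls_sorted
  names(assignment) <- names(scores)
  structure(list(assignment = assignment, scores = scores, k = k,
                 class_means = tapply(scores, assignment, mean),
                 class_sizes = as.integer(table(assignment)),
                 sse = cost[k, n]),
            class = "class_partition")
}

#' @export
print.class_partition <- function(x, ...) {
  cat(sprintf("class_partition: %d scores in %d classes (SSE %.4g)\n",
              length(x$scores), x$k, x$sse))
  s <- data.frame(class = seq_len(x$k), n = x$class_sizes,
                  mean = as.numeric(x$class_means))
  if (!is.null(x$letters)) s$letter <- unname(x$letters)
  print(s, row.names = FALSE)
  invisible(x)
}

# within / between sums of squares of a partition
partition_ss <- function(partition) {
  x <- partition$scores
  g <- partition$assignment
  means <- tapply(x, g, mean)
  nj <- tapply(x, g, length)
  ssw <- sum((x - means[as.character(g)])^2)
  ssb <- sum(nj * (means - mean(x))^2)
  list(ssw = ssw, ssb = ssb, means = means, nj = nj,
       k = length(means), N = length(x))
}

#' One-way ANOVA of comscore by class
#'
#' Fixed-effects one-way ANOVA of the scores over the class assignment:
#' `F = MSB / MSW` on `(k - 1, N - k)` degrees of freedom. Note the
#' classes were themselves formed from these scores, so the test is
#' circular by construction; it is reproduced as the conventional
#' specific-class analysis, not as confirmatory inference.
#'
#' @param partition A `class_partition` from [kmeans_1d()].
#' @return List with `F`, `p`, `df1`, `df2`, `msw`. When every class has
#'   zero within-class variance but the means differ, `p` is reported as
#'   0 and the condition is logged; when all values are identical the
#'   statistic is undefined (`F = NaN`, `p = NA`).
#' @export
class_anova <- function(partition) {
  ss <- partition_ss(partition)
  assert_that(ss$k >= 2, "need >= 2 classes")
  assert_that(ss$N > ss$k, "need more observations than classes")
  df1 <- as.integer(ss$k - 1); df2 <- as.integer(ss$N - ss$k)
  if (ss$ssw == 0) {
    if (ss$ssb > 0) {
      log_info("ANOVA: zero within-class variance with unequal means; p = 0")
      return(list(F = Inf, p = 0, df1 = df1, df2 = df2, msw = 0))
    }
    log_info("ANOVA: all values identical; statistic undefined")
    return(list(F = NaN, p = NA_real_, df1 = df1, df2 = df2, msw = 0))
  }
  msb <- ss$ssb / df1
  msw <- ss$ssw / df2
  Fstat <- msb / msw
  list(F = Fstat, p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2, msw = msw)
}

# maximal cliques of the non-significance graph over classes, used for
# the compact letter display; k is small (default 5) so subset
# enumeration is exact
nonsig_cliques <- function(k, nonsig) {
  assert_that(k <= 15, "letter display supports at most 15 classes")
  subsets <- lapply(seq_len(2^k - 1), function(b) which(bitwAnd(b, 2^(0:(k - 1))) > 0))
  ok <- vapply(subsets, function(s) {
    if (length(s) < 2) return(TRUE)
    prs <- utils::combn(s, 2)
    all(nonsig[cbind(prs[1, ], prs[2, ])])
  }, TRUE)
  cliques <- subsets[ok]
  maximal <- vapply(seq_along(cliques), function(i) {
    !any(vapply(cliques, function(other) {
      length(other) > length(cliques[[i]]) && all(cliques[[i]] %in% other)
    }, TRUE))
  }, TRUE)
  cliques[maximal]
}

#' Tukey-Kramer pairwise comparisons and compact letter display
#'
#' For every class pair computes the studentized-range statistic
#' `q = |mean_i - mean_j| / sqrt((MSW / 2) * (1/n_i + 1/n_j))`
#' referred to the studentized-range distribution with `k` groups and
#' `N - k` degrees of freedom (the Kramer adjustment for unequal class
#' sizes; with equal sizes it reduces to the ordinary Tukey HSD).
#' Letters are assigned from the maximal cliques of the
#' non-significance graph, lettered from the highest-mean class down, so
#' classes share a letter exactly when they are not significantly
#' different at `alpha`.
#'
#' @param partition A `class_partition` from [kmeans_1d()].
#' @param alpha Significance level for the letter display (default 0.01).
#' @return The partition, augmented with `anova` (see [class_anova()]),
#'   `tukey` (data frame `class_i`, `class_j`, `diff`, `q`, `p`),
#'   `letters` (character vector by class) and `alpha`.
#' @export
tukey_kramer <- function(partition, alpha = 0.01) {
  an <- class_anova(partition)
  ss <- partition_ss(partition)
  k <- ss$k
  prs <- utils::combn(k, 2)
  means <- as.numeric(ss$means)
  nj <- as.numeric(ss$nj)
  d <- abs(means[prs[1, ]] - means[prs[2, ]])
  se <- sqrt((an$msw / 2) * (1 / nj[prs[1, ]] + 1 / nj[prs[2, ]]))
  q <- d / se
  if (an$msw == 0) {
    # degenerate: identical values within every class
    p <- ifelse(d == 0, 1, 0)
    q <- ifelse(d == 0, 0, Inf)
  } else {
    p <- stats::ptukey(q, nmeans = k, df = an$df2, lower.tail = FALSE)
  }
  tukey <- data.frame(class_i = prs[1, ], class_j = prs[2, ],
                      diff = means[prs[1, ]] - means[prs[2, ]],
                      q = q, p = p)
  nonsig <- matrix(TRUE, k, k)
  nonsig[cbind(prs[1, ], prs[2, ])] <- p >= alpha
  nonsig[cbind(prs[2, ], prs[1, ])] <- p >= alpha
  cliques <- nonsig_cliques(k, nonsig)
  # letter 'a' to the clique containing the highest mean, and so on down
  cliques <- cliques[order(-vapply(cliques, function(s) max(means[s]), 0),
                           -lengths(cliques))]
  letter_of <- stats::setNames(letters[seq_along(cliques)], NULL)
  lab <- vapply(seq_len(k), function(cl) {
    in_cl <- vapply(cliques, function(s) cl %in% s, TRUE)
    paste(sort(letter_of[in_cl]), collapse = "")
  }, "")
  partition$anova <- an
  partition$tukey <- tukey
  partition$letters <- lab
  partition$alpha <- alpha
  partition
}

#' Extract the leader class and its genes
#'
#' Leader genes are the members of the highest-mean comscore class,
#' provided that class is significantly separated (pairwise Tukey-Kramer
#' p < `alpha`) from every lower-mean class — equivalently, it carries a
#' letter shared with no other class. If the top class is not uniquely
#' separated, the result is empty and a warning is logged.
#'
#' @param partition A `class_partition` processed by [tukey_kramer()].
#' @param alpha Significance level (default 0.01).
#' @return List with `class` (integer or `NA`) and `genes` (sorted
#'   character vector, possibly empty).
#' @export
leader_class <- function(partition, alpha = 0.01) {
  assert_that(!is.null(partition$tukey),
              "run tukey_kramer() before leader_class()")
  k <- partition$k
  tk <- partition$tukey
  vs_top <- tk[tk$class_i == k | tk$class_j == k, , drop = FALSE]
  if (nrow(vs_top) && all(vs_top$p < alpha)) {
    genes <- names(partition$assignment)[partition$assignment == k]
    list(class = k, genes = sort(genes))
  } else {
    log_info("no class is uniquely separated at alpha = %g; empty leader set",
             alpha)
    list(class = NA_integer_, genes = character(0))
  }
}

#' Shared leader genes of two diseases
#'
#' @param leadersA,leadersB Character vectors of leader genes.
#' @return Sorted character vector: the intersection.
#' @export
shared_leader_genes <- function(leadersA, leadersB) {
  sort(intersect(unique(canon_symbol(leadersA)),
                 unique(canon_symbol(leadersB))))
}

#' Comscore classification of a network in one call
#'
#' Convenience wrapper: [comscore()], [kmeans_1d()], [tukey_kramer()].
#'
#' @param net A [ppi_network()].
#' @param k Number of classes (default 5).
#' @param alpha Significance level for the letter display (default 0.01).
#' @return A `class_partition` with Tukey results attached.
#' @export
classify_comscores <- function(net, k = 5, alpha = 0.01) {
  tukey_kramer(kmeans_1d(comscore(net), k = k), alpha = alpha)
}

#' Write per-gene class table and per-class summary
#'
#' @param partition A `class_partition` processed by [tukey_kramer()].
#' @param path Per-gene TSV (gene, comscore, class, class_mean, letter).
#' @param summary_path Optional per-class TSV (class, n, mean, letter).
#' @return `path`, invisibly.
#' @export
write_class_table <- function(partition, path, summary_path = NULL) {
  cls <- partition$assignment
  df <- data.frame(gene = names(cls), comscore = unname(partition$scores),
                   class = unname(cls),
                   class_mean = as.numeric(partition$class_means[as.character(cls)]),
                   letter = partition$letters[cls],
                   stringsAsFactors = FALSE)
  df <- df[order(-df$class, -df$comscore, df$gene), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(summary_path)) {
    sm <- data.frame(class = seq_len(partition$k),
                     n = partition$class_sizes,
                     mean = as.numeric(partition$class_means),
                     letter = partition$letters)
    utils::write.table(sm, summary_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
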