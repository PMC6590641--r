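# Independent oracles used across the suite. Each is coded from the
# defining formula or by exhaustive enumeration, deliberately avoiding
# the code paths (and numerical methods) of the package implementation.

# --- moderated t, formula-by-formula --------------------------------
# Posterior variance s2_post = (d0 s0^2 + dg s2_g) / (d0 + dg) with
# (d0, s0^2) from the method of moments on log sample variances.
# trigamma inversion by uniroot (the package uses Newton).
oracle_moderated_t <- function(values, groups, d0_override = NULL) {
  case <- values[, groups == "case", drop = FALSE]
  ctrl <- values[, groups == "control", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  dg <- n1 + n2 - 2
  lfc <- rowMeans(case) - rowMeans(ctrl)
  s2 <- (rowSums((case - rowMeans(case))^2) +
         rowSums((ctrl - rowMeans(ctrl))^2)) / dg
  z <- log(s2)
  e <- z - digamma(dg / 2) + log(dg / 2)
  evar <- stats::var(e) - trigamma(dg / 2)
  if (!is.null(d0_override)) {
    d0 <- d0_override
    s02 <- if (d0 > 0) exp(mean(e) + digamma(d0 / 2) - log(d0 / 2)) else NA
  } else if (evar > 0) {
    half_d0 <- stats::uniroot(function(y) trigamma(y) - evar,
                              lower = 1e-8, upper = 1e8, tol = 1e-14)$root
    d0 <- 2 * half_d0
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(mean(e))
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else if (d0 == 0) s2 else
    (d0 * s02 + dg * s2) / (d0 + dg)
  tt <- lfc / sqrt(s2_post * (1 / n1 + 1 / n2))
  list(d0 = d0, s02 = s02, t = tt,
       p = 2 * stats::pt(-abs(tt), df = dg + d0), df = dg + d0,
       logFC = lfc)
}

# --- hypergeometric upper tail by exhaustive enumeration -------------
# P(|draw of size n from 1..N meets 1..K| >= k) counting all C(N, n)
# draws explicitly.
oracle_hyper_upper <- function(N, K, n, k) {
  if (n == 0) return(if (k <= 0) 1 else 0)
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# --- BH step-up from the definition ----------------------------------
# q_(i) = min over j >= i of min(1, p_(j) * m / j), mapped back through
# the sort order; explicit double loop, no cummin.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  qs <- numeric(m)
  for (i in seq_len(m)) {
    qs[i] <- min(vapply(i:m, function(j) min(1, ps[j] * m / j), 0))
  }
  out <- numeric(m)
  out[ord] <- qs
  out
}

# --- exhaustive optimal contiguous partition (1-D k-means) -----------
oracle_kmeans_sse <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  sse_block <- function(a, b) {
    v <- x[a:b]
    sum((v - mean(v))^2)
  }
  if (k == 1) return(sse_block(1, n))
  cuts <- utils::combn(n - 1, k - 1)   # cut after these sorted positions
  best <- Inf
  for (cc in seq_len(ncol(cuts))) {
    bounds <- c(0, cuts[, cc], n)
    sse <- sum(vapply(seq_len(k), function(b) {
      sse_block(bounds[b] + 1, bounds[b + 1])
    }, 0))
    best <- min(best, sse)
  }
  best
}

# --- studentized range upper tail by numerical integration -----------
# P(Q >= q) for k groups and df error degrees of freedom:
# P(Q < q) = int_0^inf f_S(s) * k int phi(z) [Phi(z) - Phi(z - q s)]^(k-1) dz ds
# with S = sqrt(chisq_df / df).
oracle_srange_upper <- function(q, k, df) {
  inner <- function(s) {
    stats::integrate(function(z) {
      k * stats::dnorm(z) *
        pmax(0, stats::pnorm(z) - stats::pnorm(z - q * s))^(k - 1)
    }, -9, 9, rel.tol = 1e-10)$value
  }
  outer <- stats::integrate(function(s) {
    vapply(s, function(si) {
      2 * si * df * stats::dchisq(si^2 * df, df) * inner(si)
    }, 0)
  }, 0, 8, rel.tol = 1e-9)
  1 - outer$value
}

# --- highest k-core by subset enumeration ----------------------------
# adj: named list of neighbor vectors; <= ~10 nodes. The union of all
# subsets whose minimum internal degree attains the maximum is the
# highest k-core.
oracle_highest_kcore <- function(adj) {
  nodes <- names(adj)
  n <- length(nodes)
  if (n == 0) return(list(k = 0L, core = character(0)))
  best_k <- 0L
  best_sets <- list(nodes)  # 0-core is everything
  for (b in seq_len(2^n - 1)) {
    s <- nodes[which(bitwAnd(b, 2^(0:(n - 1))) > 0)]
    mindeg <- min(vapply(s, function(v) length(intersect(adj[[v]], s)), 0L))
    if (mindeg > best_k) {
      best_k <- as.integer(mindeg)
      best_sets <- list(s)
    } else if (mindeg == best_k && best_k > 0L) {
      best_sets <- c(best_sets, list(s))
    }
  }
  list(k = best_k, core = sort(unique(unlist(best_sets))))
}

oracle_mcode_weight <- function(net, v) {
  edges <- net$edges
  nb <- c(v, edges$to[edges$from == v], edges$from[edges$to == v])
  keep <- edges$from %in% nb & edges$to %in% nb
  sub_edges <- edges[keep, , drop = FALSE]
  adj <- stats::setNames(lapply(nb, function(u) {
    c(sub_edges$to[sub_edges$from == u], sub_edges$from[sub_edges$to == u])
  }), nb)
  kc <- oracle_highest_kcore(adj)
  if (kc$k == 0L) return(0)
  nc <- length(kc$core)
  ec <- sum(sub_edges$from %in% kc$core & sub_edges$to %in% kc$core)
  kc$k * 2 * ec / (nc * (nc - 1))
}

# --- small random graph helpers --------------------------------------
random_edge_df <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n))
  prs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(prs)) < p
  data.frame(from = prs[1, keep], to = prs[2, keep],
             cas = round(stats::runif(sum(keep), 0.4, 1), 3),
             stringsAsFactors = FALSE)
}

random_net <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n))
  df <- random_edge_df(n, p, seed)
  ppi_network(df, nodes = nodes)
}

# clique edge data frame with constant CAS
clique_edges <- function(nodes, cas = 0.9) {
  prs <- utils::combn(nodes, 2)
  data.frame(from = prs[1, ], to = prs[2, ], cas = cas,
             stringsAsFactors = FALSE)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
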