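# Newton solve of trigamma(y) = x, needed by the method-of-moments fit
# of the variance prior. Monotone decreasing, so the iteration below
# (in 1/y space) converges from any start.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (iter in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' Per-gene two-group test with optional empirical-Bayes moderation
#'
#' For each gene computes the log2 fold change (case minus control mean)
#' and an equal-variance two-sample t-test. With `moderation = TRUE`
#' (the default) the per-gene variances are shrunk toward a common prior
#' before forming the statistic: the prior degrees of freedom `d0` and
#' prior variance `s0^2` are estimated by the method of moments on the
#' log sample variances (matching the scaled inverse-chi-square model),
#' the posterior variance is
#' `s2_post = (d0 * s0^2 + dg * s2_g) / (d0 + dg)`, and the moderated t
#' is referred to `d0 + dg` degrees of freedom. When the estimated `d0`
#' is 0 the moderated test reduces exactly to the ordinary t.
#'
#' Degenerate genes: zero pooled variance with zero fold change gives
#' p = 1 (no evidence); zero pooled variance with a nonzero fold change
#' under `moderation = FALSE` gives p = 0 and is reported in the log.
#'
#' @param em An [expression_matrix()].
#' @param moderation Logical; shrink variances before testing.
#' @return Data frame (one row per gene, input order) with columns
#'   `gene`, `logFC`, `t`, `p`, `df`.
#' @seealso [screen_degs()] for the downstream screen.
#' @export
fit_gene_stats <- function(em, moderation = TRUE) {
  case <- em$values[, em$groups == "case", drop = FALSE]
  ctrl <- em$values[, em$groups == "control", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  assert_that(n1 >= 2 && n2 >= 2, "need >= 2 samples per group")
  logfc <- rowMeans(case) - rowMeans(ctrl)
  dg <- n1 + n2 - 2
  ss <- rowSums((case - rowMeans(case))^2) +
        rowSums((ctrl - rowMeans(ctrl))^2)
  s2 <- ss / dg
  se_scale <- sqrt(1 / n1 + 1 / n2)

  if (moderation && sum(s2 > 0) >= 2) {
    pos <- s2 > 0
    z <- log(s2[pos])
    e <- z - digamma(dg / 2) + log(dg / 2)
    evar <- stats::var(e) - trigamma(dg / 2)
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s02 <- exp(mean(e))
    }
    s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else
      (d0 * s02 + dg * s2) / (d0 + dg)
    df_total <- dg + d0
    tstat <- logfc / (sqrt(s2_post) * se_scale)
    p <- 2 * stats::pt(-abs(tstat), df = df_total)
    df_out <- rep(df_total, length(s2))
    zero <- s2_post == 0
    if (any(zero)) {
      p[zero] <- ifelse(logfc[zero] == 0, 1, 0)
      tstat[zero] <- ifelse(logfc[zero] == 0, 0, Inf * sign(logfc[zero]))
    }
  } else {
    tstat <- logfc / (sqrt(s2) * se_scale)
    p <- 2 * stats::pt(-abs(tstat), df = dg)
    zero <- s2 == 0
    if (any(zero & logfc != 0)) {
      log_info("%d gene(s) with zero variance but nonzero logFC; p set to 0",
               sum(zero & logfc != 0))
    }
    p[zero] <- ifelse(logfc[zero] == 0, 1, 0)
    tstat[zero] <- ifelse(logfc[zero] == 0, 0, Inf * sign(logfc[zero]))
    df_out <- rep(dg, length(s2))
  }
  data.frame(gene = rownames(em$values), logFC = unname(logfc),
             t = unname(tstat), p = unname(p), df = unname(df_out),
             stringsAsFactors = FALSE)
}

#' Screen differentially expressed genes
#'
#' Applies the conventional screen: keep genes with p-value strictly
#' below `p_max` and absolute log2 fold change of at least `lfc_min`
#' (inclusive). No multiple-testing adjustment is applied at this stage;
#' the raw-p screen is deliberate and matched by the enrichment stage's
#' adjusted cutoffs.
#'
#' @param table Data frame from [fit_gene_stats()].
#' @param p_max Strict upper bound on p (default 0.05).
#' @param lfc_min Inclusive lower bound on |logFC| (default 1).
#' @return Sorted character vector of gene symbols passing the screen.
#' @export
screen_degs <- function(table, p_max = 0.05, lfc_min = 1) {
  assert_that(p_max > 0 && p_max <= 1, "p_max must lie in (0, 1]")
  assert_that(lfc_min >= 0, "lfc_min must be >= 0")
  keep <- table$p < p_max & abs(table$logFC) >= lfc_min
  log_info("DEG screen: %d of %d genes pass p < %g and |logFC| >= %g",
           sum(keep), nrow(table), p_max, lfc_min)
  sort(table$gene[keep])
}

#' Union of DEG sets across datasets
#'
#' Datasets are analyzed separately and their DEG sets combined by
#' identity only (de-duplicated union, no meta-analysis). A gene up in
#' one dataset and down in another is kept once; such direction
#' conflicts are reported in the log when the per-dataset tables are
#' supplied.
#'
#' @param sets List of character vectors (one DEG set per dataset).
#' @param tables Optional list of [fit_gene_stats()] tables matching
#'   `sets`, used only to report direction conflicts.
#' @return Sorted character vector: the union.
#' @export
union_degs <- function(sets, tables = NULL) {
  out <- sort(unique(unlist(sets, use.names = FALSE))) %||% character(0)
  if (!is.null(tables) && length(tables) >= 2) {
    sgn <- lapply(seq_along(tables), function(i) {
      tb <- tables[[i]]
      stats::setNames(sign(tb$logFC), tb$gene)[intersect(sets[[i]], tb$gene)]
    })
    common <- Reduce(intersect, lapply(sgn, names))
    if (length(common)) {
      mat <- vapply(sgn, function(s) s[common], numeric(length(common)))
      conflict <- apply(matrix(mat, nrow = length(common)), 1,
                        function(r) length(unique(r[r != 0])) > 1)
      if (any(conflict)) {
        log_info("union: %d gene(s) with conflicting direction kept once: %s",
                 sum(conflict),
                 paste(common[conflict], collapse = ", "))
      }
    }
  }
  out
}

#' Write a DEG table with its screen flag
#'
#' @param table Data frame from [fit_gene_stats()].
#' @param path Output TSV path.
#' @param p_max,lfc_min Screen thresholds stored alongside the flag.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(table, path, p_max = 0.05, lfc_min = 1) {
  table$is_deg <- table$p < p_max & abs(table$logFC) >= lfc_min
  utils::write.table(format(table, digits = 15, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
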