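# Edge and node weighting: 1-|cor| edge weights, Fisher r-to-z two-group
# edge p-values, per-gene Welch tests, and multiple-testing utilities.

cor_for_edges <- function(g, X) {
  nodes <- igraph::V(g)$name
  missing <- setdiff(nodes, colnames(X))
  if (length(missing))
    validation_error(sprintf("graph node(s) absent from expression columns: %s",
                             paste(missing, collapse = ", ")))
  nodes
}

#' Default co-expression edge weights, 1 - |cor|
#'
#' Assigns to every edge of `g` the weight `1 - |cor(Y_j, Y_k)|` computed on
#' the full expression matrix (Pearson, complete observations required at
#' load time). Weights lie in `[0, 1]` and are symmetric in endpoint order.
#'
#' @param g igraph object whose nodes appear as columns of `X`.
#' @param X subjects x genes numeric matrix.
#' @return `g` with edge attribute `weight` replaced.
#' @export
cor_edge_weights <- function(g, X) {
  validate_gene_graph(g)
  check_expression_matrix(X, min_subjects = 3L)
  nodes <- cor_for_edges(g, X)
  sds <- apply(X[, nodes, drop = FALSE], 2L, stats::sd)
  if (any(sds == 0))
    validation_error(sprintf("constant expression column(s): %s",
                             paste(nodes[sds == 0], collapse = ", ")))
  el <- igraph::as_edgelist(g, names = TRUE)
  r <- vapply(seq_len(nrow(el)),
              function(i) stats::cor(X[, el[i, 1L]], X[, el[i, 2L]]),
              0.0)
  igraph::E(g)$weight <- 1 - abs(r)
  g
}

#' Differential co-expression edge p-values (Fisher r-to-z)
#'
#' For each edge, the Pearson correlation is computed within each group,
#' Fisher-transformed (`atanh`), and the group difference tested with the
#' normal statistic `(z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3))`. The two-sided
#' p-value becomes the edge weight, so differentially co-expressed edges are
#' cheap for tree search.
#'
#' @param g igraph object whose nodes appear as columns of `X`.
#' @param X subjects x genes numeric matrix.
#' @param groups two-level group labels, one per subject; each group needs
#'   at least 4 subjects.
#' @param clip_r magnitude at which correlations are clipped before `atanh`
#'   so collinear pairs yield finite statistics.
#' @return `g` with edge attribute `weight` set to the p-values.
#' @export
rtoz_edge_pvalues <- function(g, X, groups, clip_r = 0.999999) {
  validate_gene_graph(g)
  check_expression_matrix(X)
  grp <- check_groups(groups, nrow(X), min_per_group = 4L)
  nodes <- cor_for_edges(g, X)
  el <- igraph::as_edgelist(g, names = TRUE)
  lv <- levels(grp)
  i1 <- grp == lv[1L]; i2 <- grp == lv[2L]
  n1 <- sum(i1); n2 <- sum(i2)
  r_in <- function(rows) {
    vapply(seq_len(nrow(el)), function(i) {
      suppressWarnings(stats::cor(X[rows, el[i, 1L]], X[rows, el[i, 2L]]))
    }, 0.0)
  }
  r1 <- r_in(i1); r2 <- r_in(i2)
  if (anyNA(r1) || anyNA(r2))
    validation_error("constant expression column within a group; cannot compute edge correlations")
  r1 <- clip_correlation(r1, clip_r); r2 <- clip_correlation(r2, clip_r)
  stat <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- 2 * stats::pnorm(-abs(stat))
  p[p == 0] <- .Machine$double.xmin   # keep weights strictly positive
  igraph::E(g)$weight <- p
  g
}

#' Per-gene two-group statistics (Welch t-test + BH)
#'
#' Welch's unequal-variance t-test per gene with Benjamini-Hochberg
#' adjustment across all genes. Genes with zero variance in both groups are
#' untestable: they are flagged `degenerate`, keep a missing raw p-value and
#' receive adjusted p = 1, so the output always has one row per input gene.
#'
#' The effect sign is `sign(mean(second level) - mean(first level))`; with
#' labels ordered control, case this is the usual case-minus-control sign.
#'
#' @param X subjects x genes numeric matrix.
#' @param groups two-level labels, at least 2 subjects per group.
#' @return data.frame with columns `gene`, `sign`, `p`, `p_adj`, `flag`.
#' @export
node_group_stats <- function(X, groups) {
  check_expression_matrix(X, min_subjects = 4L)
  grp <- check_groups(groups, nrow(X), min_per_group = 2L)
  lv <- levels(grp)
  X1 <- X[grp == lv[1L], , drop = FALSE]
  X2 <- X[grp == lv[2L], , drop = FALSE]
  n1 <- nrow(X1); n2 <- nrow(X2)
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  v1 <- apply(X1, 2L, stats::var); v2 <- apply(X2, 2L, stats::var)
  se2 <- v1 / n1 + v2 / n2
  degen <- se2 == 0
  tval <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tval), df)
  p[degen] <- NA_real_
  p_adj <- rep(1.0, ncol(X))
  if (any(!degen)) p_adj[!degen] <- bh_adjust(p[!degen])
  data.frame(gene = colnames(X),
             sign = ifelse(degen, 0, sign(m2 - m1)),
             p = p, p_adj = p_adj,
             flag = ifelse(degen, "degenerate", "ok"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Direct implementation of the step-up recursion: sorted p-values are
#' scaled by `m / rank`, cumulative minima taken from the largest down, and
#' results capped at 1; input order is preserved.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    validation_error("p-values must lie in [0, 1] with no missing values")
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

#' Bonferroni-style combination of p-values
#'
#' `kind = "paths"` combines K path p-values as `K * min(p)`;
#' `kind = "two_sided_pair"` combines an activation/inhibition pair as
#' `2 * min(P+, P-)`. Both are capped at 1.
#'
#' @param p numeric p-values; exactly two for `two_sided_pair`.
#' @param kind combination rule.
#' @return a single combined p-value.
#' @export
bonferroni_combine <- function(p, kind = c("paths", "two_sided_pair")) {
  kind <- match.arg(kind)
  if (length(p) == 0L) validation_error("empty p-value vector")
  if (anyNA(p) || any(p < 0 | p > 1))
    validation_error("p-values must lie in [0, 1]")
  if (kind == "two_sided_pair" && length(p) != 2L)
    validation_error("'two_sided_pair' requires exactly two p-values")
  k <- if (kind == "paths") length(p) else 2
  min(1, k * min(p))
}
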