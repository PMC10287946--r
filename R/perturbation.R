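# Group-perturbation statistics on a recovered directed tree: per-node SEM
# regressions with a group covariate (activation / inhibition p-values, DEG
# counts) and per-path average causal effect (ACE) group-difference tests
# with Bonferroni-style combinations.

#' Fit the tree-structured SEM with a group covariate
#'
#' For every non-root node `j`, ordinary least squares of `Y_j` on its
#' parent and a 0/1 group indicator (second factor level = 1); the root is
#' regressed on the group alone. One-sided p-values for the group
#' coefficient gamma come from its t statistic: `p_plus` tests activation
#' (gamma > 0), `p_minus` inhibition. Degenerate designs (constant parent
#' or child) are flagged and given neutral p-values.
#'
#' @param t a [directed_tree()] whose nodes are columns of `X`.
#' @param X subjects x genes numeric matrix.
#' @param groups two-level labels, at least 3 subjects per group.
#' @return object of class `sem_fit`: data.frame with one row per node
#'   (`node`, `parent`, `beta`, `gamma`, `sigma`, `t`, `df`, `p_plus`,
#'   `p_minus`, `p_two`, `flag`).
#' @export
fit_tree_sem <- function(t, X, groups) {
  stopifnot(inherits(t, "directed_tree"))
  check_expression_matrix(X, min_subjects = 6L)
  grp <- check_groups(groups, nrow(X), min_per_group = 3L)
  missing <- setdiff(t$nodes, colnames(X))
  if (length(missing))
    validation_error(sprintf("tree node(s) absent from data: %s",
                             paste(missing, collapse = ", ")))
  z <- as.numeric(grp == levels(grp)[2L])

  rows <- lapply(t$nodes, function(j) {
    pa <- t$parent[[j]]
    y <- X[, j]
    degenerate <- stats::sd(y) == 0 || (!is.na(pa) && stats::sd(X[, pa]) == 0)
    if (degenerate) {
      return(data.frame(node = j, parent = if (is.na(pa)) NA_character_ else pa,
                        beta = NA_real_, gamma = NA_real_, sigma = NA_real_,
                        t = NA_real_, df = NA_real_,
                        p_plus = 0.5, p_minus = 0.5, p_two = 1,
                        flag = "degenerate", stringsAsFactors = FALSE))
    }
    fit <- if (is.na(pa)) stats::lm(y ~ z) else stats::lm(y ~ X[, pa] + z)
    cf <- summary(fit)$coefficients
    gi <- nrow(cf)                         # group term is last
    tval <- cf[gi, "t value"]
    df <- fit$df.residual
    data.frame(node = j, parent = if (is.na(pa)) NA_character_ else pa,
               beta = if (is.na(pa)) NA_real_ else cf[2L, "Estimate"],
               gamma = cf[gi, "Estimate"],
               sigma = stats::var(stats::residuals(fit)),
               t = tval, df = df,
               p_plus = stats::pt(tval, df, lower.tail = FALSE),
               p_minus = stats::pt(tval, df, lower.tail = TRUE),
               p_two = 2 * stats::pt(-abs(tval), df),
               flag = "ok", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "group_levels") <- levels(grp)
  class(out) <- c("sem_fit", class(out))
  out
}

#' Gene-set perturbation summary of a tree SEM fit
#'
#' Reports (i) the DEG count — nodes whose two-sided group p-value survives
#' Benjamini-Hochberg at 0.05; (ii) the module activation and inhibition
#' p-values `P+` and `P-`, obtained by Stouffer combination of the per-node
#' one-sided z scores; and (iii) the two-sided module p-value
#' `2 * min(P+, P-)` capped at 1.
#'
#' @param fit a `sem_fit` from [fit_tree_sem()].
#' @param deg_alpha BH threshold for the DEG count.
#' @return list with `deg_count`, `p_activation`, `p_inhibition`, `p_node`,
#'   and the per-node `table` (with `p_adj` column added).
#' @export
gsa_summary <- function(fit, deg_alpha = 0.05) {
  stopifnot(inherits(fit, "sem_fit"))
  p2 <- fit$p_two
  p_adj <- bh_adjust(pmin(pmax(p2, 0), 1))
  deg_count <- sum(p_adj < deg_alpha)
  eps <- 1e-15
  zp <- stats::qnorm(pmin(pmax(fit$p_plus, eps), 1 - eps), lower.tail = FALSE)
  zm <- stats::qnorm(pmin(pmax(fit$p_minus, eps), 1 - eps), lower.tail = FALSE)
  n <- length(zp)
  p_act <- stats::pnorm(sum(zp) / sqrt(n), lower.tail = FALSE)
  p_inh <- stats::pnorm(sum(zm) / sqrt(n), lower.tail = FALSE)
  tab <- fit
  tab$p_adj <- p_adj
  list(deg_count = deg_count,
       p_activation = p_act,
       p_inhibition = p_inh,
       p_node = bonferroni_combine(c(p_act, p_inh), kind = "two_sided_pair"),
       table = tab)
}

# per-edge standardized OLS coefficients for one group of subjects
edge_coefs <- function(t, X) {
  kids <- t$nodes[t$nodes != t$root]
  n <- nrow(X)
  Xs <- scale(X[, t$nodes, drop = FALSE])
  beta <- se <- stats::setNames(numeric(length(kids)), kids)
  for (j in kids) {
    r <- stats::cor(Xs[, j], Xs[, t$parent[[j]]])
    beta[j] <- r
    se[j] <- sqrt(max(1 - r^2, 0) / (n - 2))
  }
  list(beta = beta, se = se)
}

# delta-method variance of a product of independent estimates
product_variance <- function(beta, se) {
  prods <- vapply(seq_along(beta), function(i) prod(beta[-i]), 0.0)
  sum(prods^2 * se^2)
}

#' Average causal effects along all directed paths
#'
#' For each of the `K` source-sink paths of the tree, the per-group ACE is
#' the product of standardized per-edge OLS coefficients along the path
#' (variables are standardized within group, so effects are on the
#' correlation scale). The group difference is tested with
#' `z = (ACE1 - ACE2) / sqrt(SE1^2 + SE2^2)` using delta-method standard
#' errors of each product; p-values are BH-adjusted across the `K` paths
#' and combined as `K * min(p)` capped at 1. With `groups = NULL` a single
#' pooled ACE per path is reported without a test.
#'
#' @param t a [directed_tree()].
#' @param X subjects x genes numeric matrix.
#' @param groups two-level labels (>= 4 subjects per group), or `NULL`.
#' @param alpha BH significance threshold for the significant-path count.
#' @return object of class `perturbation_report`: list with the per-path
#'   `paths` data.frame, `K`, `n_significant`, and `p_combined`.
#' @export
ace_paths <- function(t, X, groups = NULL, alpha = 0.05) {
  stopifnot(inherits(t, "directed_tree"))
  check_expression_matrix(X, min_subjects = 4L)
  missing <- setdiff(t$nodes, colnames(X))
  if (length(missing))
    validation_error(sprintf("tree node(s) absent from data: %s",
                             paste(missing, collapse = ", ")))
  pd <- directed_paths(t)
  if (pd$K == 0L) validation_error("tree has no directed paths")

  path_stats <- function(coefs) {
    t(vapply(pd$paths, function(pr) {
      kids <- pr$node_sequence[-1L]
      ace <- prod(coefs$beta[kids])
      c(ace = ace, var = product_variance(coefs$beta[kids], coefs$se[kids]))
    }, c(ace = 0.0, var = 0.0)))
  }
  src <- vapply(pd$paths, `[[`, "", "source")
  snk <- vapply(pd$paths, `[[`, "", "sink")
  len <- vapply(pd$paths, function(pr) length(pr$node_sequence) - 1L, 0L)

  if (is.null(groups)) {
    st <- path_stats(edge_coefs(t, X))
    paths <- data.frame(source = src, sink = snk, length = len,
                        ace = st[, "ace"], se = sqrt(st[, "var"]),
                        stringsAsFactors = FALSE)
    return(structure(list(paths = paths, K = pd$K,
                          n_significant = NA_integer_, p_combined = NA_real_),
                     class = "perturbation_report"))
  }

  grp <- check_groups(groups, nrow(X), min_per_group = 4L)
  lv <- levels(grp)
  st1 <- path_stats(edge_coefs(t, X[grp == lv[1L], , drop = FALSE]))
  st2 <- path_stats(edge_coefs(t, X[grp == lv[2L], , drop = FALSE]))
  sed <- sqrt(st1[, "var"] + st2[, "var"])
  z <- (st1[, "ace"] - st2[, "ace"]) / ifelse(sed > 0, sed, Inf)
  p <- 2 * stats::pnorm(-abs(z))
  p_adj <- bh_adjust(p)
  paths <- data.frame(source = src, sink = snk, length = len,
                      ace1 = st1[, "ace"], ace2 = st2[, "ace"],
                      se = sed, z = z, p = p, p_adj = p_adj,
                      stringsAsFactors = FALSE)
  structure(list(paths = paths, K = pd$K,
                 n_significant = sum(p_adj < alpha),
                 p_combined = bonferroni_combine(p, kind = "paths")),
            class = "perturbation_report")
}

#' @export
print.perturbation_report <- function(x, ...) {
  cat(sprintf("perturbation report: K = %d paths, %s significant, combined P = %s\n",
              x$K,
              if (is.na(x$n_significant)) "NA" else x$n_significant,
              if (is.na(x$p_combined)) "NA" else format(x$p_combined, digits = 4)))
  invisible(x)
}

#' Gene-set enrichment metrics
#'
#' Precision, recall and F1 of a selected gene set against a reference set;
#' F1 is defined as 0 when precision and recall are both 0.
#'
#' @param selected nonempty character vector of selected genes.
#' @param reference nonempty character vector of reference genes.
#' @return named numeric vector `c(precision, recall, f1)`.
#' @export
enrichment_metrics <- function(selected, reference) {
  selected <- unique(as.character(selected))
  reference <- unique(as.character(reference))
  if (length(selected) == 0L) validation_error("empty selected set")
  if (length(reference) == 0L) validation_error("empty reference set")
  tp <- length(intersect(selected, reference))
  precision <- tp / length(selected)
  recall <- tp / length(reference)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Jaccard similarity of two gene sets
#'
#' @param A,B character vectors with nonempty union.
#' @return `|A intersect B| / |A union B|`.
#' @export
jaccard <- function(A, B) {
  A <- unique(as.character(A)); B <- unique(as.character(B))
  u <- union(A, B)
  if (length(u) == 0L) validation_error("both sets are empty")
  length(intersect(A, B)) / length(u)
}
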