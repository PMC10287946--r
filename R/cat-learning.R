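# Causal additive trees: bivariate penalized-spline regression scores the
# two orientations of every candidate edge by the residual-variance ratio
# w = 1/2 * log(sigma_r / s_r); Chu-Liu-Edmonds then extracts the
# minimum-score arborescence. Nonlinearity of the structural functions is
# what makes the two orientations score differently, and hence the
# direction identifiable.

#' Additive-regression edge weight for one ordered gene pair
#'
#' Both variables are standardized to zero mean and unit variance, then the
#' child is regressed on the parent with a penalized (thin-plate) regression
#' spline (basis dimension 10, smoothness by generalized cross-validation),
#' the default smoother of `mgcv::gam`. The
#' weight is `w = 1/2 * log(sigma_r / s_r)` where `sigma_r` is the residual
#' variance and `s_r` the (unit) marginal variance of the child; lower
#' values mean better link prediction.
#'
#' Below `n = 20` observations the spline is replaced by a simple linear
#' fit and the result flagged; below `n = 8` the fit is refused.
#'
#' @param y_child,y_parent numeric vectors of equal length.
#' @param basis_dim spline basis dimension (reduced automatically when the
#'   parent has few unique values).
#' @return object of class `additive_fit`: list with `w`, `sigma_r`, `s_r`,
#'   `linear` (fallback flag) and the fitted model `fit`.
#' @export
additive_weight <- function(y_child, y_parent, basis_dim = 10L) {
  if (length(y_child) != length(y_parent))
    validation_error("child and parent vectors must have equal length")
  n <- length(y_child)
  if (n < 8L) validation_error("at least 8 observations required for edge weighting")
  if (anyNA(y_child) || anyNA(y_parent) ||
      any(!is.finite(y_child)) || any(!is.finite(y_parent)))
    validation_error("non-finite values in input vectors")
  if (stats::sd(y_child) == 0) validation_error("constant child variable")
  if (stats::sd(y_parent) == 0) validation_error("constant parent variable")

  yc <- as.numeric(scale(y_child))
  yp <- as.numeric(scale(y_parent))
  s_r <- stats::var(yc)    # 1 by construction

  linear <- n < 20L
  k <- min(basis_dim, length(unique(yp)) - 1L)
  if (k < 4L) linear <- TRUE
  fit <- if (linear) stats::lm(yc ~ yp)
         else tryCatch(
           mgcv::gam(yc ~ s(yp, k = k, bs = "tp")),
           error = function(e)      # near-degenerate design: simpler bases
             tryCatch(mgcv::gam(yc ~ s(yp, k = k, bs = "cr")),
                      error = function(e) stats::lm(yc ~ yp)))
  sigma_r <- stats::var(stats::residuals(fit))
  # regression cannot inflate variance beyond numerical tolerance
  sigma_r <- min(sigma_r, s_r * (1 + 1e-8))
  sigma_r <- max(sigma_r, .Machine$double.eps)
  structure(list(w = 0.5 * log(sigma_r / s_r),
                 sigma_r = sigma_r, s_r = s_r,
                 linear = linear, fit = fit),
            class = "additive_fit")
}

#' @export
print.additive_fit <- function(x, ...) {
  cat(sprintf("additive fit: w = %.4f (sigma_r = %.4f, s_r = %.4f)%s\n",
              x$w, x$sigma_r, x$s_r, if (x$linear) " [linear fallback]" else ""))
  invisible(x)
}

#' Linear-case symmetric edge weight (negative mutual information)
#'
#' For standardized linear relations the additive weight degenerates to a
#' symmetric quantity; this returns `-MI = log(1 - |cor(y1, y2)|)`
#' (`mi = "printed"`) or the Gaussian form `1/2 * log(1 - cor^2)`
#' (`mi = "gaussian"`). Correlations are clipped at `clip_r` so collinear
#' pairs stay finite.
#'
#' @param y1,y2 numeric vectors.
#' @param mi which functional form to use.
#' @param clip_r clipping constant for `|r|`.
#' @return a nonpositive scalar weight.
#' @export
mi_linear_weight <- function(y1, y2, mi = c("printed", "gaussian"),
                             clip_r = 0.999999) {
  mi <- match.arg(mi)
  if (stats::sd(y1) == 0 || stats::sd(y2) == 0)
    validation_error("constant input vector")
  r <- clip_correlation(stats::cor(y1, y2), clip_r)
  if (mi == "printed") log(1 - abs(r)) else 0.5 * log(1 - r^2)
}

#' Causal additive tree (CAT)
#'
#' Builds the mutual weight table by scoring both orientations of every
#' candidate pair with [additive_weight()] — all `p(p-1)` ordered pairs in
#' full-graph mode, or the two orientations of each skeleton edge when a
#' skeleton is supplied (non-skeleton pairs are forbidden) — and recovers
#' the minimum-weight spanning arborescence with Chu-Liu-Edmonds.
#'
#' @param X subjects x genes numeric matrix.
#' @param skeleton optional undirected igraph restricting candidate edges;
#'   its nodes must be a subset of the columns of `X`.
#' @param basis_dim spline basis dimension passed to [additive_weight()].
#' @param max_n if `n > max_n`, rows are subsampled to `max_n` (controlled
#'   by `seed`); off by default.
#' @param seed RNG seed for the optional subsampling only (the fit itself
#'   is deterministic).
#' @return a [directed_tree()]; the weight table is attached as attribute
#'   `"weights"`.
#' @export
cat_tree <- function(X, skeleton = NULL, basis_dim = 10L, max_n = Inf,
                     seed = NULL) {
  check_expression_matrix(X, min_subjects = 8L)
  if (!is.null(skeleton)) {
    validate_gene_graph(skeleton)
    nodes <- igraph::V(skeleton)$name
    missing <- setdiff(nodes, colnames(X))
    if (length(missing))
      validation_error(sprintf("skeleton node(s) absent from data: %s",
                               paste(missing, collapse = ", ")))
  } else {
    nodes <- colnames(X)
  }
  if (length(nodes) < 2L) validation_error("at least two genes required")
  if (nrow(X) > max_n) {
    if (!is.null(seed)) set.seed(seed)
    X <- X[sample.int(nrow(X), max_n), , drop = FALSE]
  }

  if (is.null(skeleton)) {
    pr <- t(utils::combn(nodes, 2L))
  } else {
    pr <- igraph::as_edgelist(skeleton, names = TRUE)
  }
  W <- weight_table(nodes)
  for (i in seq_len(nrow(pr))) {
    a <- pr[i, 1L]; b <- pr[i, 2L]
    W[a, b] <- additive_weight(X[, b], X[, a], basis_dim = basis_dim)$w
    W[b, a] <- additive_weight(X[, a], X[, b], basis_dim = basis_dim)$w
  }
  t <- cle_min_arborescence(W)
  attr(t, "weights") <- W
  t
}

#' Polytree CPDAG from data
#'
#' Two-stage Chow-Liu style learner: (1) the undirected skeleton is the
#' optimal spanning tree under symmetric mutual-information weights
#' ([mi_linear_weight()]); (2) every skeleton triple `k - j - l` is oriented
#' as a collider `k -> j <- l` when the marginal (unconditional) correlation
#' test between `k` and `l` fails to reject independence at `alpha` (Fisher
#' z on the pooled data); (3) the first Meek rule (`k -> j`, `j - l`,
#' `k` and `l` non-adjacent implies `j -> l`) is applied to closure.
#' Remaining edges stay undirected; the result represents the Markov
#' equivalence class of the polytree.
#'
#' @param X subjects x genes numeric matrix (`n >= 4`).
#' @param alpha significance level of the independence test.
#' @param mi functional form of the skeleton weights, see
#'   [mi_linear_weight()].
#' @return object of class `cpdag`: list with `graph` (directed igraph with
#'   logical edge attribute `oriented`; unoriented edges are stored in
#'   canonical order), `skeleton` (undirected igraph), `v_structures`
#'   (data.frame), `alpha`.
#' @export
cpdag_polytree <- function(X, alpha = 0.05, mi = c("printed", "gaussian")) {
  mi <- match.arg(mi)
  check_expression_matrix(X, min_subjects = 4L)
  p <- ncol(X)
  if (p < 2L) validation_error("at least two genes required")
  n <- nrow(X)
  genes <- colnames(X)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    validation_error(sprintf("constant expression column(s): %s",
                             paste(genes[sds == 0], collapse = ", ")))

  C <- stats::cor(X)
  pr <- t(utils::combn(genes, 2L))
  r <- clip_correlation(C[pr], warn = FALSE)
  wts <- if (mi == "printed") log(1 - abs(r)) else 0.5 * log(1 - r^2)
  skeleton <- prim_mst(gene_graph(pr[, 1L], pr[, 2L], weight = wts))

  # collider detection on marginal independence of the triple endpoints
  el <- igraph::as_edgelist(skeleton, names = TRUE)
  oriented <- character(0)   # "k\rj" means k -> j
  vstruct <- list()
  for (j in genes) {
    nb <- sort(igraph::V(skeleton)$name[
      as.integer(igraph::neighbors(skeleton, j))])
    if (length(nb) < 2L) next
    for (idx in utils::combn(length(nb), 2L, simplify = FALSE)) {
      k <- nb[idx[1L]]; l <- nb[idx[2L]]
      z <- atanh(clip_correlation(C[k, l], warn = FALSE)) * sqrt(n - 3)
      pval <- 2 * stats::pnorm(-abs(z))
      if (pval > alpha) {
        oriented <- union(oriented, c(paste(k, j, sep = "\r"),
                                      paste(l, j, sep = "\r")))
        vstruct[[length(vstruct) + 1L]] <-
          data.frame(from1 = k, from2 = l, collider = j, p_indep = pval,
                     stringsAsFactors = FALSE)
      }
    }
  }
  # drop edges claimed in both directions (conflicting colliders)
  both <- intersect(oriented,
                    vapply(strsplit(oriented, "\r", fixed = TRUE),
                           function(x) paste(x[2L], x[1L], sep = "\r"), ""))
  if (length(both)) {
    warning(sprintf("%d edge orientation conflict(s); left undirected", length(both) / 2),
            call. = FALSE)
    oriented <- setdiff(oriented, both)
  }

  # Meek rule 1 until closure (rules 2-4 need adjacencies a tree lacks)
  repeat {
    added <- FALSE
    for (key in oriented) {
      kj <- strsplit(key, "\r", fixed = TRUE)[[1L]]
      j <- kj[2L]
      nb <- igraph::V(skeleton)$name[as.integer(igraph::neighbors(skeleton, j))]
      for (l in setdiff(nb, kj[1L])) {
        fwd <- paste(j, l, sep = "\r"); rev <- paste(l, j, sep = "\r")
        if (!(fwd %in% oriented) && !(rev %in% oriented)) {
          oriented <- c(oriented, fwd); added <- TRUE
        }
      }
    }
    if (!added) break
  }

  okeys <- do.call(rbind, strsplit(oriented, "\r", fixed = TRUE))
  from <- character(0); to <- character(0); isdir <- logical(0)
  for (i in seq_len(nrow(el))) {
    a <- el[i, 1L]; b <- el[i, 2L]
    if (paste(a, b, sep = "\r") %in% oriented) {
      from <- c(from, a); to <- c(to, b); isdir <- c(isdir, TRUE)
    } else if (paste(b, a, sep = "\r") %in% oriented) {
      from <- c(from, b); to <- c(to, a); isdir <- c(isdir, TRUE)
    } else {
      lo <- min(a, b); hi <- max(a, b)
      from <- c(from, lo); to <- c(to, hi); isdir <- c(isdir, FALSE)
    }
  }
  g <- gene_graph(from, to, nodes = genes, directed = TRUE)
  # gene_graph sorts edges; recover orientation flags by lookup
  el2 <- igraph::as_edgelist(g, names = TRUE)
  dirkeys <- paste(from, to, sep = "\r")[isdir]
  igraph::E(g)$oriented <- paste(el2[, 1L], el2[, 2L], sep = "\r") %in% dirkeys
  structure(list(graph = g, skeleton = skeleton,
                 v_structures = if (length(vstruct)) do.call(rbind, vstruct)
                                else data.frame(from1 = character(0),
                                                from2 = character(0),
                                                collider = character(0),
                                                p_indep = numeric(0)),
                 alpha = alpha),
            class = "cpdag")
}

#' @export
print.cpdag <- function(x, ...) {
  ndir <- sum(igraph::E(x$graph)$oriented)
  cat(sprintf("polytree CPDAG: %d nodes, %d edges (%d directed, %d undirected), %d v-structure(s)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              ndir, igraph::ecount(x$graph) - ndir, nrow(x$v_structures)))
  invisible(x)
}
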