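# Dimension control: minimax-linkage hierarchical clustering with
# prototypes, dendrogram cutting at h = 1 - |rho0|, and contraction of the
# graph onto prototype nodes. After a cut at height h every cluster member
# is guaranteed to satisfy |cor(member, prototype)| >= 1 - h, because the
# minimax merge height is the smallest covering radius achievable by one
# member (the prototype).

#' Minimax-linkage hierarchical clustering with prototypes
#'
#' Agglomerative clustering where the distance between two clusters is
#' `min_p max_x D(p, x)` over candidate prototypes `p` and members `x` of
#' the union; the minimizing member becomes the merged cluster's prototype.
#' All ties (merge pair, prototype) are broken lexicographically by label.
#'
#' @param D symmetric numeric distance matrix with zero diagonal, finite
#'   entries and row/column labels.
#' @return object of class `protoclust_tree`: list with `heights`,
#'   `prototypes`, `members` (label sets per merge, in merge order) and
#'   `labels`.
#' @export
minimax_protoclust <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    validation_error("distance matrix must be square")
  if (anyNA(D) || any(!is.finite(D)))
    validation_error("distance matrix must be finite with no missing values")
  if (max(abs(D - t(D))) > 1e-12)
    validation_error("distance matrix must be symmetric")
  if (any(diag(D) != 0))
    validation_error("distance matrix must have a zero diagonal")
  labels <- rownames(D) %||% paste0("V", seq_len(nrow(D)))
  if (anyDuplicated(labels)) validation_error("duplicate labels in distance matrix")
  n <- nrow(D)
  rownames(D) <- colnames(D) <- labels

  minimax <- function(U) {   # U: integer members; returns c(dist, proto_index)
    sub <- D[U, U, drop = FALSE]
    radii <- apply(sub, 1L, max)
    best <- which(radii == min(radii))
    if (length(best) > 1L) best <- best[order(labels[U[best]])][1L]
    list(d = radii[[best]], proto = U[best])
  }

  members <- as.list(seq_len(n))          # active cluster -> member indices
  minlab <- labels                         # smallest member label per cluster
  active <- rep(TRUE, n)
  # pairwise cluster distances, grown as merges happen
  M <- D; M[!upper.tri(M)] <- Inf

  heights <- numeric(n - 1L)
  prototypes <- character(n - 1L)
  msets <- vector("list", n - 1L)

  for (step in seq_len(n - 1L)) {
    idx <- which(M == min(M), arr.ind = TRUE)
    if (nrow(idx) > 1L) {
      keys <- apply(idx, 1L, function(ij) {
        paste(sort(c(minlab[ij[1L]], minlab[ij[2L]])), collapse = "\r")
      })
      idx <- idx[order(keys), , drop = FALSE]
    }
    i <- idx[1L, 1L]; j <- idx[1L, 2L]
    U <- c(members[[i]], members[[j]])
    mm <- minimax(U)
    heights[step] <- mm$d
    prototypes[step] <- labels[mm$proto]
    msets[[step]] <- labels[sort(U)]

    # retire i and j, register the merged cluster in slot i
    active[j] <- FALSE
    M[j, ] <- Inf; M[, j] <- Inf
    members[[i]] <- U
    minlab[i] <- min(minlab[i], minlab[j])
    for (k in which(active)) {
      if (k == i) next
      d <- minimax(c(U, members[[k]]))$d
      if (k < i) M[k, i] <- d else M[i, k] <- d
    }
  }
  structure(list(heights = heights, prototypes = prototypes,
                 members = msets, labels = labels),
            class = "protoclust_tree")
}

#' Cut a minimax dendrogram at a height
#'
#' Applies every merge with height `<= h`; each leaf is mapped to the
#' prototype of the last merge that absorbed it (itself if none). As a
#' special case `h = 0` performs no merging at all (the `rho0 = 1` cut),
#' even for zero-distance duplicates.
#'
#' @param pc a `protoclust_tree`.
#' @param h cut height in `[0, 1)`.
#' @return named character vector mapping each label to its prototype.
#' @export
cut_protoclust <- function(pc, h) {
  stopifnot(inherits(pc, "protoclust_tree"))
  if (!is.numeric(h) || length(h) != 1L || is.na(h) || h < 0 || h >= 1)
    validation_error("cut height must lie in [0, 1)")
  map <- stats::setNames(pc$labels, pc$labels)
  if (h > 0) {
    for (i in seq_along(pc$heights)) {
      if (pc$heights[i] <= h) map[pc$members[[i]]] <- pc$prototypes[i]
    }
  }
  map
}

protoclust_from_expression <- function(g, X) {
  validate_gene_graph(g)
  check_expression_matrix(X, min_subjects = 3L)
  nodes <- igraph::V(g)$name
  missing <- setdiff(nodes, colnames(X))
  if (length(missing))
    validation_error(sprintf("graph node(s) absent from expression columns: %s",
                             paste(missing, collapse = ", ")))
  sub <- X[, nodes, drop = FALSE]
  sds <- apply(sub, 2L, stats::sd)
  if (any(sds == 0))
    validation_error(sprintf("constant expression column(s): %s",
                             paste(nodes[sds == 0], collapse = ", ")))
  D <- 1 - abs(stats::cor(sub))
  D <- (D + t(D)) / 2
  diag(D) <- 0
  minimax_protoclust(D)
}

#' Merge correlated nodes onto prototypes
#'
#' Clusters the graph's genes by minimax linkage on `1 - |cor|` distances,
#' cuts the dendrogram at height `h = 1 - |rho0|`, and contracts each
#' cluster onto its prototype gene: the contracted graph inherits an edge
#' between two prototypes whenever any pair of their members was adjacent
#' (minimum weight kept, self-loops dropped), and the reduced expression
#' matrix keeps only prototype columns. Every member then has
#' `|cor(member, prototype)| >= 1 - h`.
#'
#' @param g igraph object over genes present in `X`.
#' @param X subjects x genes numeric matrix.
#' @param h cut height in `[0, 1)`; `h = 0` is the identity.
#' @return list with `graph` (contracted), `mapping` (named character,
#'   member -> prototype), `data` (reduced matrix), `height`.
#' @export
merge_nodes <- function(g, X, h) {
  pc <- protoclust_from_expression(g, X)
  map <- cut_protoclust(pc, h)
  nodes <- igraph::V(g)$name
  protos <- unique(unname(map[nodes]))
  if (length(protos) == length(nodes)) {
    return(list(graph = g, mapping = map, data = X[, nodes, drop = FALSE], height = h))
  }
  memb <- match(map[nodes], protos)
  cg <- igraph::contract(g, memb, vertex.attr.comb = list(name = "ignore"))
  igraph::V(cg)$name <- protos
  has_w <- !is.null(igraph::E(g)$weight)
  cg <- igraph::simplify(cg, remove.multiple = TRUE, remove.loops = TRUE,
                         edge.attr.comb = if (has_w) list(weight = "min") else "ignore")
  list(graph = cg, mapping = map, data = X[, protos, drop = FALSE], height = h)
}

#' Smallest cut height meeting a size cap
#'
#' Scans the dendrogram's merge-height grid for the smallest height at
#' which the number of clusters drops to at most `target_size`; returns 0
#' when the graph is already under the cap.
#'
#' @param g igraph object over genes present in `X`.
#' @param X subjects x genes numeric matrix.
#' @param target_size maximum number of merged nodes (>= 1).
#' @return a height usable with [merge_nodes()].
#' @export
size_cap_height <- function(g, X, target_size) {
  if (!is.numeric(target_size) || length(target_size) != 1L || target_size < 1)
    validation_error("'target_size' must be a positive integer")
  n <- igraph::vcount(g)
  if (n <= target_size) return(0)
  pc <- protoclust_from_expression(g, X)
  pc$heights[n - target_size]
}
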