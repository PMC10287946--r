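# Graph-algorithm engines: Chu-Liu-Edmonds minimum spanning arborescence,
# Prim's minimum spanning tree, and Kou's Steiner-tree heuristic.

#' Empty mutual weight table
#'
#' Ordered-pair weight matrix `W[k, j] = w(k -> j)`; `Inf` marks forbidden
#' pairs and the diagonal is always forbidden.
#'
#' @param nodes character vector of node identifiers.
#' @return square numeric matrix filled with `Inf`, dimnames set to `nodes`.
#' @export
weight_table <- function(nodes) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) validation_error("duplicate node identifiers")
  matrix(Inf, length(nodes), length(nodes), dimnames = list(nodes, nodes))
}

check_weight_table <- function(W) {
  if (!is.matrix(W) || nrow(W) != ncol(W) ||
      is.null(rownames(W)) || !identical(rownames(W), colnames(W)))
    validation_error("weight table must be a square matrix with matching dimnames")
  offdiag <- W[row(W) != col(W)]
  if (anyNA(offdiag) || any(is.nan(offdiag)) || any(offdiag == -Inf))
    validation_error("weight table entries must be finite or +Inf")
  invisible(W)
}

# one round of Chu-Liu-Edmonds for a fixed root (minimization); W rows are
# parents, columns children; returns a named parent vector over rownames(W)
cle_fixed_root <- function(W, root, level = 0L) {
  nodes <- rownames(W)
  others <- setdiff(nodes, root)
  if (length(others) == 0L) {
    pa <- stats::setNames(NA_character_, root)
    return(pa)
  }
  pa <- vapply(others, function(v) {
    col <- W[, v]; col[v] <- Inf
    j <- which.min(col)                      # ties: first (lexicographically smallest) row
    if (!is.finite(col[j])) NA_character_ else nodes[j]
  }, "")
  if (anyNA(pa))
    validation_error(sprintf("no incoming edge for node(s): %s",
                             paste(others[is.na(pa)], collapse = ", ")))
  # cycle detection over the chosen-parent function
  color <- stats::setNames(integer(length(nodes)), nodes)  # 0 unseen 1 active 2 done
  color[root] <- 2L
  cycle <- NULL
  for (v in others) {
    if (color[v] != 0L) next
    path <- character(0); u <- v
    while (!is.na(u) && color[u] == 0L) {
      color[u] <- 1L; path <- c(path, u)
      u <- if (u == root) NA_character_ else pa[[u]]
    }
    if (!is.na(u) && color[u] == 1L) {
      cycle <- path[seq(match(u, path), length(path))]
      break
    }
    color[path] <- 2L
  }
  if (is.null(cycle)) {
    full <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
    full[others] <- pa[others]
    return(full)
  }

  # contract the cycle into a supernode and recurse
  cnode <- sprintf("\rcyc%d", level)
  outside <- setdiff(nodes, cycle)
  win <- vapply(cycle, function(v) W[pa[[v]], v], 0.0)   # internal incoming weights
  W2 <- matrix(Inf, length(outside) + 1L, length(outside) + 1L,
               dimnames = list(c(outside, cnode), c(outside, cnode)))
  W2[outside, outside] <- W[outside, outside]
  enter_choice <- stats::setNames(rep(NA_character_, length(outside)), outside)
  leave_choice <- stats::setNames(rep(NA_character_, length(outside)), outside)
  for (u in outside) {
    adj <- W[u, cycle] - win
    j <- which.min(adj)
    if (is.finite(adj[j])) { W2[u, cnode] <- adj[j]; enter_choice[u] <- cycle[j] }
    out <- W[cycle, u]
    j <- which.min(out)
    if (is.finite(out[j])) { W2[cnode, u] <- out[j]; leave_choice[u] <- cycle[j] }
  }
  pa2 <- cle_fixed_root(W2, root, level + 1L)

  full <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  for (u in outside) {
    pu <- pa2[[u]]
    full[u] <- if (identical(pu, cnode)) leave_choice[[u]] else pu
  }
  ustar <- pa2[[cnode]]
  vstar <- enter_choice[[ustar]]
  full[cycle] <- vapply(cycle, function(v) pa[[v]], "")
  full[vstar] <- ustar
  full[root] <- NA_character_
  full
}

#' Minimum-weight spanning arborescence (Chu-Liu-Edmonds)
#'
#' Finds the spanning arborescence minimizing total edge weight over all
#' admissible roots. The optimum over roots is obtained with an artificial
#' super-root connected to every node at a prohibitively large constant
#' weight, so exactly one artificial edge (identifying the best root)
#' appears in any optimal solution.
#'
#' @param W mutual weight table from [weight_table()]: `W[k, j]` is the cost
#'   of edge `k -> j`, `Inf` forbidden.
#' @return a [directed_tree()] with `total_weight` equal to the achieved
#'   minimum.
#' @export
cle_min_arborescence <- function(W) {
  check_weight_table(W)
  nodes <- sort(rownames(W))
  W <- W[nodes, nodes, drop = FALSE]
  diag(W) <- Inf
  if (length(nodes) == 1L)
    return(directed_tree(stats::setNames(NA_character_, nodes)))

  finite <- is.finite(W)
  M <- 2 * sum(abs(W[finite])) + 1
  aroot <- "\raroot"
  Waug <- rbind(cbind(W, rep(Inf, length(nodes))), rep(M, length(nodes) + 1L))
  rownames(Waug) <- colnames(Waug) <- c(nodes, aroot)
  Waug[aroot, aroot] <- Inf

  pa <- cle_fixed_root(Waug, aroot)
  art_children <- nodes[pa[nodes] == aroot]
  if (length(art_children) != 1L) {
    ij <- which(finite, arr.ind = TRUE)
    g <- igraph::make_empty_graph(directed = TRUE)
    g <- igraph::add_vertices(g, length(nodes), name = nodes)
    if (nrow(ij))
      g <- igraph::add_edges(g, rbind(nodes[ij[, 1L]], nodes[ij[, 2L]]))
    reach <- vapply(nodes, function(r)
      length(igraph::subcomponent(g, r, mode = "out")), 0L)
    best <- nodes[which.max(reach)]
    unreachable <- setdiff(nodes, names(igraph::subcomponent(g, best, mode = "out")))
    validation_error(sprintf(
      "no spanning arborescence exists; node(s) unreachable from best root '%s': %s",
      best, paste(unreachable, collapse = ", ")))
  }
  parent <- pa[nodes]
  parent[art_children] <- NA_character_
  kids <- nodes[!is.na(parent)]
  ew <- stats::setNames(W[cbind(parent[kids], kids)], kids)
  directed_tree(parent, ew)
}

#' Minimum spanning tree (Prim)
#'
#' Deterministic Prim implementation: the start vertex is the smallest node
#' label, vertex selection ties are broken by label and equal-weight edge
#' ties by canonical edge label.
#'
#' @param g connected, undirected, weighted igraph object.
#' @return spanning tree as an igraph object (subgraph of `g`).
#' @export
prim_mst <- function(g) {
  validate_gene_graph(g)
  if (igraph::is_directed(g)) validation_error("MST requires an undirected graph")
  w <- igraph::E(g)$weight
  if (is.null(w)) validation_error("graph must carry edge weights")
  if (!igraph::is_connected(g))
    validation_error("graph is disconnected; apply largest_component() first")
  n <- igraph::vcount(g)
  if (n <= 1L) return(g)
  nm <- igraph::V(g)$name
  dist <- rep(Inf, n); via <- rep(NA_integer_, n); eid <- rep(NA_integer_, n)
  intree <- rep(FALSE, n)
  u <- which(nm == min(nm))
  dist[u] <- 0
  chosen <- integer(0)
  for (iter in seq_len(n)) {
    cand <- which(!intree)
    u <- cand[order(dist[cand], nm[cand])][1L]
    intree[u] <- TRUE
    if (!is.na(eid[u])) chosen <- c(chosen, eid[u])
    ee <- igraph::incident(g, u)
    if (length(ee)) {
      ends <- igraph::ends(g, ee, names = FALSE)
      v <- ifelse(ends[, 1L] == u, ends[, 2L], ends[, 1L])
      we <- w[as.integer(ee)]
      open <- !intree[v]
      better <- open & (we < dist[v])
      tie <- open & (we == dist[v]) & !is.na(via[v]) &
        (edge_key(nm[u], nm[v]) < edge_key(nm[via[v]], nm[v]))
      upd <- better | tie
      dist[v[upd]] <- we[upd]; via[v[upd]] <- u; eid[v[upd]] <- as.integer(ee)[upd]
    }
  }
  igraph::subgraph_from_edges(g, chosen, delete.vertices = FALSE)
}

#' Steiner tree connecting seed genes (Kou's heuristic)
#'
#' The classical 2-approximation: (1) metric closure on the seeds via
#' shortest paths, (2) MST of the closure, (3) expansion of closure edges to
#' their shortest paths, (4) MST of the expanded subgraph, (5) repeated
#' pruning of non-seed leaves. The result is a tree containing every seed.
#'
#' @param g connected, undirected igraph with nonnegative edge weights.
#' @param seeds character vector of required (terminal) nodes.
#' @return tree as an igraph object.
#' @export
kou_steiner <- function(g, seeds) {
  validate_gene_graph(g)
  if (igraph::is_directed(g)) validation_error("Steiner search requires an undirected graph")
  w <- igraph::E(g)$weight
  if (is.null(w)) validation_error("graph must carry edge weights")
  if (any(w < 0)) validation_error("negative edge weights are not allowed")
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0L) validation_error("at least one seed required")
  missing <- setdiff(seeds, igraph::V(g)$name)
  if (length(missing))
    validation_error(sprintf("seed(s) absent from graph: %s", paste(missing, collapse = ", ")))
  memb <- igraph::components(g)$membership
  if (length(unique(memb[seeds])) > 1L)
    validation_error("seeds are split across disconnected components")
  if (length(seeds) == 1L)
    return(igraph::induced_subgraph(g, seeds))

  seeds <- sort(seeds)
  d <- igraph::distances(g, v = seeds, to = seeds, weights = w, algorithm = "dijkstra")
  pr <- t(utils::combn(seeds, 2L))
  closure <- gene_graph(pr[, 1L], pr[, 2L], weight = d[pr], directed = FALSE)
  m1 <- prim_mst(closure)

  el <- igraph::as_edgelist(m1, names = TRUE)
  eids <- integer(0)
  for (i in seq_len(nrow(el))) {
    sp <- igraph::shortest_paths(g, from = el[i, 1L], to = el[i, 2L],
                                 weights = w, output = "epath")
    eids <- union(eids, as.integer(sp$epath[[1L]]))
  }
  sub <- igraph::subgraph_from_edges(g, eids, delete.vertices = TRUE)
  m2 <- prim_mst(sub)
  repeat {
    deg <- igraph::degree(m2)
    drop <- which(deg <= 1L & !(igraph::V(m2)$name %in% seeds))
    if (length(drop) == 0L) break
    m2 <- igraph::delete_vertices(m2, drop)
  }
  m2
}

#' Data-driven minimum spanning tree
#'
#' Prim MST of the complete graph over all expression columns with
#' `1 - |cor|` edge weights: the tree skeleton of the co-expression
#' structure.
#'
#' @param X subjects x genes numeric matrix, at least 3 subjects and 2 genes.
#' @return spanning tree as an igraph object with `weight` edge attribute.
#' @export
mst_from_data <- function(X) {
  check_expression_matrix(X, min_subjects = 3L)
  if (ncol(X) < 2L) validation_error("at least two genes required")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    validation_error(sprintf("constant expression column(s): %s",
                             paste(colnames(X)[sds == 0], collapse = ", ")))
  C <- stats::cor(X)
  pr <- t(utils::combn(colnames(X), 2L))
  g <- gene_graph(pr[, 1L], pr[, 2L], weight = 1 - abs(C[pr]), directed = FALSE)
  prim_mst(g)
}
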