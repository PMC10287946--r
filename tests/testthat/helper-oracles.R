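# Independent oracles and fixture builders shared across the suite.
# Each oracle is a brute-force or closed-form implementation kept separate
# from the code path it checks.

# exhaustive minimum spanning arborescence over all roots: enumerate parent
# maps in ascending weight order and return the first feasible one
enum_min_arborescence <- function(W) {
  n <- nrow(W)
  idx <- seq_len(n)
  best <- Inf
  for (r in idx) {
    others <- setdiff(idx, r)
    grid <- as.matrix(expand.grid(lapply(others, function(v) setdiff(idx, v))))
    w <- vapply(seq_len(nrow(grid)), function(i)
      sum(W[cbind(grid[i, ], others)]), 0.0)
    for (i in order(w)) {
      if (!is.finite(w[i]) || w[i] >= best) break
      pa <- rep(NA_integer_, n); pa[others] <- grid[i, ]
      reached <- r
      repeat {
        nxt <- others[!(others %in% reached) & pa[others] %in% reached]
        if (!length(nxt)) break
        reached <- c(reached, nxt)
      }
      if (length(reached) == n) { best <- w[i]; break }
    }
  }
  best
}

# canonical undirected edge key (local copy; the package internal is unexported)
ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))

# union-find Kruskal, returns total MST weight
kruskal_weight <- function(from, to, w, nodes) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  total <- 0; used <- 0L
  for (i in order(w)) {
    ra <- find(from[i]); rb <- find(to[i])
    if (ra != rb) {
      parent[ra] <- rb
      total <- total + w[i]
      used <- used + 1L
      if (used == length(nodes) - 1L) break
    }
  }
  total
}

# exact Steiner optimum by enumerating subsets of non-seed vertices
steiner_opt_weight <- function(g, seeds) {
  others <- setdiff(igraph::V(g)$name, seeds)
  best <- Inf
  for (mask in 0:(2^length(others) - 1L)) {
    extra <- others[bitwAnd(mask, 2^(seq_along(others) - 1L)) > 0]
    H <- igraph::induced_subgraph(g, c(seeds, extra))
    if (!igraph::is_connected(H)) next
    m <- igraph::mst(H, weights = igraph::E(H)$weight)
    tw <- sum(igraph::E(m)$weight)
    if (tw < best) best <- tw
  }
  best
}

# random connected undirected weighted graph
random_connected_graph <- function(n, p_edge = 0.5) {
  repeat {
    pr <- t(utils::combn(paste0("n", sprintf("%02d", seq_len(n))), 2L))
    keep <- stats::runif(nrow(pr)) < p_edge
    if (sum(keep) < n - 1) next
    g <- gene_graph(pr[keep, 1L], pr[keep, 2L],
                    weight = round(stats::runif(sum(keep), 0.1, 1), 3))
    if (igraph::is_connected(g)) return(g)
  }
}

# random arborescence by uniform attachment, with a cap on depth so that
# iterated cubic links stay inside double-precision range
random_arborescence <- function(p, max_depth = 4L) {
  nodes <- paste0("v", sprintf("%02d", seq_len(p)))
  parent <- stats::setNames(rep(NA_character_, p), nodes)
  depth <- stats::setNames(integer(p), nodes)
  for (i in 2:p) {
    ok <- nodes[seq_len(i - 1L)][depth[seq_len(i - 1L)] < max_depth]
    pa <- ok[sample.int(length(ok), 1L)]
    parent[nodes[i]] <- pa
    depth[nodes[i]] <- depth[[pa]] + 1L
  }
  directed_tree(parent)
}

# subjects x genes matrix with given exact sample correlation between the
# first standardized column and each later one (orthogonal construction)
exact_cor_pair <- function(r, n = 5L) {
  x <- seq_len(n)
  e <- c(1, -2, 1, rep(0, n - 3L))                  # mean 0, orthogonal to x
  xs <- as.numeric(scale(x)); es <- as.numeric(scale(e))
  cbind(x = xs, y = r * xs + sqrt(1 - r^2) * es)
}

# 30-gene fixture with three planted correlation blocks
three_block_fixture <- function(n = 200L, genes_per_block = 10L, rho = 0.95,
                                seed = 421L) {
  set.seed(seed)
  blocks <- lapply(1:3, function(b) {
    common <- stats::rnorm(n)
    sapply(seq_len(genes_per_block), function(i)
      sqrt(rho) * common + sqrt(1 - rho) * stats::rnorm(n))
  })
  X <- do.call(cbind, blocks)
  colnames(X) <- paste0("b", rep(1:3, each = genes_per_block),
                        "g", sprintf("%02d", rep(seq_len(genes_per_block), 3)))
  X
}

# ring graph over the fixture genes so merge tests have a connected graph
ring_graph <- function(nodes) {
  gene_graph(nodes, c(nodes[-1L], nodes[1L]))
}

expect_valid_tree <- function(g) {
  chk <- check_tree(g)
  expect_true(chk$is_tree)
  invisible(chk)
}
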