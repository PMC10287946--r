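# CLE arborescence, Prim MST, Kou Steiner heuristic vs brute-force oracles

test_that("cle_min_arborescence solves the small worked examples", {
  W <- weight_table(c("a", "b"))
  W["a", "b"] <- 1; W["b", "a"] <- 2
  t <- cle_min_arborescence(W)
  expect_equal(t$root, "a")
  expect_equal(t$parent[["b"]], "a")
  expect_equal(t$total_weight, 1)

  W <- weight_table(c("a", "b", "c"))
  W["a", "b"] <- 1; W["b", "c"] <- 1
  t <- cle_min_arborescence(W)
  expect_equal(unname(t$parent[c("b", "c")]), c("a", "b"))
  expect_equal(t$total_weight, 2)

  W <- weight_table(c("a", "b", "c"))
  W["a", "b"] <- 1                              # c unreachable
  expect_error(cle_min_arborescence(W), "unreachable.*c")
})

test_that("cle_min_arborescence matches exhaustive enumeration on random digraphs", {
  set.seed(101)
  for (i in 1:100) {
    W <- weight_table(letters[1:5])
    W[] <- sample(1:9, 25, replace = TRUE)
    diag(W) <- Inf
    t <- cle_min_arborescence(W)
    expect_equal(t$total_weight, enum_min_arborescence(W))
    expect_true(check_tree(tree_as_igraph(t))$is_arborescence)
    expect_equal(t$total_weight, sum(t$edge_weights), tolerance = 1e-9)
  }
})

test_that("cle_min_arborescence is invariant to adding a constant to all weights", {
  set.seed(17)
  for (i in 1:20) {
    W <- weight_table(letters[1:6])
    W[] <- round(runif(36, -2, 2), 3)
    diag(W) <- Inf
    t1 <- cle_min_arborescence(W)
    shift <- 5.5
    t2 <- cle_min_arborescence(W + shift)
    expect_equal(t2$parent, t1$parent)
    expect_equal(t2$total_weight, t1$total_weight + 5 * shift, tolerance = 1e-9)
  }
})

test_that("prim_mst solves the worked examples deterministically", {
  tri <- gene_graph(c("a", "b", "c"), c("b", "c", "a"), weight = c(1, 2, 3))
  m <- prim_mst(tri)
  expect_equal(sort(igraph::E(m)$weight), c(1, 2))

  tree <- gene_graph(c("a", "b"), c("b", "c"), weight = c(0.3, 0.7))
  m <- prim_mst(tree)
  expect_equal(igraph::ecount(m), 2L)
  expect_equal(sum(igraph::E(m)$weight), 1)

  disc <- gene_graph(c("a", "x"), c("b", "y"), weight = c(1, 1))
  expect_error(prim_mst(disc), "disconnected")
})

test_that("prim_mst total weight equals an independent Kruskal oracle", {
  set.seed(202)
  for (i in 1:100) {
    g <- random_connected_graph(8)
    m <- prim_mst(g)
    expect_valid_tree(m)
    el <- igraph::as_edgelist(g)
    expect_equal(sum(igraph::E(m)$weight),
                 kruskal_weight(el[, 1], el[, 2], igraph::E(g)$weight,
                                igraph::V(g)$name),
                 tolerance = 1e-12)
  }
})

test_that("kou_steiner handles the documented cases", {
  # all nodes as seeds on a tree-shaped graph: the graph itself
  tree <- gene_graph(c("a", "a", "b"), c("b", "c", "d"),
                     weight = c(1, 2, 3))
  st <- kou_steiner(tree, c("a", "b", "c", "d"))
  expect_equal(igraph::ecount(st), 3L)
  expect_equal(sum(igraph::E(st)$weight), 6)

  # single seed: one node, no edges
  st <- kou_steiner(tree, "c")
  expect_equal(igraph::vcount(st), 1L)
  expect_equal(igraph::ecount(st), 0L)

  # 4-cycle with weights 1,1,5,5: optimum path a-b-c of weight 2
  cyc <- gene_graph(c("a", "b", "c", "d"), c("b", "c", "d", "a"),
                    weight = c(1, 1, 5, 5))
  st <- kou_steiner(cyc, c("a", "c"))
  expect_setequal(igraph::V(st)$name, c("a", "b", "c"))
  expect_equal(sum(igraph::E(st)$weight), 2)
  expect_equal(steiner_opt_weight(cyc, c("a", "c")), 2)  # confirmed optimum

  expect_error(kou_steiner(cyc, c("a", "zz")), "zz")
  two <- gene_graph(c("a", "x"), c("b", "y"), weight = c(1, 1))
  expect_error(kou_steiner(two, c("a", "x")), "components")
})

test_that("kou_steiner spans all seeds within the 2(1-1/s) approximation bound", {
  set.seed(303)
  for (i in 1:200) {
    n <- sample(6:10, 1)
    g <- random_connected_graph(n, p_edge = 0.45)
    s <- sample(2:4, 1)
    seeds <- sample(igraph::V(g)$name, s)
    st <- kou_steiner(g, seeds)
    expect_true(all(seeds %in% igraph::V(st)$name))
    expect_valid_tree(st)
    # non-seed leaves pruned
    deg <- igraph::degree(st)
    expect_true(all(igraph::V(st)$name[deg <= 1] %in% seeds) ||
                  igraph::vcount(st) == 1L)
    opt <- steiner_opt_weight(g, seeds)
    expect_lte(sum(igraph::E(st)$weight), 2 * (1 - 1 / s) * opt + 1e-9)
  }
})

test_that("mst_from_data recovers the co-expression skeleton", {
  # crafted fixture: strong 1-2 and 2-3 correlations, weak 1-3
  set.seed(404)
  n <- 500
  z <- rnorm(n)
  X <- cbind(g1 = z + rnorm(n, sd = 0.45),
             g2 = z + rnorm(n, sd = 0.45),
             g3 = rnorm(n))
  X[, "g3"] <- 0.8 * scale(X[, "g2"]) + 0.6 * rnorm(n)
  C <- cor(X)
  # oracle: with three nodes the MST is the two cheapest of the three edges
  w <- c(`g1 g2` = 1 - abs(C["g1", "g2"]), `g1 g3` = 1 - abs(C["g1", "g3"]),
         `g2 g3` = 1 - abs(C["g2", "g3"]))
  expected <- names(sort(w))[1:2]
  m <- mst_from_data(X)
  el <- igraph::as_edgelist(m)
  expect_setequal(ekey(el[, 1], el[, 2]), expected)

  # two genes: the single edge
  m2 <- mst_from_data(X[, 1:2])
  expect_equal(igraph::ecount(m2), 1L)

  # duplicated columns give legal weight-0 edges
  Xd <- cbind(X, g4 = X[, "g1"])
  m3 <- mst_from_data(Xd)
  expect_valid_tree(m3)
  expect_equal(min(igraph::E(m3)$weight), 0)
})
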