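# additive spline edge weights, CAT recovery, CPDAG polytree

test_that("additive_weight scores signal and no-signal pairs correctly", {
  set.seed(11)
  yp <- rnorm(1000); yc <- rnorm(1000)
  fit <- additive_weight(yc, yp)
  expect_lt(abs(fit$w), 0.02)              # sigma_r ~ s_r without signal
  expect_false(fit$linear)
  expect_lte(fit$sigma_r, fit$s_r * (1 + 1e-8))
  expect_gt(fit$sigma_r, 0)

  # causal direction has smaller residual variance for a cubic link
  set.seed(12)
  yp <- rnorm(500); yc <- yp^3 + rnorm(500, sd = 0.3)
  w_causal <- additive_weight(yc, yp)$w
  w_anti <- additive_weight(yp, yc)$w
  expect_lt(w_causal, w_anti)

  # linear pair: spline collapses to the line, w ~ 0.5*log(1 - r^2) both ways
  set.seed(13)
  yp <- rnorm(800); yc <- 0.7 * yp + sqrt(1 - 0.49) * rnorm(800)
  r <- cor(yc, yp)
  expected <- 0.5 * log(1 - r^2)
  expect_lt(abs(additive_weight(yc, yp)$w - expected), 0.02)
  expect_lt(abs(additive_weight(yp, yc)$w - expected), 0.02)
})

test_that("additive_weight enforces its preconditions", {
  expect_error(additive_weight(rnorm(5), rnorm(5)), "at least 8")
  expect_error(additive_weight(rep(1, 30), rnorm(30)), "constant child")
  expect_error(additive_weight(rnorm(30), rep(2, 30)), "constant parent")
  set.seed(14)
  fit <- additive_weight(rnorm(12), rnorm(12))
  expect_true(fit$linear)                  # n < 20: linear fallback, flagged
})

test_that("mi_linear_weight follows the printed formula", {
  x <- exact_cor_pair(0.5, n = 50)
  expect_equal(mi_linear_weight(x[, 1], x[, 2]), log(0.5), tolerance = 1e-10)
  expect_equal(mi_linear_weight(x[, 1], x[, 2], mi = "gaussian"),
               0.5 * log(0.75), tolerance = 1e-10)
  x0 <- exact_cor_pair(0, n = 50)
  expect_equal(mi_linear_weight(x0[, 1], x0[, 2]), 0, tolerance = 1e-10)
  expect_warning(w <- mi_linear_weight(x[, 1], 2 * x[, 1] + 1), "clipped")
  expect_true(is.finite(w) && w < -5)
})

test_that("cat_tree recovers a cubic chain and respects skeletons", {
  pa <- c(x1 = NA, x2 = "x1", x3 = "x2")
  X <- simulate_nonlinear_sem(directed_tree(pa), "cubic", n = 1000,
                              noise_sd = 0.3, seed = 42)
  tr <- cat_tree(X)
  expect_equal(tr$root, "x1")
  expect_equal(tr$parent[c("x2", "x3")], c(x2 = "x1", x3 = "x2"))

  # full mode evaluates exactly p(p-1) ordered pairs
  W <- attr(tr, "weights")
  expect_equal(sum(is.finite(W)), 3 * 2)

  # total weight is self-consistent with independently recomputed edge weights
  recomputed <- vapply(names(tr$edge_weights), function(j)
    additive_weight(X[, j], X[, tr$parent[[j]]])$w, 0.0)
  expect_equal(tr$total_weight, sum(recomputed), tolerance = 1e-9)

  # p = 2: the cheaper orientation wins
  X2 <- X[, c("x1", "x2")]
  t2 <- cat_tree(X2)
  w12 <- additive_weight(X2[, "x2"], X2[, "x1"])$w
  w21 <- additive_weight(X2[, "x1"], X2[, "x2"])$w
  expect_equal(t2$root, if (w12 <= w21) "x1" else "x2")

  # skeleton-restricted run only uses skeleton edges
  skel <- gene_graph(c("x1", "x2"), c("x2", "x3"))
  ts <- cat_tree(X, skeleton = skel)
  for (j in names(ts$edge_weights)) {
    expect_true(igraph::are_adjacent(skel, ts$parent[[j]], j))
  }
})

test_that("cpdag_polytree orients colliders and leaves chains undirected", {
  # collider x -> z <- y with independent x, y
  set.seed(21)
  n <- 2000
  x <- rnorm(n); y <- rnorm(n)
  z <- 0.7 * x + 0.7 * y + rnorm(n, sd = 0.5)
  cp <- cpdag_polytree(cbind(x = x, y = y, z = z))
  skel_el <- igraph::as_edgelist(cp$skeleton)
  expect_setequal(ekey(skel_el[, 1], skel_el[, 2]), c("x z", "y z"))
  expect_equal(nrow(cp$v_structures), 1L)
  el <- igraph::as_edgelist(cp$graph)
  expect_true(all(igraph::E(cp$graph)$oriented))
  expect_setequal(paste(el[, 1], el[, 2]), c("x z", "y z"))

  # linear chain x -> z -> y: Markov-equivalent class, all edges undirected
  set.seed(22)
  x <- rnorm(n); z <- 0.8 * x + rnorm(n, sd = 0.6); y <- 0.8 * z + rnorm(n, sd = 0.6)
  cp <- cpdag_polytree(cbind(x = x, y = y, z = z))
  skel_el <- igraph::as_edgelist(cp$skeleton)
  expect_setequal(ekey(skel_el[, 1], skel_el[, 2]), c("x z", "y z"))
  expect_false(any(igraph::E(cp$graph)$oriented))

  # p = 2: a single undirected edge, nothing to orient
  cp <- cpdag_polytree(cbind(a = rnorm(50), b = rnorm(50)))
  expect_equal(igraph::ecount(cp$graph), 1L)
  expect_false(any(igraph::E(cp$graph)$oriented))
})

test_that("cpdag_polytree output is an acyclic p-1 edge pattern", {
  set.seed(23)
  for (i in 1:5) {
    t <- random_arborescence(7)
    X <- simulate_nonlinear_sem(t, "linear", n = 300, noise_sd = 0.5)
    cp <- cpdag_polytree(X)
    expect_equal(igraph::ecount(cp$graph), 6L)
    dir_edges <- igraph::as_edgelist(cp$graph)[igraph::E(cp$graph)$oriented, ,
                                               drop = FALSE]
    if (nrow(dir_edges)) {
      sub <- igraph::graph_from_edgelist(dir_edges, directed = TRUE)
      expect_true(igraph::is_dag(sub))
    }
  }
})
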