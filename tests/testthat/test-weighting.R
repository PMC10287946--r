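# edge/node weighting schemes and multiple-testing utilities

test_that("cor_edge_weights matches closed-form Pearson values", {
  g <- gene_graph("x", "y")

  X <- cbind(x = c(1, 2, 3), y = c(3, 2, 1))
  gw <- cor_edge_weights(g, X)
  expect_equal(igraph::E(gw)$weight, 0)          # perfect anticorrelation

  Xr <- exact_cor_pair(0.6)                      # crafted 5-point fixture
  # closed-form Pearson oracle
  r_oracle <- sum(scale(Xr[, 1]) * scale(Xr[, 2])) / (nrow(Xr) - 1)
  expect_equal(r_oracle, 0.6, tolerance = 1e-12)
  gw <- cor_edge_weights(g, Xr)
  expect_equal(igraph::E(gw)$weight, 0.4, tolerance = 1e-12)

  set.seed(99)
  Xn <- cbind(x = rnorm(2000), y = rnorm(2000))
  gw <- cor_edge_weights(g, Xn)
  expect_gte(igraph::E(gw)$weight, 0.95)         # null |r| ~ 1/sqrt(n)
  expect_lte(igraph::E(gw)$weight, 1)
})

test_that("cor_edge_weights validates inputs and ignores affine rescaling", {
  g <- gene_graph("x", "y")
  X <- cbind(x = c(1, 1, 1), y = c(1, 2, 3))
  expect_error(cor_edge_weights(g, X), "x")
  expect_error(cor_edge_weights(gene_graph("x", "z"), X), "z")

  set.seed(5)
  X <- cbind(x = rnorm(30), y = rnorm(30))
  w0 <- igraph::E(cor_edge_weights(g, X))$weight
  X2 <- X; X2[, "y"] <- -3 * X2[, "y"] + 7
  expect_equal(igraph::E(cor_edge_weights(g, X2))$weight, w0, tolerance = 1e-12)
})

test_that("rtoz_edge_pvalues reproduces the Fisher r-to-z statistic", {
  g <- gene_graph("x", "y")

  # equal correlations in the two groups -> p = 1
  set.seed(8)
  block <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("x", "y")))
  X <- rbind(block, block)
  groups <- rep(c("a", "b"), each = 10)
  expect_equal(igraph::E(rtoz_edge_pvalues(g, X, groups))$weight, 1)

  # r1 = 0.8, r2 = 0.2, n1 = n2 = 23 against the normal-CDF oracle
  X <- rbind(exact_cor_pair(0.8, n = 23), exact_cor_pair(0.2, n = 23))
  groups <- rep(c("a", "b"), each = 23)
  p <- igraph::E(rtoz_edge_pvalues(g, X, groups))$weight
  z_oracle <- (atanh(0.8) - atanh(0.2)) / sqrt(1 / 20 + 1 / 20)
  expect_equal(z_oracle, 2.8329, tolerance = 1e-4)
  expect_equal(p, 2 * pnorm(-z_oracle), tolerance = 1e-10)

  # collinear pair is clipped to a finite statistic with a warning
  X <- rbind(exact_cor_pair(1, n = 10), exact_cor_pair(0.2, n = 10))
  groups <- rep(c("a", "b"), each = 10)
  expect_warning(gw <- rtoz_edge_pvalues(g, X, groups), "clipped")
  expect_true(is.finite(igraph::E(gw)$weight) && igraph::E(gw)$weight > 0)

  expect_error(rtoz_edge_pvalues(g, X[c(1:3, 11:20), ], groups[c(1:3, 11:20)]),
               ">= 4")
})

test_that("rtoz p-values are uniform under a permutation null", {
  set.seed(1234)
  n <- 60; p_genes <- 50
  X <- matrix(rnorm(n * p_genes), n, p_genes,
              dimnames = list(NULL, paste0("g", 1:p_genes)))
  pr <- t(combn(colnames(X), 2))[1:500, ]
  g <- gene_graph(pr[, 1], pr[, 2])
  groups <- sample(rep(c("a", "b"), each = n / 2))
  pv <- igraph::E(rtoz_edge_pvalues(g, X, groups))$weight
  ks <- suppressWarnings(ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("node_group_stats behaves under null and shifted alternatives", {
  # permutation null: ~0 BH discoveries at m = 500, over 20 seeds
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    X <- matrix(rnorm(40 * 500), 40, 500, dimnames = list(NULL, paste0("g", 1:500)))
    st <- node_group_stats(X, rep(c("a", "b"), each = 20))
    sum(st$p_adj < 0.05)
  }, 0L)
  expect_lte(mean(hits), 0.5)

  # one gene shifted by 3 SD is detected
  set.seed(77)
  X <- matrix(rnorm(40 * 50), 40, 50, dimnames = list(NULL, paste0("g", 1:50)))
  X[21:40, "g7"] <- X[21:40, "g7"] + 3
  st <- node_group_stats(X, factor(rep(c("ctrl", "case"), each = 20),
                                   levels = c("ctrl", "case")))
  expect_lt(st$p_adj[st$gene == "g7"], 0.05)
  expect_equal(st$sign[st$gene == "g7"], 1)   # case minus control

  # single-gene matrix: BH with m = 1 leaves p unchanged
  X1 <- matrix(rnorm(20), 20, 1, dimnames = list(NULL, "g1"))
  st <- node_group_stats(X1, rep(c("a", "b"), each = 10))
  expect_equal(st$p_adj, st$p)

  # untestable gene flagged, output length preserved
  X[, "g3"] <- 5
  st <- node_group_stats(X, rep(c("a", "b"), each = 20))
  expect_equal(nrow(st), 50L)
  expect_equal(st$flag[st$gene == "g3"], "degenerate")
  expect_equal(st$p_adj[st$gene == "g3"], 1)
})

test_that("bh_adjust matches hand-stepped values and its properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(c(0.005, 0.5)), c(0.01, 0.5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(2)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))  # monotone in rank
    expect_equal(adj, p.adjust(p, "BH"), tolerance = 1e-12)  # cross-check
  }
})

test_that("bonferroni_combine applies the printed formulas", {
  expect_equal(bonferroni_combine(c(0.01, 0.2, 0.5)), 0.03)
  expect_equal(bonferroni_combine(c(0.9, 0.9), kind = "two_sided_pair"), 1)
  expect_equal(bonferroni_combine(c(0.004, 0.5, 0.6, 0.7, 0.8)), 0.02)
  expect_error(bonferroni_combine(numeric(0)), "empty")
  expect_error(bonferroni_combine(c(0.1, 0.2, 0.3), kind = "two_sided_pair"),
               "exactly two")
})
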