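# Generators for every input the pipeline needs: multivariate-normal
# case/control datasets with a planted perturbed module, nonlinear-SEM
# samples on a known arborescence, and a scale-free reference network
# stand-in with the true module planted as a connected subgraph.

#' Simulation configuration
#'
#' Declares the case/control simulation scenarios. Scenarios 1-3 plant a
#' 50-gene module with mean shift delta of 1.0, 0.8 and 0.6 respectively
#' and within-module case correlation 0.7; scenario 4 plants a 40-gene
#' module with delta 0.8 and correlation 0.5; the "white" scenario carries
#' no signal. Background genes are uncorrelated with unit variance
#' (`rho_control = 0`). All values can be overridden.
#'
#' @param scenario one of `"1" .. "4"`, `"white"`.
#' @param p number of genes.
#' @param n_per_group subjects per group.
#' @param module_size,delta,rho_case,rho_control optional overrides of the
#'   scenario defaults.
#' @param replicates number of simulation replicates for study runs.
#' @param seed base RNG seed.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(scenario = c("1", "2", "3", "4", "white"),
                              p = 500L, n_per_group = 20L,
                              module_size = NULL, delta = NULL,
                              rho_case = NULL, rho_control = NULL,
                              replicates = 100L, seed = 1L) {
  scenario <- match.arg(as.character(scenario), c("1", "2", "3", "4", "white"))
  defaults <- switch(scenario,
    "1" = list(module_size = 50L, delta = 1.0, rho_case = 0.7, rho_control = 0),
    "2" = list(module_size = 50L, delta = 0.8, rho_case = 0.7, rho_control = 0),
    "3" = list(module_size = 50L, delta = 0.6, rho_case = 0.7, rho_control = 0),
    "4" = list(module_size = 40L, delta = 0.8, rho_case = 0.5, rho_control = 0),
    "white" = list(module_size = 50L, delta = 0, rho_case = 0, rho_control = 0))
  cfg <- list(scenario = scenario, p = as.integer(p),
              n_per_group = as.integer(n_per_group),
              module_size = as.integer(module_size %||% defaults$module_size),
              delta = delta %||% defaults$delta,
              rho_case = rho_case %||% defaults$rho_case,
              rho_control = rho_control %||% defaults$rho_control,
              replicates = as.integer(replicates), seed = as.integer(seed))
  if (cfg$module_size > cfg$p) validation_error("module size exceeds gene count")
  if (abs(cfg$rho_case) >= 1 || abs(cfg$rho_control) >= 1)
    validation_error("correlations must lie in (-1, 1)")
  if (cfg$replicates < 1L) validation_error("at least one replicate required")
  structure(cfg, class = "sim_config")
}

# n draws from a compound-symmetric MVN block with unit variances
rmvn_cs <- function(n, m, rho, mean = 0) {
  if (m == 0L) return(matrix(numeric(0), n, 0L))
  if (1 + (m - 1) * rho <= 0)
    validation_error(sprintf("correlation %g is not positive definite for block size %d", rho, m))
  X <- if (rho == 0) {
    matrix(stats::rnorm(n * m), n, m)
  } else if (rho > 0) {
    common <- stats::rnorm(n)
    sqrt(rho) * common + sqrt(1 - rho) * matrix(stats::rnorm(n * m), n, m)
  } else {
    S <- matrix(rho, m, m); diag(S) <- 1
    matrix(stats::rnorm(n * m), n, m) %*% chol(S)
  }
  X + mean
}

#' Simulate a case/control expression pair with a planted module
#'
#' The control matrix is standard multivariate normal. In the case matrix
#' the module genes receive mean `delta` and pairwise correlation
#' `rho_case` (compound-symmetric block, unit variances); background genes
#' have mean 0 and correlation `rho_control`. Module genes are drawn at
#' random from the gene set.
#'
#' @param cfg a [simulation_config()]; its `seed` drives all randomness.
#' @return list with `control` and `case` (n x p matrices with gene
#'   columns and subject rownames) and `truth` (module gene set and the
#'   scenario parameters).
#' @export
simulate_case_control <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  genes <- gene_ids(cfg$p)
  module <- sort(sample(genes, cfg$module_size))
  n <- cfg$n_per_group
  control <- matrix(stats::rnorm(n * cfg$p), n, cfg$p,
                    dimnames = list(paste0("ctrl", seq_len(n)), genes))
  case <- matrix(NA_real_, n, cfg$p,
                 dimnames = list(paste0("case", seq_len(n)), genes))
  bg <- setdiff(genes, module)
  case[, bg] <- rmvn_cs(n, length(bg), cfg$rho_control)
  case[, module] <- rmvn_cs(n, length(module), cfg$rho_case, mean = cfg$delta)
  list(control = control, case = case,
       truth = list(module = module, scenario = cfg$scenario,
                    params = cfg[c("p", "n_per_group", "module_size",
                                   "delta", "rho_case", "rho_control")]))
}

#' Simulate nonlinear-SEM samples on a known arborescence
#'
#' The root is standard normal; in topological order every child equals
#' `f(parent)` plus Gaussian noise, with `f` one of the cubic (`y^3`),
#' sine, `y + y^2 + y^3` or identity (linear) forms.
#'
#' By default (`standardize_parent = TRUE`) each structural function is
#' applied to the standardized parent values, i.e. `f_j(y) = f(y / sd(y))`.
#' Unbounded forms iterated down a deep tree otherwise explode
#' double-precision range (a chain of cubics multiplies the variance by
#' roughly `15 * sd^4` per level), which destroys every downstream fit;
#' rescaling the argument keeps all nodes on comparable scale while leaving
#' the parent-child mechanism nonlinear.
#'
#' @param t a [directed_tree()].
#' @param f_family structural function family.
#' @param n number of samples.
#' @param noise_sd standard deviation of the additive errors.
#' @param seed optional RNG seed.
#' @param standardize_parent apply `f` to the standardized parent values.
#' @return n x p numeric matrix with the tree's nodes as columns.
#' @export
simulate_nonlinear_sem <- function(t, f_family = c("cubic", "sine", "poly123", "linear"),
                                   n, noise_sd = 0.3, seed = NULL,
                                   standardize_parent = TRUE) {
  stopifnot(inherits(t, "directed_tree"))
  f_family <- match.arg(f_family)
  if (!is.null(seed)) set.seed(seed)
  f <- switch(f_family,
              cubic = function(y) y^3,
              sine = function(y) sin(y),
              poly123 = function(y) y + y^2 + y^3,
              linear = function(y) y)
  X <- matrix(NA_real_, n, length(t$nodes),
              dimnames = list(NULL, t$nodes))
  X[, t$root] <- stats::rnorm(n)
  todo <- setdiff(t$nodes, t$root)
  while (length(todo)) {
    ready <- todo[vapply(todo, function(j) !anyNA(X[, t$parent[[j]]]), TRUE)]
    for (j in ready) {
      yp <- X[, t$parent[[j]]]
      if (standardize_parent) yp <- yp / stats::sd(yp)
      X[, j] <- f(yp) + stats::rnorm(n, sd = noise_sd)
    }
    todo <- setdiff(todo, ready)
  }
  X
}

#' Scale-free reference network stand-in
#'
#' Connected preferential-attachment (Barabasi-Albert) graph used as a
#' desk-scale surrogate for a pathway-derived interactome: heavy-tailed
#' degree distribution, `p` nodes named like the simulated genes.
#'
#' @param p number of nodes (`>= attach_m + 1`).
#' @param attach_m edges attached by each incoming node.
#' @param seed optional RNG seed.
#' @return undirected igraph object.
#' @export
random_ppi_like_network <- function(p, attach_m = 3L, seed = NULL) {
  if (p < attach_m + 1L) validation_error("'p' must exceed 'attach_m'")
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::sample_pa(p, m = attach_m, directed = FALSE)
  igraph::V(g)$name <- gene_ids(p)
  igraph::simplify(g)
}

#' Plant a connected module into a reference network
#'
#' Wires the module genes into a random spanning tree (each gene attaches
#' to a uniformly chosen earlier module gene) and adds those edges to the
#' network, so the ground-truth module is guaranteed connected.
#'
#' @param g undirected igraph containing all module genes.
#' @param module character vector of module genes.
#' @param seed optional RNG seed.
#' @return the augmented igraph object.
#' @export
plant_module <- function(g, module, seed = NULL) {
  validate_gene_graph(g)
  missing <- setdiff(module, igraph::V(g)$name)
  if (length(missing))
    validation_error(sprintf("module gene(s) absent from network: %s",
                             paste(missing, collapse = ", ")))
  if (length(module) < 2L) return(g)
  if (!is.null(seed)) set.seed(seed)
  perm <- sample(module)
  anchors <- vapply(2:length(perm),
                    function(i) perm[sample.int(i - 1L, 1L)], "")
  g2 <- igraph::add_edges(g, rbind(perm[-1L], anchors))
  igraph::simplify(g2)
}

#' Seed-based Steiner-tree module detector
#'
#' Builds the detector used in the simulation study: differential
#' expression (Welch + BH at `seed_alpha`) selects seed genes, the network
#' edges are weighted either by `1 - |cor|` (`weighting = "cor"`) or by
#' Fisher r-to-z differential co-expression p-values
#' (`weighting = "rtoz"`), and Kou's Steiner tree connects the seeds. The
#' detector returns the tree's gene set.
#'
#' @param weighting edge weighting scheme.
#' @param seed_alpha BH threshold for seed selection.
#' @return a function `(network, case, control) -> character vector`.
#' @export
steiner_detector <- function(weighting = c("rtoz", "cor"), seed_alpha = 0.05) {
  weighting <- match.arg(weighting)
  function(network, case, control) {
    X <- rbind(control, case)
    groups <- factor(rep(c("control", "case"), c(nrow(control), nrow(case))),
                     levels = c("control", "case"))
    stats_tab <- node_group_stats(X, groups)
    seeds <- intersect(stats_tab$gene[stats_tab$p_adj < seed_alpha],
                       igraph::V(network)$name)
    if (length(seeds) < 2L) return(seeds)
    gw <- if (weighting == "rtoz") rtoz_edge_pvalues(network, X, groups)
          else cor_edge_weights(network, X)
    tree <- kou_steiner(gw, seeds)
    igraph::V(tree)$name
  }
}

#' Run the case/control simulation study for one detector
#'
#' For each requested scenario and replicate: simulate a case/control pair,
#' build the reference network with the true module planted, run the
#' detector, and score its gene set against the ground truth with
#' [enrichment_metrics()]. Replicates whose detected module has at most one
#' node are excluded from the averages, as are detector failures (recorded
#' separately).
#'
#' @param cfg a [simulation_config()]; `replicates` and `seed` are taken
#'   from it (per-replicate seeds are `seed + replicate` offsets).
#' @param detector function `(network, case, control) -> character vector`.
#' @param scenarios character vector of scenario ids to run (default: the
#'   configured one).
#' @param attach_m preferential-attachment parameter of the network
#'   stand-in.
#' @param verbose print one line per scenario.
#' @return data.frame with one row per scenario: mean precision, recall and
#'   F1 over included replicates, plus `n_included` and `n_failed`.
#' @export
run_simulation_study <- function(cfg, detector, scenarios = NULL,
                                 attach_m = 3L, verbose = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  scenarios <- as.character(scenarios %||% cfg$scenario)
  out <- lapply(scenarios, function(sc) {
    prec <- rec <- f1 <- numeric(0)
    n_failed <- 0L; n_small <- 0L
    for (r in seq_len(cfg$replicates)) {
      rep_seed <- (cfg$seed + 7919L * match(sc, c("1", "2", "3", "4", "white")) +
                     r) %% .Machine$integer.max
      sccfg <- simulation_config(sc, p = cfg$p, n_per_group = cfg$n_per_group,
                                 replicates = 1L, seed = rep_seed)
      sim <- simulate_case_control(sccfg)
      net <- random_ppi_like_network(cfg$p, attach_m = attach_m,
                                     seed = rep_seed + 1L)
      net <- plant_module(net, sim$truth$module, seed = rep_seed + 2L)
      genes <- tryCatch({
        # detectors declaring a fourth argument receive the ground truth
        # (used by oracle detectors in calibration checks)
        if (length(formals(detector)) >= 4L)
          detector(net, sim$case, sim$control, sim$truth)
        else detector(net, sim$case, sim$control)
      }, error = function(e) e)
      if (inherits(genes, "error")) { n_failed <- n_failed + 1L; next }
      if (length(genes) <= 1L) { n_small <- n_small + 1L; next }
      m <- enrichment_metrics(genes, sim$truth$module)
      prec <- c(prec, m[["precision"]])
      rec <- c(rec, m[["recall"]])
      f1 <- c(f1, m[["f1"]])
    }
    if (verbose)
      message(sprintf("scenario %s: %d included, %d excluded (<2 nodes), %d failed",
                      sc, length(f1), n_small, n_failed))
    data.frame(scenario = sc,
               mean_precision = mean(prec), mean_recall = mean(rec),
               mean_f1 = mean(f1),
               n_included = length(f1), n_excluded = n_small,
               n_failed = n_failed, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
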