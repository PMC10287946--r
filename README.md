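# treesem

Tree-based structure learning for gene networks with structural equation
models.

## The problem

Active-module detection asks: given a genome-scale interaction network
and expression profiles for two groups of subjects (say, cases and
controls), which connected subnetwork carries the condition-specific
signal? And once a module is in hand: which way does influence flow
through it, and how strongly is each gene and each regulatory path
perturbed between the groups?

`treesem` answers both questions with trees. Trees — undirected or
directed — are deliberately simple models of a biological network, but
they admit exact, fast structure search and give every downstream
statistic (per-node effects, per-path effects) a closed form. The package
provides:

* **Steiner-tree module detection (ST)** — Kou's 2-approximation connects
  a set of seed genes (e.g. differentially expressed genes) through a
  weighted interactome in the most compact way. Edge weights are either
  `1 - |cor|` (co-expression) or Fisher r-to-z differential-co-expression
  p-values.
* **Minimum spanning trees (MST)** — Prim's algorithm on a weighted
  graph, or on the complete co-expression graph.
* **Causal additive trees (CAT)** — a *directed* tree learned from data:
  every ordered gene pair `(k -> j)` is scored by the residual-variance
  ratio of a penalized-spline regression,
  `w = 1/2 * log(sigma_r / s_r)`, and Chu–Liu–Edmonds extracts the
  minimum-weight spanning arborescence. For nonlinear relations the
  anticausal direction has strictly larger residual variance, which is
  what makes the orientation identifiable; for linear relations the
  weight degenerates to the symmetric `-MI = log(1 - |cor|)`.
* **CPDAG polytrees** — Chow–Liu skeleton plus marginal-independence
  collider orientation: the Markov-equivalence class when directions are
  only partly identifiable.
* **Perturbation statistics** — per-node SEM group effects (activation /
  inhibition p-values `P+`/`P-`, DEG counts, module p-value
  `2*min(P+, P-)`) and per-path average causal effects with the
  Bonferroni-style combination `K * min(p)` across the `K` source–sink
  paths.
* **Node merging** — minimax-linkage clustering with prototypes; cutting
  at height `h` guarantees every merged gene has `|cor| >= 1 - h` with
  its prototype, capping module size (~200 nodes) without losing
  interpretability.
* **Simulation study** — multivariate-normal case/control generators with
  a planted module, a scale-free interactome stand-in, nonlinear-SEM
  samplers on known arborescences, and a detector-agnostic scoring loop
  (precision / recall / F1 against the planted truth).

## Worked example

Simulate a case/control dataset (scenario 1: a 50-gene module with mean
shift 1.0 and within-module correlation 0.7 planted among 500 genes, 20
subjects per group), detect the module with the r-to-z-weighted Steiner
tree, convert it to a causal additive tree, and test the perturbation:

```r
library(treesem)

cfg    <- simulation_config("1", seed = 7)
sim    <- simulate_case_control(cfg)
net    <- plant_module(random_ppi_like_network(500, seed = 8),
                       sim$truth$module, seed = 9)
X      <- rbind(sim$control, sim$case)
groups <- factor(rep(c("control", "case"), each = 20),
                 levels = c("control", "case"))

# seeds = BH-significant differentially expressed genes (Welch test)
stats <- node_group_stats(X, groups)
seeds <- stats$gene[stats$p_adj < 0.05]      # 14 seed genes here

# Steiner tree on differential co-expression weights
gw   <- rtoz_edge_pvalues(net, X, groups)
tree <- kou_steiner(gw, seeds)               # 27-node module
enrichment_metrics(igraph::V(tree)$name, sim$truth$module)
#> precision    recall        f1
#>     1.000     0.540     0.701

# convert the undirected module to a directed tree and evaluate it
cat_t <- cat_tree(X[, igraph::V(tree)$name], skeleton = tree)
cat_t
#> directed tree: 27 nodes, root 'g181', total weight -3.665104

gsa <- gsa_summary(fit_tree_sem(cat_t, X, groups))
gsa$deg_count        # 16 DEGs among the 27 module genes
gsa$p_activation     # 3.22e-33  -> the module is activated in cases
gsa$p_node           # 6.45e-33  =  2 * min(P+, P-)

ace_paths(cat_t, X, groups)
#> perturbation report: K = 119 paths, 47 significant, combined P = 0.01625
```

Every detected gene is a true module gene (precision 1.00), 27 of the 50
planted genes were recovered (recall 0.54), and the directed tree shows a
strongly activated module: 47 of its 119 root-to-leaf regulatory paths
differ significantly between groups after BH correction.

## Command line

```sh
inst/cli/treesem simulate --scenario 1 --seed 7 --out sim/
inst/cli/treesem tree --type mst --data sim/case.tsv --out out/
inst/cli/treesem study --scenarios 1,3 --replicates 100 --weighting rtoz --seed 1 --out study/
```

Subcommands: `weight`, `tree` (`st`/`mst`/`cat`/`cpdag`), `merge`,
`evaluate`, `simulate`, `study`. Validation errors exit with status 2;
every run writes a JSON manifest recording inputs, parameters and seed.

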