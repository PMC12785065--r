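# lazynet

One-step log–linear–exp neural ODE modelling of two-snapshot CRISPR
perturbation screens, with elasticity-based network inference and the
matching validation statistics.

## The problem

Pooled CRISPR activation/interference screens with single-cell RNA readout
(Perturb-seq) record, for every cell, which gene was perturbed and the
resulting expression state — but only **two snapshots** per perturbation: a
baseline ("time-0") and one post-perturbation state. `lazynet` treats that
pair as a single explicit Euler step of an underlying gene-regulatory ODE

```
x_{n+1} = x_n + F(x_n) Δt,          F(x) = V · exp(W₂ · log(W₁ x + b₁) + b₂)
```

where the rate law `F` is a log–linear–exp (LLE) block with a signed output
map `V`. Working in log space makes each hidden unit an exact monomial
`c · x₁^{α₁} ⋯ x_d^{α_d}`: a `K`-term power-law rate law over `d` genes is
represented *exactly* with `K(d+1)` trainable scalars (exponent rows in
`W₂`, log-coefficients in `b₂`). Because most biochemical rate laws are
finite sums of such monomials, the architecture encodes multiplicative
gene–gene interactions (including synergies) as first-class parameters
rather than emergent behaviour, and stays CPU-tractable.

The fitted model exposes **elasticities** — Jacobian sensitivities
`S[g, i] = ∂(predicted xᵢ)/∂x_g` at a baseline state, averaged over an
ensemble of replicate fits. Rows are sources: row `g` lists the genes
downstream of `g`. Seeded breadth-first expansion over `|S|` (magnitude
floor + per-gene percentile cutoff + top-N per hop) turns the matrix into a
compact directed subgraph, and the package ships the statistics used to
judge such graphs against external evidence:

* benchmark recall and fold enrichment over uniform random gene selection,
* matched-null co-expression enrichment (expression- and degree-matched
  random pairs, unsigned / sign-matched / opposite-sign variants),
* one-tailed hypergeometric edge overlap against a reference network,
* reference-graph density versus size-matched random gene sets and
  degree-preserving Maslov–Sneppen rewiring,
* protein-layer concordance: MinProb left-censored imputation, per-edge
  Spearman correlations, and a 21-bin degree-matched null with a Wilcoxon
  rank-sum comparison.

A fully synthetic-data module generates ground-truth monomial systems,
two-snapshot screens with control/singlet/multiplet guide structure and a
negative-binomial count readout, and reference tables with planted signal —
so every stage of the pipeline is exercised end-to-end against a known
answer.

## Worked example

```r
library(lazynet)

# a small synthetic screen: 10-gene monomial network, 40 background genes
cfg <- screen_sim_config(n_genes = 10, n_terms = 14, n_background_genes = 40,
                         n_control_cells = 100, n_singlet_cells = 600,
                         n_multiplet_cells = 50, seed = 1)
sim <- simulate_guide_screen(cfg)

prep <- prepare_snapshot_pairs(sim$counts, sim$guides, hvg_fraction = 0.5,
                               min_cells_per_gene = 3, min_genes_per_cell = 20)
splits <- group_split(prep$pairs, seed = 1)
fit <- lazynet(splits$train, width = 32, replicas = 3, epochs = 800, seed = 1)
print(fit)
#> LazyNet ensemble: 3 member(s), 25 genes, width 32, Huber delta 0.1
#> final training Huber loss: 0.04409, 0.04355, 0.04351

pred <- predict(fit, splits$test)
print(unlist(evaluate_regression(pred, splits$test$post)), digits = 3)
#>      rmse       mae pearson_r
#>     0.644     0.503     0.725

E <- compute_elasticity(fit, t(unique(t(splits$train$time0), MARGIN = 1)))
sg <- merge_subgraphs(lapply(c("g1", "g2"), function(s)
  expand_seed(E, s, top = 8, depth = 2, pct = 95, floor = 1e-4)))
print(sg)
#> Subgraph: 7 genes, 9 directed edges (seeds: g1, g2)

dyn <- rownames(sim$truth$support)
print(benchmark_recall(sg, benchmark = dyn, background_size = length(prep$panel)))
#> Recall 6/10 (60%); expected by chance 2.80; enrichment 2.14 (graph of 7 genes, background 25)
```

Reading the output: held-out multiplicative-noise snapshots are predicted
with RMSE 0.64 on a working scale whose targets span several units
(Pearson r 0.73); expanding two seed genes over the fitted elasticities
recovers 6 of the 10 true network genes in a 7-gene subgraph, 2.1-fold more
than a random gene set of that size would catch.

The same pipeline is available from a shell via the thin CLI in
`inst/cli/lazynet.R`:

```sh
Rscript inst/cli/lazynet.R simulate --out sim/ --seed 1
Rscript inst/cli/lazynet.R prepare  --counts sim/ --guides sim/guides.tsv --hvg 0.25 --out pairs.json
Rscript inst/cli/lazynet.R train    --pairs pairs.json --replicas 3 --out model.json --seed 1
Rscript inst/cli/lazynet.R infer-network --model model.json --pairs pairs.json \
    --seeds seeds.txt --top 32 --depth 4 --pct 99 --floor 0.001 --out graph.tsv
```

Every subcommand writes a resolved-config YAML next to its output, and
identical config + seed gives byte-identical outputs.

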