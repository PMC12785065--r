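---
title: "LazyNet methods: a one-step log-linear-exp neural ODE for two-snapshot CRISPR screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LazyNet methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lazynet)
```

## The model

A pooled CRISPR activation/interference screen with single-cell readout
yields, per perturbation, a baseline expression state and one
post-perturbation state. We treat this pair as one explicit Euler step of an
autonomous ODE over the modeled gene panel:

$$x_{n+1} = x_n + F(x_n)\,\Delta t, \qquad
  F(x) = V\,\exp\!\big(W_2 \log(W_1 x + b_1) + b_2\big).$$

The inner log / linear / exp composition (the LLE block) is the point of the
architecture: a hidden unit with exponent row $\alpha$ in $W_2$ and bias
$\log c$ in $b_2$ computes the monomial $c\,\prod_j x_j^{\alpha_j}$
*exactly* (with $W_1 = I$, $b_1 = 0$). Any finite sum of signed monomials —
the form of most mass-action and power-law rate laws — is therefore
representable with $K(d+1)$ trainable scalars plus signs, and
`embed_monomial_system()` performs that construction explicitly. The package
verifies the exactness claim property-style: over 100 random sparse systems,
the embedded model agrees with direct rate-law evaluation to $10^{-10}$
relative error.

Two departures from the bare printed form are deliberate:

* **Signed output map.** A pure `exp` output is strictly positive and could
  never decrease expression. `F` is therefore a signed combination
  $V\,m(x)$ of positive hidden rates $m(x)$; in embedded models $V$ holds
  the $\pm 1$ production/decay routing, in fitted models it is a free real
  matrix (the "learned output signs" choice, generalized).
* **Clamped log argument.** $W_1 x + b_1$ can drift non-positive during
  optimization; the argument is clamped at `eps_floor` ($10^{-8}$) before
  the log, which preserves finite gradients. The same floor clamps the Euler
  update so states stay positive.

### What is, and is not, identifiable

With only two snapshots, the absolute time step is not identifiable: a model
with step $\Delta t = a$ is exactly the model with $\Delta t = 1$ and
$b_2 + \log a$ (tested as an invariant). `dt` is therefore fixed to 1 during
fitting, and all downstream use of the model emphasizes rankings and signs,
which are invariant to that rescaling. Multi-step behaviour
(`simulate.lazynet()`) is qualitative extrapolation only; delays and
oscillations are outside the model class.

## Fitting

`lazynet()` fits `replicas` independently seeded models by full-batch
Adam-style gradient descent on the mean Huber loss
($\delta = 0.1$ by default — residuals on the sparse working scale are
heavy-tailed, and the small $\delta$ keeps outlying cells from dominating)
and returns the ensemble; prediction is the arithmetic mean over members.
Gradients are closed-form matrix algebra, so fitting is deterministic and
bitwise reproducible per seed.

During fitting the inner layer is held at the identity with a learnable
positive offset $b_1$ (initialized at 1). Each hidden unit is then exactly a
learnable monomial in the shifted inputs; the hidden width `width`
(default 64 at the test scale; several hundred is the sensible range at
transcriptome scale) is the number of monomial units. A single log–exp pair
is used throughout: stacking further pairs is numerically fragile in this
residual setting and is not supported.

Tunables with their defaults and rationale:

| parameter | default | role |
|---|---|---|
| `delta` | 0.1 | Huber transition point, working-scale units |
| `width` | 64 | hidden monomial units; underfits if far too small |
| `lr` | 0.02 | Adam step size; stable across the tested regimes |
| `epochs` | 1500 | full-batch iterations; see problem sizes below |
| `weight_decay` | 1e-4 | ridge on $W_2$, $V$; see identification note |
| `eps_floor` | 1e-8 | log-argument and positivity clamp |
| `wall_time` | Inf | per-replica cap; last checkpoint within the cap is kept |

A validation set (`val_pairs`) enables best-checkpoint selection on
validation Huber loss, evaluated every 25 epochs. A non-finite loss aborts
with a diagnostic rather than silently continuing — the known failure mode
of over-deep or over-wide variants. Exponents are capped ($u \le 30$ before
`exp`) as an overflow guard; the cap never binds in a healthy fit.

**Why weight decay matters here.** Screen-style training inputs are highly
degenerate: every time-0 vector is the control baseline with a single edited
coordinate, so the data constrain the fitted map along a few dozen
directions. Without a mild ridge the interpolant's *gradients* — exactly
what elasticity analysis reads out — are free to be wild off those
directions. The default `1e-4` was chosen as the smallest value that
stabilized Jacobian rankings in the synthetic regime.

## Data preparation

`prepare_snapshot_pairs()` chains the standard steps, each available
separately: QC (genes detected in ≥ 3 cells, cells with ≥ 200 detected
genes, inclusive bounds, gene-pass first), library-size normalization to the
median per-cell total followed by $z = \log(x + \varepsilon)$ with
$\varepsilon = 1$ on the counts scale, and a frozen highly-variable-gene
panel (top fraction by variance of the working-scale values; ties broken
lexicographically so the panel is deterministic). Variance of the normalized
log values was chosen as the dispersion statistic for its reproducibility;
it is the only place a different HVG statistic would plug in.

Time-0 states are built without leakage: the per-gene mean over control
(non-targeting) cells, with a single edit at the target — a small
working-scale floor for interference/knockout, or the observed mean post
level of the target across its perturbed cells for activation. The floor
default is $10^{-3}$: on a $\log(x+1)$ working scale a zero count maps to 0,
so the floor sits just above the image of "absent" (a counts-scale
pseudocount would be far too high on this scale). No other coordinate is
touched, and the tests assert bit-identity of non-target coordinates.
For activation the per-target (not per-guide) mean post level is used.

Splits are group-aware: whole `(target, guide, batch)` groups are assigned
to train/validation/test at 80/10/10 by largest-remainder allocation of a
seeded shuffle, so no guide or batch straddles a partition.

## Elasticities and network expansion

`compute_elasticity()` evaluates the Jacobian of the one-step prediction
analytically (finite differences are retained as a cross-check; the two
agree to $10^{-4}$ relative on spot checks and to $10^{-6}$ against
closed-form monomial derivatives on embedded models), averages over ensemble
members, and stores the result with **rows as sources**:
$S[g,i] = \partial \hat x_i / \partial x_g$. The residual identity
contribution to the diagonal is excluded by default so entries measure
regulatory influence only.

The baseline is configurable. The conventional choice is the mean control
state; but because two-snapshot training data constrain derivatives only
near observed inputs, the package also accepts a matrix of states and
averages per-state absolute Jacobians. In the synthetic end-to-end benchmark
this observed-state averaging is decisively more reliable than a single
unobserved baseline and is what the recovery test uses. Elasticities remain
local quantities; both summaries inherit that caveat.

`expand_seed()` grows a subgraph breadth-first from a seed gene. At each
frontier gene, candidates are the union of its row (downstream) and column
(upstream) entries; a candidate survives if its magnitude is at least
`floor` (default 0.001) *and* exceeds the `pct`-th percentile of that gene's
own candidate list (per-frontier-gene, not global — each seed's ranked list
defines its own cutoff). The `top` strongest surviving neighbor genes are
added (ties by gene id), already-visited genes contribute edges but are not
re-expanded. Empirical upper-tail p-values from the global off-diagonal
distribution are attached and Benjamini–Hochberg filtered at `bh_q`; the
default `bh_q = 1` is a pass-through (no FDR filtering), with the machinery
present for stricter settings. Percentile and top-N are applied to the
row/column union rather than separately per direction.

`benchmark_recall()` reports hits, recall, the uniform-chance expectation
$|B|\,|G|/N$ and their ratio. Seed genes that are benchmark members count as
hits by default — matching the published arithmetic, where the recall cells
are consistent with seeds included — and can be excluded via
`count_seeds = FALSE`.

## Validation statistics

* **Matched-null co-expression enrichment** bins genes by control-cell mean
  expression (quintiles) and by out-/in-degree in the edge graph
  (quintiles), samples ~400 matched pairs per edge from the joint stratum of
  its endpoints, and reports observed/expected tail fractions at each
  $\tau$ (default grid 0.20, 0.40) for unsigned, sign-matched and
  opposite-sign variants. An empty stratum falls back to the full universe
  with a warning. Edges without a reference value are excluded from
  numerator and denominator alike.
* **Hypergeometric overlap** collapses directed edges to deduplicated
  unordered pairs and takes the population to be all $\binom{|U|}{2}$
  pairs of the supplied universe. The universe is an explicit argument
  because two defensible choices exist (all protein-coding genes versus the
  subgraph's own gene set) and they give very different p-values; the
  package refuses to guess.
* **Density null**: reference links among the node set over
  $\binom{n}{2}$, compared with 1000 size-matched uniform draws; empirical
  p uses the add-one correction $(1 + \#\{\text{null} \ge \text{obs}\}) /
  (1 + n_{\text{draws}})$ so resampling never reports exactly zero.
* **Maslov–Sneppen rewiring** delegates to igraph's degree-preserving swap
  machinery; "1000 iterations" is interpreted as 1000 swap attempts per
  edge (`n_per_edge`), the stricter reading.
* **Quartile classes** dichotomize model and reference scores at their own
  75th percentiles into both-high / reference-only / model-only / neither.
* **Proteomics**: cleaning (flag removal, upper-casing, duplicate
  averaging, zeros → missing), MinProb imputation (per-channel
  $N(\mu - 1.8\sigma, (0.3\sigma)^2)$ from observed values only, the
  Perseus convention), $\log_2$ + per-channel median centering, per-edge
  Spearman over ≥ 3 paired finite channels, and a degree-matched null
  (degrees binned 0…19, 20+) compared by two-sided Wilcoxon rank-sum.
  Imputation precedes the log transform in the CLI pipeline, following the
  printed order of the protocol it mirrors; both orders are reachable
  through the exported functions.

## The synthetic-data generator

`simulate_guide_screen()` emulates the regime the pipeline targets: a
sparse monomial ODE (default $d = 20$ genes, $K = 30$ terms, integer
exponents in $\{-2,-1,1,2\}$, log-uniform coefficients in $[0.1, 1]$), a
damped-Euler quiet baseline (deliberately not an exact fixed point —
root-finding has no place in a fixture), 300 control cells, 2000 singlets
(two guides per target, interference and activation split by gene), 200
two-guide multiplets, multiplicative log-normal expression noise
(SD 0.1), per-cell library-size factors (CV 0.2), and a negative-binomial
readout (dispersion 0.3, ~25 counts per unit expression) — the sparse,
overdispersed regime of real screens.

Two generator features deserve explanation because they encode assumptions
rather than knobs:

* **Background transcriptome.** The readout includes 180 non-dynamical
  genes. Library-size normalization assumes the modeled panel is a small
  share of each cell's total; real screens measure tens of thousands of
  genes, so a 20-gene-only readout would make per-cell totals — and hence
  every normalized value — swing with the perturbed gene, a compositional
  artifact of miniaturization rather than a property of the method.
* **Response development.** The post snapshot is taken after 3 Euler
  substeps of the true dynamics (controls live through the same window, so
  the shared drift cancels from contrasts). A screen measures cells after
  the response has unfolded, not after an infinitesimal step; a few
  substeps give measurable direct effects while keeping multi-hop
  propagation subordinate — precisely the regime in which a one-step model
  of two-snapshot data is a sensible approximation, model misspecification
  included.

What the generator does **not** emulate: ambient RNA, doublets, batch
chemistry, cell-cycle structure, guide efficiency variation, or
transcriptome-scale gene counts. Passing tests therefore demonstrate that
the machinery is correct and well calibrated in a faithful miniature of the
design — not that the method meets any particular accuracy on real screens.

`make_reference_tables()` plants external evidence consistent with a
system: co-expression near `signal_r` on true pairs and near 0 on decoys, a
reference edge list containing a configurable fraction of true edges, and a
protein matrix in which each true pair owns a latent channel factor and
each gene mixes the normalized sum of its pairs' latents with private noise
(adjacent genes co-vary at roughly `signal_r`/√(nᵢnⱼ); non-adjacent pairs
are uncorrelated in expectation — hubs dilute, which is exactly what the
degree-matched null is for).

## Numerical choices and degenerate inputs

Quantiles use R's default type 7 everywhere. HVG and expansion ties break
lexicographically by gene id. The expansion floor excludes exact zeros by
construction (`floor > 0`). Empirical p-values use add-one corrections.
Wilcoxon tests use the exact distribution where R's implementation provides
it (small samples, no ties). Degenerate inputs fail loudly: empty QC
results, fewer than 3 groups to split, zero-variance targets
(Pearson reported as missing), single-class labels (AUCs reported as
missing), sub-coverage or constant protein profiles (excluded with
reasons), columns with fewer than two observed values (imputation error).

## Problem sizes in the shipped tests

The suite runs the full pipeline at $d = 20$, $K = 30$, 2000 singlets with
a 64-unit, 3-replica ensemble trained for 2500 epochs (about two minutes),
plus property tests at $d \le 20$. These sizes were chosen so the entire suite exercises every
claim, end to end, in a few minutes on one CPU core; nothing in the
implementation is specific to them, and the CLI accepts arbitrarily larger
inputs at proportional cost.

## Known limitations

Positive-scale modelling ties results to the normalization and pseudocount;
one Euler step cannot represent delays or oscillations and leaves $\Delta t$
unidentified; elasticities are local to the evaluation state(s); the
matched-null and degree-matched nulls control abundance and hubness but not
every conceivable confounder; and reference evidence (co-expression,
interaction databases, proteomes) measures different biological facets than
a perturbation-response Jacobian, so moderate — not perfect — concordance is
the expected healthy outcome.
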