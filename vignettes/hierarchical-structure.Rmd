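---
title: "Hierarchical Bayesian clustering of multi-allelic genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical Bayesian clustering of multi-allelic genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Bayesian admixture clustering assigns individuals to `K` latent clusters
from co-dominant multi-allelic genotypes, and the Evanno ΔK statistic is the
de-facto standard for choosing `K`. For species fragmented into many
strongly differentiated subpopulations, ΔK has a well-known failure mode: it
detects the *uppermost* level of structure — very often `K = 2` — and the
true number of genetic units is drastically underestimated. The remedy is
*hierarchical* analysis: re-run the clustering inside each inferred cluster,
recursively, until no subset can be subdivided, and count the terminal
clusters ("genetic components"). `hierstruct` implements that full loop —
the admixture Gibbs sampler, ΔK model selection, the recursion, and the
classical supporting statistics — plus a genotype simulator with known
hierarchical ground truth so that every stage can be validated.

## The admixture model and its sampler

For diploid individual `i`, locus `l` and gene copy `c`, the observed allele
`x_ilc` arises by first drawing a latent cluster of origin
`z_ilc ~ Categorical(q_i)` and then an allele from that cluster's frequency
vector, `x_ilc ~ Categorical(p_{z,l})`. Priors: each `q_i ~ Dirichlet(α,
…, α)` (admixture proportions), each `p_{k,l} ~ Dirichlet(λ, …, λ)`
(independent-frequency model), with `α` given a uniform prior on
`(0, α_max]` and updated by a random-walk Metropolis step. All three full
conditionals are conjugate, giving a plain Gibbs sweep:

* `P(z_ilc = k) ∝ q_ik · p_{k,l,x}`,
* `p_{k,l} | Z ~ Dirichlet(λ + allele counts assigned to k)`,
* `q_i | Z ~ Dirichlet(α + per-cluster copy counts of i)`.

Missing gene copies are simply skipped (no imputation): they carry no `z`,
enter no count, and contribute 0 to the likelihood. Model evidence for a run
is estimated from the thinned post-burn-in log-likelihood trace as
`Ln Pr(X|K) ≈ mean(lnL) − var(lnL)/2`, the same penalized estimator
STRUCTURE reports; the ΔK machinery consumes that quantity. The correlated
allele-frequency model, linkage model and informative-prior variants are
deliberately out of scope — the base model is fully specified and testable.

The production chain is compiled (Rcpp); Dirichlet draws use a
Marsaglia–Tsang gamma generator fed by R's RNG, so a run is a pure function
of `(data, config, seed)`. A pure-R implementation of every single update
(`mcmc_init_state()`, `mcmc_update_z/p/q/alpha()`, `run_mcmc_reference()`)
is exported and the two routes are cross-checked in the tests; the compiled
path is never its own oracle.

Label switching across replicate runs is resolved by `align_runs()`: a
greedy cluster permutation per run maximizing summed Q-column correlation
with the first run.

## ΔK model selection

`build_k_table()` implements the Evanno table over replicate runs: mean and
sample s.d. (n−1 denominator, the harvester convention) of `Ln Pr(X|K)` per
`K`, first and absolute second differences, and
`ΔK = |L''(K)| / s(K)`. `select_optimal_k()` takes the interior argmax,
breaking ties toward smaller `K`. Two conventions the source tooling leaves
unspecified are fixed here: `s(K) = 0` with `|L''| > 0` yields `+Inf` (it
wins the argmax but warns — degenerate replication), and ΔK is never
evaluated at the boundary Ks, so "no structure at all" is decided by the
hierarchy's termination rules rather than by ΔK.

## The hierarchical pipeline

`run_hierarchical()` recurses depth-first. Each node scans
`K = 1 … min(k_max, n_pops + k_slack)` with `runs_per_k` replicate chains
(top-level convention `k_max = 12`), picks `K*` by ΔK, assigns each
individual to its argmax-`q` cluster in the best (highest-lnPD) run at
`K*`, and recurses into every retained cluster. Tunables, with defaults:

| parameter | default | role |
|---|---|---|
| `min_individuals` | 10 | subsets smaller than this are terminal |
| `min_cluster_size` | 5 | smaller clusters dissolve; members reported unassigned |
| `q_threshold` | 0.6 | terminal when mean max-q falls below (symmetric Q = no structure) |
| `max_depth` | 8 | recursion cap |
| `assignment` | individual | argmax per individual; population-majority mode available |

The `q_threshold` rule is this package's operationalization of the stopping
phenomenon ("no further components found"): when a subset has no real
structure, the admixture posterior spreads each individual across clusters
(`mean max-q ≈ 1/K < 0.6` for `K ≥ 2`). Terminal nodes receive component
labels `C1, C2, …`; `population_component_summary()` calls a population
"unique" iff some component contains only that population's individuals
*and* holds a majority of them.

## The F-model simulator

Ground truth comes from a Dirichlet drift (F-model) simulator — the same
generative family the clustering model assumes, which is what makes
closed-form oracles possible. A rooted `deme_tree()` carries a drift
intensity `F ∈ (0,1)` on every branch; ancestral frequencies are drawn from
a symmetric Dirichlet(`λ_A`), each branch applies
`child ~ Dirichlet(parent · (1−F)/F)` (so `E[child] = parent`,
`Var[child_j] = F p_j(1−p_j)`), and each leaf deme's individuals draw two
gene copies per locus from the realized leaf frequencies. Whole genotypes
drop out at `missing_rate` to emulate PCR failure. Drift composes along a
path as `F_tot = 1 − Π(1 − F_edge)`.

`parametric_gst()` computes Nei's G_ST from the realized leaf frequencies —
the exact differentiation of a particular simulation, used as the recovery
target for the sample-based estimators. Two relations matter when
calibrating: for two demes whose lineages each accrued `F_tot`, pairwise
G_ST ≈ `F_tot/(2 − F_tot)` while Weir–Cockerham θ ≈ `F_tot`; with `r` demes
G_ST ≈ `F_tot(1−1/r)/(1−F_tot/r)`, converging to θ as `r` grows. Estimator
recovery tests therefore use 20-deme star trees, where the two scales agree
to < 0.02.

`study_mimic_tree()` is the package's stated reference world: 38 demes of
9–33 diploids in four clades (4, 9, 23, 2 demes; subclades 6+3 and 11+11+1),
genotyped at 12 loci with 8 alleles each. Drift values (terminal 0.40,
subclade 0.15, deep 0.25, direct-leaf 0.45) put *every* pairwise θ in the
0.37–0.74 band characteristic of an extremely fragmented, low-gene-flow
shrub metapopulation, with clade membership adding a further increment —
a shallow-but-ubiquitous hierarchy. An earlier, steeper calibration (weak
within-clade drift) made ΔK collapse to `K = 2` for essentially any
subsample, erasing the contrast the clade-composition experiment measures;
the flat-but-strong calibration reproduces the qualitative phenomena the
meta-experiments target and was frozen before the acceptance suite.

What the simulator does *not* emulate: stepwise mutation (allele sizes are
exchangeable symbols), selection, admixture between demes, isolation by
distance, genotyping artifacts other than random dropout. A green recovery
test therefore establishes correctness of the inference machinery under the
model's own assumptions — not robustness to murkier real-world data.

## Supporting statistics

* `pairwise_fst()` / `wc_theta()`: Weir–Cockerham θ (default, summed
  variance components over alleles and loci; may be slightly negative,
  reported raw) and Nei G_ST. Tested against an independent
  indicator-variable ANOVA implementation.
* `nm_from_fst()`: island-model `Nm = (1−F)/(4F)`; F ≤ 0 is an error (the
  unbounded-gene-flow case is signalled, not clamped).
* `nei_distance()`: standard (`D = −ln I`) and unbiased (sample-size
  corrected; may dip below 0, reported raw) variants; the unbiased variant
  is the default for the PCoA-on-Nei path.
* `amova_three_level()`: Excoffier-style decomposition on allele-mismatch
  distances (0/1/2 per locus), with the unequal-size coefficients, Φ
  statistics, and seeded permutation tests (individuals among pops for
  Φ_ST, within groups for Φ_SC, whole pops among groups for Φ_CT).
  Negative components are reported raw and floored at 0 only for the
  percentages. A single group degenerates to the two-level analysis.
* `upgma()`: size-weighted average linkage, merge heights = mean distance,
  leaves at height/2 (ultrametric); ties merge the first pair in current
  cluster order. Checked against `hclust(method = "average")`.
* `pcoa()`: Gower double-centering of `−d²/2` + eigendecomposition;
  negative eigenvalues are reported but excluded from percent-variance and
  carry no coordinates.

## The meta-experiments

`run_subsample_experiment()` draws random population subsets at levels
4–30 (each population at most once per draw), determines each subset's `K*`
and summarises per level — the "optimal K versus number of populations"
design. `run_clade_experiment()` draws 4-population samples, classifies
each by clade composition ("1 clade", "2 clades", "2 clades, 3+ subclades",
"3–4 clades" — the subclade refinement applies when exactly two clades are
present) and tabulates `K*` and mean pairwise F_ST per category. Clade
annotations come from simulator truth by default; `cut_upgma_clades()`
provides the tree-cut route for real data (clade cut at the height giving
the requested count, subclades by one further split of each clade root).

## Numerical choices and edge cases

* Gamma draws with near-zero shape are floored at 1e-300 before
  normalisation (prevents 0/0 simplexes and `log(0)` at extreme drift or
  tiny α); an all-zero Dirichlet draw falls back to point mass on the
  largest shape.
* `estimate_lnPD()` uses the sample variance (n−1); a constant trace
  returns its value exactly.
* Dense per-locus allele recoding happens inside `run_mcmc()`; alleles
  absent from a subset are dropped from that subset's model, as a
  re-analysis of a data subset would see.
* Argmax ties (assignment, ΔK) break toward the lowest index / smallest K,
  deterministically.
* All stochastic entry points take explicit seeds; internal per-run seeds
  derive from the master seed through a fixed 32-bit mixing function, so
  whole pipelines are bit-reproducible.

## Computational scaling

Package defaults (burn-in 2,000; 8,000 sweeps; thinning 10; 5 runs per K)
are a deliberate desk-scale reduction of production settings (100,000 /
500,000 / 12 runs), which remain one `mcmc_config()` edit away. The
acceptance tests scale chain lengths down further (never the replicate or
seed counts their criteria state): the hierarchy-recovery block uses
500/2,000-sweep chains with 3 runs per K, and the experiment-direction
block 400/1,600-sweep chains, keeping the full suite inside a CI budget on
one CPU. The sampler's cost per sweep is linear in individuals × loci × K.

## Known limitations

* Only the independent-frequency admixture model; no correlated
  frequencies, no linkage, no prior population information.
* ΔK cannot endorse `K = 1`; homogeneity is inferred only through the
  termination heuristics, whose `q_threshold` is a tunable convention.
* AMOVA skips locus comparisons where either individual is missing without
  rescaling, which slightly down-weights high-missingness pairs.
* `nm_from_fst()` is the equilibrium infinite-island conversion; published
  Nm figures produced by other toolchains frequently disagree with it, so
  cross-study comparisons should recompute Nm from F_ST rather than mix
  printed values.
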