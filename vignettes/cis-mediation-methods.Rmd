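---
title: "Methods: network-directed cis-mediation analysis of trans-eQTLs"
author: "cismediatr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-directed cis-mediation analysis of trans-eQTLs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cismediatr)
```

## The problem and the model

Risk variants discovered by association studies are mostly regulatory.
Their proximal (cis) effects on gene expression are comparatively easy to
map; their distal (trans) effects are not, because a transcriptome-wide
trans scan pays an enormous multiple-testing price. A large fraction of
trans effects, however, is believed to be relayed through a cis-regulated
intermediary — a transcription factor or signaling gene whose expression
the variant perturbs directly. `cismediatr` implements this
*cis-mediator* strategy: restrict the trans search space to genes that are
co-expressed with cis-regulated genes, then test each candidate chain
explicitly.

The causal unit is a trio: a variant **L** with additive dosage in
[0, 2], its cis gene **C** (transcript within 1 Mb of the variant), and a
distal gene **T** (at least 10 Mb from the cis gene, or on another
chromosome — the exclusion zone avoids mistaking long-range linkage
disequilibrium for trans action). The hypothesis is the chain
**L → C → T**: the trans association of L with T exists because L moves C
and C moves T.

The pipeline stages are:

1. **Covariates.** Per-sample technical covariates plus expression
   principal components (every component explaining ≥ 1% of total
   variance) absorb latent non-genetic variation.
2. **eQTL scan.** For each (variant, gene) pair, ordinary least squares
   of expression on dosage with intercept and covariates; two-sided t
   tests on `n − k − 2` degrees of freedom.
3. **Screening.** Per transcript, the smallest association p-value across
   variants is Bonferroni-adjusted for the number of risk loci; the
   adjusted values are converted to Benjamini–Hochberg q-values across
   transcripts, and transcripts with q < 0.20 enter the network. The
   level is deliberately permissive: the screen is a dimension reducer,
   not a discovery filter.
4. **Co-expression graph.** Meinshausen–Bühlmann neighborhood selection
   on the screened transcripts: an L1-penalized regression of every gene
   on all others, supports symmetrized into an undirected edge set,
   penalty chosen by stability (StARS).
5. **Peak cis selection.** Per gene, the cis variant with the smallest
   p-value; pairs significant at `0.05 / (number of cis tests)` define
   the significant cis genes.
6. **Trios.** Every graph neighbor of a significant cis gene that is
   trans-eligible with respect to that pair is a candidate trio.
7. **Mediation test.** The four-component intersection-union test below,
   Bonferroni-corrected over the realized trio count.
8. **Robustness (optional).** A genotype-stratified permutation null for
   the omnibus p-value.

## The intersection-union mediation test

`cit_test()` rejects only when *all four* component nulls are rejected,
so its omnibus p-value is the maximum of the component p-values — a
conservative test by construction:

* `p1`: L associated with T (`T ~ X + L`);
* `p2`: L associated with C given T (`C ~ X + T + L`);
* `p3`: C associated with T given L (`T ~ X + L + C`);
* `p4`: an equivalence-style test that L is *independent* of T given C.

Components 1–3 are partial F tests in nested least-squares models.
Component 4 is the interesting one: its null is that a conditional L–T
signal *remains*, so small p4 must support conditional independence.
The observed statistic is the F for L in `T ~ X + C + L`. Its reference
distribution is built by a mediator-perturbing permutation: residualize C
on the covariates, permute the residuals *within genotype classes of L*,
and add the fitted values back. The surrogate `C*` preserves the L–C and
X–C relations (class means are untouched) but severs the residual
coupling between C and T. Under pure mediation the observed F is small
while every surrogate F recovers the full marginal L–T effect, so
`p4 = (1 + #{F* ≤ F_obs}) / (B + 1)` is small; under a direct
(non-mediated) L→T effect the observed and surrogate F are exchangeable
and p4 is uniform. The default `B_cond4 = 1000` inner permutations put
the attainable floor at `1/1001`; the count is a package choice — the
omnibus construction fixes only the test, not its permutation budget.

Two summary effects accompany the test: the marginal trans slope
`beta_T` (`T ~ X + L`) and the cis-adjusted slope `beta_Tadj`
(`T ~ X + C + L`). The mediated proportion is

```
M = (beta_T − beta_Tadj) / beta_T
```

M is 1 under complete mediation, 0 when adjustment changes nothing, and
is deliberately not clamped: sampling noise can push it outside [0, 1],
and clamping would bias averages. `beta_T = 0` leaves M undefined (`NA`).
Measurement error in C attenuates its coefficient and therefore M; partial
mediation is the expected observation even when the chain is real.

### Genotype-stratified permutation robustness

`permutation_robustness()` permutes T across samples *within* genotype
classes (dosages rounded to 0/1/2), holding everything else fixed, and
recomputes the full omnibus p-value per permutation. The reported value,
`(1 + #{p* ≤ p_obs}) / (B + 1)`, uses the add-one estimator, whose floor
at `B = 100,000` is `1/100001 ≈ 1.0e-5`. Stratifying by genotype
preserves the marginal genotype–phenotype structure, so the null being
sampled is "no sample-level linkage of T to (C, X) beyond what genotype
class explains". Ties count as extreme by default ("as or more extreme");
a strict-inequality flag exists because the convention is ambiguous. The
component-4 mediator permutations are drawn once and reused across outer
permutations — the randomization scheme is then identical for every
permuted dataset, and the outer loop reduces to cross-products.

## Network estimation choices

The per-node lasso is solved by coordinate descent with warm starts along
the penalty path (glmnet); with exactly two genes the single-predictor
solution is the closed-form soft threshold (neighbor selected iff
`|r̂| > λ`), computed directly. Columns are standardized internally with
the 1/n variance convention, so `λ_max` — the smallest penalty with every
neighborhood empty — equals the largest absolute pairwise correlation.
The grid is 10 log-spaced values down to `0.1 · λ_max`.

Design points the estimator itself leaves open, and how this package
resolves them:

* **Symmetrization.** OR by default (an edge exists if either node's
  regression selects the other), matching the documented behavior of the
  reference neighborhood-selection implementation; AND is available.
* **Penalty selection.** StARS: 20 subsamples of size `⌊10√n⌋` (capped at
  `n − 1`), per-edge instability `2ξ(1−ξ)` averaged over all gene pairs,
  and the densest λ whose total instability is ≤ 0.1. We use the raw
  instability profile rather than the monotonized envelope: with very few
  genes the sparsest grid point sits exactly on the `λ_max` boundary and
  flickers across subsamples, and a monotonized envelope would let that
  boundary artifact veto every denser (stable) graph. A fixed
  `lambda_index` override pins the selection exactly.
* **Residualization.** The pipeline residualizes screened expression on
  the same covariates used for the eQTL scan before network estimation
  (flag `residualize_network` to disable). Shared technical structure
  otherwise manufactures edges.
* **Degenerate screens.** With fewer than three screened transcripts a
  graphical model is meaningless; the pipeline falls back to the complete
  graph on the screened set and logs it in the manifest. This keeps the
  desk-scale null path honest: trios still require a significant peak cis
  pair and a significant omnibus test.

## The synthetic-data generator

`simulate_genotypes()` draws integer dosages Binomial(2, MAF) under
Hardy–Weinberg equilibrium. `simulate_trio_expression()` generates

```
C = a·L + γ'U + τ_C'W + ε_C
T = b·C + d·L + δ'U + τ_T'W + ε_T
```

with latent confounders U (standing in for hidden expression factors),
two generic technical covariates W (stand-ins for the tissue-composition
covariates a real study would record), and Gaussian residuals. Background
genes come from a zero-mean multivariate normal with a known sparse
precision matrix (chain, hub, or random adjacency; edge value 0.3 and
diagonal inflated to `|λ_min| + 0.2`, the convention of the standard
graphical-model simulators). Scenario labels are derived from the effect
pattern: mediated (`a≠0, b≠0, d=0`), direct (`d≠0, b=0`), independent
(all zero), reverse (generation direction flipped).

Default study conditions, chosen once: 471 samples (the motivating
study's cohort size), MAF 0.3 (a common variant), `a = 0.5`, `b = 0.8`,
`d = 0`, unit residual scales, confounder loadings 0.5, technical
loadings 0.2, 30 background genes on a chain. Coordinates are assigned
deterministically: the cis gene 50 kb from the anchor variant, everything
else on other chromosomes (hence trivially trans-eligible).

What the generator does *not* emulate: read counts and their
normalization, linkage disequilibrium between candidate variants,
isoform structure, non-Gaussian expression tails, and cell-type
composition gradients. Passing tests therefore demonstrate correctness of
the statistical machinery under a linear Gaussian world with known truth,
not robustness to everything real tissue data does.

## Numerical conventions

* Distances: 1-based inclusive coordinates; variant-to-gene distance is 0
  inside the transcript, otherwise the gap to the nearest boundary; both
  the 1 Mb cis rule and the 10 Mb trans rule are boundary-inclusive. The
  trans exclusion is measured from the cis gene (flag for variant-based).
* The scan residualizes both sides on the covariates once and sweeps
  cross-products; by Frisch–Waugh–Lovell this equals the per-pair fit
  (verified to 1e-10 against `lm()`).
* Monomorphic variants yield `p = 1` records flagged `monomorphic`
  rather than errors; missing dosages are mean-imputed at load with a
  message; missing expression is an error.
* Peak-cis ties break by variant position, then id — deterministic across
  runs.
* BH q-values are computed by the definitional step-up
  (`cummin` of `m·p/rank`), which agrees with the brute-force definition
  bit-for-bit and with `stats::p.adjust` to floating-point noise.
* All stochastic stages (StARS subsampling, both permutation layers)
  take explicit seeds; reruns are bit-identical, and pipeline outputs echo
  the config.
* Expression-PC adjustment: with transcriptome-scale inputs the ≥ 1%
  variance rule reproduces the usual "a dozen PCs" behavior; with tens of
  genes it would keep essentially every component and regress the signal
  away, so desk-scale runs adjust for the generator's returned
  confounders directly (`compute_pcs = FALSE`, the generator returns them
  by default) and a `max_pcs` cap exists for intermediate cases.

## Validation summary and problem sizes

The test suite generates everything it checks. The main statistical
checks, at the sizes the package adopts for its own validation: type-I
error of the omnibus test under the independent and direct-only scenarios
(500 replicates each, n = 500, `B_cond4 = 500`); power and M recovery
under the mediated scenario (200 replicates, n = 1000), including the
measurement-error attenuation of M; chain and hub edge recovery
(precision/recall at n = 500, 20 genes, 100 replicates); and end-to-end
planted-trio recovery and null behavior (50 replicates each, 30
background genes). `scripts/acceptance.R` recomputes the same quantities
at reduced replicate counts and writes them as JSON.

## Limitations

The mediation test is conservative by construction (an intersection-union
test rejects only when its weakest component does), so its realized
type-I error is far below nominal and its power against weak chains is
limited. Component 4's permutation scheme assumes the genotype classes
are meaningful strata; continuous imputed dosages are rounded (a strict
flag refuses them). The graph stage assumes approximately Gaussian,
linearly related expression; no nonparanormal transform is provided. The
10 Mb trans rule is a heuristic guard against long-range LD, not proof of
distal action. And M is a ratio estimator: near-zero marginal trans
effects make it unstable, which is why trio significance is decided by
the omnibus test, never by M.
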