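---
title: "Reconstructing partially observed multiplex networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing partially observed multiplex networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muxrec)
```

## The problem

A multiplex network is a set of layers $Z = \{Z^\ell\}$ over one shared node
set $N$; each layer is an undirected, unweighted simple graph encoding one
relation type. In covert-network intelligence, transport mapping and
connectomics the recorded data are *partial topologies* $X^\ell \subseteq
Z^\ell$: per layer, only a subset of nodes is observed, and a pair of nodes
is informative only when **both** endpoints are observed. Everything else is
missing — not "absent". Reconstruction means estimating, for every
unobserved pair in every layer, the probability that a link exists.

Two features make this harder than classical link prediction. First, links
incident to a hidden node are missing wholesale, so similarity scores
computed from the observed neighborhood of a hidden node are all zero.
Second, the layers of interest are sparse (mean degrees of 1.5–12 in the
datasets that motivate the package), so the label distribution is extremely
imbalanced and evaluation must be imbalance-aware.

## The solver

`run_ema()` alternates three steps until the mean absolute change of the
unobserved probabilities between consecutive iterations drops below a
tolerance (`ema_config(tolerance = 1e-5, max_iterations = 100)`).

**E-step.** Each layer follows the configuration model: with degree
estimates $d^\ell$ and edge count $|E^\ell|$, an unobserved pair gets
$p^\ell_{ij} = \min\!\big(1,\, d^\ell_i d^\ell_j / (2|E^\ell| - 1)\big)$,
while observed pairs stay clamped to $X^\ell_{ij}$ at every iteration. The
un-clamped model value is kept for *all* pairs (`prior_p`) because the
aggregation step needs genuine priors in its denominator: if clamped
posteriors were used, any observed link would force the denominator to 1 and
the aggregation update would be a universal no-op.

**A-step.** The OR-aggregate topology has $A_{ij} = 1$ exactly when some
layer links $(i,j)$. Restricted to observations, $A_{ij}$ is known to be 1
as soon as one layer *observed* a link, and known to be 0 only when every
layer observed its absence. For pairs with witnessed evidence ($A_{ij} = 1$)
each layer's prior is conditioned on that evidence by Bayes' rule:
$p^\ell_{ij} \leftarrow \min\!\big(1,\, p^\ell_{ij} \,/\, (1 - \prod_h (1 -
p^h_{ij}))\big)$. The update never decreases a probability (the denominator
is at most 1), is skipped when the denominator is 0, never touches observed
entries, and is a no-op with a single layer (the literal update would force
every candidate pair to 1). A variant applying the update to every
unobserved pair regardless of evidence is available
(`a_step = "all_pairs"`); the evidence-gated form is the default because
conditioning on $A_{ij} = 1$ without any witness has no Bayesian
justification. `a_step = "off"` gives the classical EM ablation.

**M-step.** Degrees are re-estimated from the current probabilities. The
default is the large-$|E|$ update $d_i = \sum_j p_{ij}$; the exact update
solves the stationarity condition $d_i(2|E| - d_i) = (2|E| - 1)\sum_j
p_{ij}$ and takes the smaller quadratic root (the larger one exceeds the
layer's link count). A real root exists iff no node carries more than half
of a layer's edge ends — the no-giant-hub condition `check_hub_condition()`
screens data for. The root is evaluated in conjugate form, $d_i = s_i(2|E| -
1)/(|E| + \sqrt{|E|^2 - 2|E| s_i + s_i})$, which is algebraically identical
but avoids catastrophic cancellation when $s_i \ll |E|$; its fixed-point
residual is at machine precision across the feasible range.

## Identifying the edge count

The configuration-model probability needs a per-layer edge count, and for
the unobserved regime there is a genuine design choice
(`ema_config(edge_count = ...)`):

* `"anchor"` (default) fixes $\hat E^\ell$ at the inverse-probability
  (Horvitz–Thompson) inflation of the observed subgraph's edge count,
  $\hat E = E_{obs}\, n(n-1)/(k(k-1))$ for $k$ observed nodes, and
  constrains the approximate M-step to $\sum_i d_i = 2\hat E$ (degree
  updates are rescaled — the maximization under the fixed-mass constraint).
* `"estimate"` keeps the fully self-consistent $|E| = \sum_i d_i / 2$,
  recomputed after every M-step.
* `"known"` takes caller-supplied true counts — the same oracle the random
  baseline is granted anyway, useful for ceiling analyses.

The anchored form is the default for an identifiability reason. Under
`"estimate"` the degree *scale* is a quasi-neutral direction: a hidden
node's update is $d_i \leftarrow \sum_{j} d_i d_j / (2|E| - 1)$ with $|E| =
\sum d/2$, which is nearly invariant under $d \to \alpha d$. Starting from
the standard $d_i \sim U(1, |N|)$ initialization the total mass decays
toward the truth only algebraically (empirically $\sim 1/t$, hundreds of
iterations to tolerance on $n = 200$ problems), and the mass it settles at
can sit far above the true edge count. Because top-k ranking is scale-free
the *ranking* quality is barely affected, but convergence in the MAE sense
is, and the probability calibration is poor. Anchoring removes the neutral
direction: the iteration then contracts geometrically (typically 10–15
iterations for EM, 40–90 for EMA at tolerance $10^{-5}$). A layer with
fewer than two observed nodes has nothing to anchor on and falls back to
`"estimate"`; with no observations at all the problem is unidentifiable and
the result is just a configuration-model-consistent fixed point.

Note that fixing a small $\hat E$ *without* the sum constraint is a trap:
the $U(1,|N|)$ initialization saturates every unobserved probability at the
cap 1, row sums then keep every probability saturated, and the iteration
"converges" to the useless all-ones state. The constraint is what makes the
anchored variant sound.

## The observation model

`mask_nodes(net, fraction, shared_across_layers = FALSE, seed)` draws, per
layer, a uniform node subset of size `round(fraction * n)` (half-up) and
marks a pair observed iff both endpoints are in the subset. Unobserved
entries are stored as `NA`, never 0. By default the subsets are independent
across layers: this matches the multi-source provenance of real multilayer
data (each relation type surveilled separately) and it is the regime in
which aggregation can help — with one shared subset every pair's observation
status is identical in all layers, no pair ever has cross-layer witnessed
evidence, and the evidence-gated A-step degenerates to a no-op.
`shared_across_layers = TRUE` is provided for exactly that kind of ablation.

## The synthetic generator

`generate_multiplex(n_nodes, n_layers, degree, overlap, seed)` emulates the
regimes the solver targets: sparse layers with a prescribed degree
distribution (Poisson for homogeneous social/transport-like layers,
truncated power law for hub-dominated ones, or an explicit sequence) and a
tunable interlayer dependency. A backbone graph is drawn from the erased
configuration model (stub matching, then self-loops and multi-edges
discarded — the reconstruction model assumes simple graphs); every layer
keeps each backbone edge independently with probability $\omega$ and
supplements it with an independent configuration draw whose degrees are a
binomial $(1-\omega)$-thinning of the layer's degree model (for Poisson
degrees the thinning is exact, so the per-layer marginal is preserved for
every $\omega$). $\omega = 0$ gives independent layers, $\omega = 1$
identical ones, and the realized interlayer edge Jaccard grows monotonically
in between (reported in the `provenance` attribute). The expected fraction
of a layer's edges shared with another layer is about $\omega^2$.

Defaults used throughout the tests mirror the sparse study regime: $n =
200$, $m = 2$, Poisson mean degree 3, $\omega = 0.7$, observed fraction
$0.5$, 30 paired repetitions, solver tolerance $10^{-5}$ with a 100
iteration cap; the random-baseline calibration uses 200 repetitions and
recovery/oracle checks use $n = 300$ and 1000 random parameter pairs. These
sizes keep the full suite and the acceptance script in the minutes range
while leaving the Monte-Carlo standard errors well below the effect sizes
they probe.

## Evaluation protocol

Predictions and evaluation are restricted to the unobserved pairs — the
candidate set: pairs among observed nodes are known and scoring them would
only dilute the metrics. Probabilities are binarized top-k per layer with
$k$ equal to the true number of unobserved links, the same budget the
random baseline draws uniformly; ties at the cutoff break by canonical
(row-major) pair order so results are bitwise reproducible. A threshold
rule ($p \ge 0.5$) is available (`evaluate_reconstruction(rule =
"threshold")`). Confusion counts are reported per layer and pooled, with
MCC (zero by convention when a denominator factor vanishes) and G-mean
(undefined and excluded from averages when a class is empty).

## What the synthetic studies do and do not show

On the study conditions the aggregation-augmented solver beats its EM
ablation decisively (pooled MCC ≈ 0.10–0.12 versus ≈ 0.00, G-mean ≈ 0.35
versus ≈ 0.11): almost all of its lift comes from pairs observed linked in
one layer and unobserved in another, for which the backbone dependency makes
a true link about $\omega^2 \approx 0.5$ likely against a 1.5% base rate.

Two findings deserve emphasis because they qualify what passing tests say
about real data.

*EM versus random under Poisson degrees.* With Poisson layer degrees a
node's observed degree is exactly uninformative about its hidden link count
(thinning a Poisson gives independent components), so degree-product ranking
carries no signal on the candidate set and EM equals the random baseline *in
expectation* under these conditions — their mean-MCC ordering at any finite
repetition count is sampling noise. EM's advantage over random requires
overdispersed (e.g. power-law) degrees, which the generator supports; real
covert networks are strongly overdispersed, which is why EM is a meaningful
baseline there.

*Layer-count effect.* Under top-k binarization the EMA−EM gap *grows* from
2 to 3 layers here (≈ 0.117 to ≈ 0.130): with a single shared backbone the
per-pair precision of witnessed evidence stays $\approx \omega^2$ while the
volume of evidence grows with the number of other layers. The often-cited
dilution of aggregate evidence with more layers acts through the magnitude
of the Bayes boost $p/(1 - \prod_h (1-p^h))$, which shrinks as $m$ grows —
a mechanism that binds under threshold binarization but that rank-based
top-k scoring deliberately ignores. Analyses of layer-count effects should
therefore fix the binarization rule first, and backbone-style generators
should not be expected to reproduce dilution under top-k parity.

## Numerical and degenerate-input conventions

* Symmetry everywhere by construction: random draws and updates are made on
  $i < j$ and mirrored; diagonals are pinned to zero.
* A zero A-step denominator (all priors zero) leaves entries untouched; a
  prior of 1 in another layer makes the update equal the prior.
* `e_step()` refuses a layer whose edge-count estimate has degenerated to
  $\le 1/2$ (no mass to place).
* The exact M-step signals a structured `muxrec_infeasible` error naming the
  offending nodes when the no-giant-hub condition fails; callers can fall
  back to the approximate update.
* Non-convergence at the iteration cap is a flagged result (`converged =
  FALSE`), never an error; the full MAE trace is kept for inspection.
* Component statistics use the population standard deviation for the
  coefficient of variation of component sizes, so a single-component layer
  reports exactly 0 and a lone component is not undefined; isolated nodes
  count as size-1 components. Per-layer statistics are computed on the
  layer's active (non-isolated) nodes by default, matching how published
  multiplex tables count per-layer nodes, with `nodes = "all"` for the
  shared-node-set convention the solver itself uses.
* All seeds fan out from a single master seed through a deterministic hash,
  so every sweep cell, masking draw and initialization is reproducible in
  isolation.

## Limitations

The solver takes the node set as known — it completes links, it does not
discover nodes. Layers are binary and undirected; weights and directions are
out of scope. The configuration-model prior ignores clustering, communities
and degree–degree correlation, all present in real networks: synthetic
results here bound what the model class can do, not what richer models
could. Observation noise (false positive links) is not modeled; missingness
is node-level only.
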