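---
title: "Sampling path-based link predictions: classical and quantum-walk scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sampling path-based link predictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(walklink)
```

## The model

A link prediction method scores unconnected node pairs of a simple
undirected network by a function of the adjacency matrix, `P = f(A)`, and
the pairs with the highest scores are its predictions. For path-based
methods the score of `(i, j)` counts paths between `i` and `j`: `A²` counts
common neighbours (direct similarity), `A³` length-three paths (neighbour
similarity, the variant that performs well on protein interaction
networks, where proteins bind partners whose neighbourhoods resemble their
own). `walklink` studies *samplers*: algorithms that output pairs with
probability proportional to their score,

$$\mathcal{P}[(i,j) \mid f] = \frac{|f(A)_{ij}|^q}{\lVert f(A)\rVert_q^q},$$

normalized by the entrywise $L_{q,q}$ norm. The classical samplers use
`f(A) = A², A³` with `q = 1`; the quantum-walk sampler draws from the
measurement distribution of a continuous-time quantum walk, with `q = 2`
built into the Born rule:

$$p^{\text{even}}_{ij}(t) = \tfrac{1}{N}\,\cos(At)_{ij}^2, \qquad
  p^{\text{odd}}_{ij}(t) = \tfrac{1}{N}\,\sin(At)_{ij}^2 .$$

The cosine and sine series contain the even and odd powers of `A`
respectively, weighted by the walk time `t`, so one walk distribution
carries both similarity families, separated by a measured parity label.
Unitarity of `exp(-iAt)` forces the two parity totals to sum to one.

Not every sample is a prediction: draws landing on an existing link or on
the diagonal are *bad*. The good mask `G = J - (A + I)` marks the useful
pairs, and `p_G` — the mass of a distribution on `G` — controls the
rejection overhead `1/p_G` every sampler pays per useful sample.

## What is computed, and how

**Walk distributions.** `cos(At)` and `sin(At)` come from the symmetric
eigendecomposition `A = QΛQ'` as `Q cos(Λt) Q'` and `Q sin(Λt) Q'` —
exact to floating point. No complex exponential, statevector or gate-level
circuit is ever formed; the measurement statistics are the only quantum
object with observable consequences here, and they are classical matrices.
On real hardware the walk would instead be an ε-accurate simulation whose
query cost the resource estimator accounts separately; ε enters only
there, polylogarithmically.

**Usefulness curves.** `p_G(t)` needs the walk mass on the good mask. We
use the complement: each parity's total mass over *all* pairs is a
function of the eigenvalues alone ($\sum_k \cos^2(\lambda_k t)/N$ for the
even part), and the bad mass touches only the `N + 2|E|` diagonal and edge
entries, each computable in `O(N)` from the eigenvectors. A whole
50-point time grid therefore costs one eigendecomposition per network
instead of a dense matrix function per time point. Tests assert the
spectral route equals the dense route to 1e-12 on small graphs.

**Classical samplers.** The `A²` sampler draws a node `v` with probability
`k_v²/Σk²` (a cumulative array bisection), then two independent uniform
neighbours of `v`. Summing over `v` gives exactly the `A²` law, because
`Σ_v k_v² = ‖A²‖₁,₁`. The `A³` sampler draws an ordered adjacent pair
`(u, v)` with probability `k_u k_v / Z`, then one uniform neighbour of
each; `Z = ‖A³‖₁,₁`. Both identities hold in integer arithmetic and are
property-tested. Because `i` and `j` are drawn independently, `i = j` is
possible and counts as a bad sample — consistent with `A²` having diagonal
mass. Both samplers are verified against the brute-force exact
distribution by total variation distance and chi-square goodness of fit,
not trusted from their construction.

**Query accounting.** All classical input access flows through an oracle
offering degree, l-th neighbour and vertex-pair queries at unit cost, with
per-type counters. Neighbour lists are ordered ascending — any fixed order
yields the same distributions, ascending is deterministic and testable —
and `l` is 1-based, with `NA` as the out-of-range sentinel. The oracle
never caches: repeated queries are recounted, and caching is an
algorithm-level decision (the `A³` sampler caches the whole input it
necessarily read; the `A²` sampler deliberately does not, so its
accounting stays at `N` preprocessing queries plus 3 per draw). Vectorized
draw paths advance the counters in bulk by exactly the per-draw cost.

**Precision.** Link-removal cross-validation: each fold independently
removes a uniform 10% of links (folds resample, they do not partition — each
fold emulates one observation of the same incomplete network), the
distributions are recomputed on the training network, and the conditional
precision `p_C|G = p_C / p_G` compares mass on the held-out links to mass
on all good pairs. Where a parity's `p_G` falls below a stability floor
(default 1e-8, the small-`t` regime) the division is reported missing
rather than amplified noise; fold averages skip missing values and report
how many were skipped. Fold aggregation is the arithmetic mean, with
standard deviations alongside.

## Tunable parameters

- **Walk time `t`** (dimensionless): the one genuine hyper-parameter. It
  sets the weight of each power of `A` in the score series; small `t`
  keeps the walk near the diagonal (low `p_G`, high rejection overhead),
  large `t` costs proportionally more walk-simulation queries. No default
  is endorsed — every interface requires it explicitly. Curve experiments
  default to a 50-point grid on `[0, 5]`; precision curves start at
  `t = 0.1` to stay clear of the small-`p_G` instability.
- **`gamma`** (power-law exponent, `> 2`; typical real networks fall in
  `2 < gamma ≤ 4`) and **`k_min`** for the scale-free generator: degrees
  are drawn i.i.d. from the discrete power law truncated at `N - 1`, the
  sum forced even by incrementing one random node, and the sequence
  realized by stub pairing with degree-preserving edge switching until
  simple (non-graphical sequences are resampled, bounded retries).
- **`fraction` and `folds`** for cross-validation: defaults 0.1 and 10,
  the standard 10-fold 10%-removal protocol.
- **Dense-mode cap** (default `N ≤ 5000`): the eigendecomposition guard;
  larger networks are rejected with guidance rather than silently
  subsampled.

## Numerical choices

- At `t = 0` the walk is the identity; `p_G(0)` is returned as exact zero
  rather than the ~1e-15 spectral residue.
- Cumulative-array bisection resolves boundary ties to the lower index;
  with continuous uniforms ties have probability zero.
- Each draw consumes a fixed number of RNG variates (three uniforms), so
  seeded runs replay sample-for-sample.
- The resource estimator sets the constants and polylog factors of the
  asymptotic query statement to one: `n_s · k_max · t / p_G` is a
  comparator across parameter settings, not an absolute cost.
- The command-line `sample` runs an exact zero-`p_G` precheck (via the
  brute-force distribution) before the rejection loop, so requesting
  useful samples from a distribution with no good mass terminates with a
  report instead of looping forever — e.g. `A³` on a path or star, whose
  odd-length paths only connect existing links.

## What the synthetic generator does and does not emulate

The configuration-model generator reproduces the degree heterogeneity of
scale-free networks — the feature the complexity claims rest on, since the
quantum sampler's per-sample cost scales with the largest hub,
`k_max = O(N^(1/(γ-1)))` — and the ensemble tests recover that exponent
from generated networks within ±0.15. It does not emulate community
structure, degree correlations, clustering or the hub-sparse regime of
real interactomes and social networks. Passing tests therefore certify the
samplers' distributional correctness and the scaling of hub-driven
quantities, not prediction precision on any real network; precision
numbers from `fig3_experiment` on synthetic graphs characterize the
pipeline, not biology.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen to keep
ensemble statistics meaningful: saturation curves on scale-free networks
up to `N = 1000` (10 seeds), hub-scaling ensembles up to `N = 4000`
(20 repetitions per size), sampler equivalence at 1e5 draws on graphs of
up to 30 nodes, and cross-validation on 40-60-node graphs.

## Known limitations

- Dense eigendecomposition limits networks to a few thousand nodes; the
  spectral mask trick removes the per-time-point cost but not the one-off
  decomposition.
- Empirical total-variation distance at a finite number of draws has a
  statistical floor — the expected TV of a *correct* sampler,
  `Σ_c sqrt(2 p_c (1-p_c) / (π n)) / 2` — that grows with the spread of
  the distribution. On a 30-node ER graph at 1e5 draws this floor is
  ~0.02-0.03, so tight TV bounds there test the noise, not the sampler;
  the chi-square test is the sound check in that regime.
- Weighted, directed and multi-graphs are out of scope, as are coherent
  (superposed) oracle queries, gate-level circuit simulation, and
  ranking-based metrics (AUC, precision@k).
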