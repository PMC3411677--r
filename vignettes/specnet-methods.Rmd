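---
title: "Generating spatial networks with tunable structure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating spatial networks with tunable structure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specnet)
```

## The problem

Questions about contact networks — how a disease spreads through livestock
transports, how structure constrains dynamics on an ecological web — need
*theoretical* networks whose structure can be dialled across the whole range
observed in real systems. Most generators cover only a corner of that range;
in particular, strongly *disassortative* networks (hubs linked to leaves,
degree assortativity well below zero) are hard to produce. This package
implements a spatial generator that spans nearly the full theoretical range
of four standard measures — average local clustering, Newman degree
assortativity, fragmentation and mean degree — with five scalar knobs, plus
the surrounding experimental protocol (factorial sweep, quantile tables,
ANOVA decomposition), a non-spatial configuration-model comparator, and a
grid-search fitter for regenerating empirical targets.

## The generator

A network is produced in two stages.

**1. Node landscape.** An `l_size` × `l_size` matrix of i.i.d. Normal(0.5, 2)
values is transformed with the FFT; each Fourier coefficient at radial
frequency $f$ is multiplied by $f^{-\gamma/2}$ (DC term untouched), and the
real part of the inverse transform is kept, so spectral *power* scales as
$f^{-\gamma}$. The $n$ cells with the largest values become node
coordinates (ties broken uniformly at random; one node per cell, so nodes
are never co-located). $\gamma = 0$ reproduces uniform random placement;
$\gamma \approx 2$ gives strongly aggregated clumps. The grid is a torus:
distances wrap on both axes, which removes edge effects.

**2. Link formation.** Every unordered node pair $(i, j)$ receives weight
$$ P(i,j) \propto Fsf^{\,\mathbb{1}[\text{mixed}]}\; e^{-(d_{ij}/a)^b}, $$
where $d_{ij}$ is toroidal Euclidean distance and "mixed" means exactly one
endpoint belongs to the randomly chosen *focal* class (a fraction $F$ of
nodes; think farms that trade with very many partners). Links are drawn one
at a time with probability proportional to current weight, drawn pairs are
zeroed and the weights renormalised, until $L = \mathrm{round}(l_d\,n(n-1)/2)$
links exist. The graph is simple and undirected; isolated nodes are allowed,
as they are in time-windowed empirical transport data.

The kernel is the two-dimensional generalized normal
$\exp(-(d/a)^b)$, parameterised by its distance moments: kurtosis
$\kappa = \Gamma(6/b)\Gamma(2/b)/\Gamma(4/b)^2$ fixes the shape $b$
(monotone, inverted by bracketing to $10^{-10}$), and the standard deviation
$\sigma$ fixes the scale $a = \sigma\sqrt{\Gamma(2/b)/\Gamma(4/b)}$.
$\kappa = 10/3$ corresponds exactly to $b = 1$, the exponential kernel, used
as the default because it keeps substantial link probability at short range.

### Parameters

| knob | meaning | default | units |
|---|---|---|---|
| `n` | nodes | 500 | count |
| `l_d` | link density; mean degree is $(n-1)\,l_d$ | 0.01 | fraction of $n(n-1)/2$ |
| `gamma` | landscape continuity (aggregation) | 0 | exponent, $\ge 0$ |
| `sigma_d` | kernel sd as multiple of the landscape diagonal $D = L_{size}\sqrt2$ | 0.1 | dimensionless |
| `fsf` | focal scale factor on regular–focal pairs | 10 | $\ge 1$ |
| `f` | focal fraction | 0 | $[0,1]$ |
| `kappa` | kernel kurtosis | 10/3 | dimensionless |
| `l_size` | grid side | 100 | cells |

Broad behaviour, confirmed by the factorial sweep in the test suite:
clustering rises with `l_d` and falls with `sigma_d`; assortativity falls as
`sigma_d`, `fsf` and `f` rise (the `f` response saturates around 0.15–0.2);
fragmentation is driven mainly by `l_d` and `sigma_d`; aggregated landscapes
($\gamma > 0$) are required for the highest clustering, assortativity and
fragmentation values, even though $\gamma$ contributes little variance on
average.

## Numerical and design choices

* **Frequency convention.** Radial frequency of coefficient $(u, v)$ is the
  Euclidean norm of the standard two-sided FFT frequency pair; the DC term
  is left unscaled to avoid division by zero. The amplitude exponent is
  $-\gamma/2$ so power goes as $f^{-\gamma}$. We validated this convention
  two ways: the radially averaged log power of scaled fields recovers slope
  $-\gamma$ within ±0.3 for $\gamma \in \{1, 2\}$, and the full-grid sweep
  statistics it produces match the published behaviour of this generator
  family far better than one-sided or doubled-exponent variants we examined.
* **$\sigma$ units.** `sigma_d` is quoted relative to the diagonal of the
  landscape actually in use, $D = L_{size}\sqrt2$, so a given `sigma_d`
  means the same relative reach on any grid. Absolute grid units are
  available through `sigma`.
* **Sequential draws.** Drawing $L$ pairs one-by-one with renormalisation is
  implemented with exponential keys ($E_i/w_i$, keep the $L$ smallest),
  which has provably the same joint distribution as the literal loop and is
  a single vectorised pass; the literal loop survives in the test suite as
  an oracle, where chi-square tests confirm the equivalence.
* **Rounding.** $L$ and the focal count $\mathrm{round}(F\,n)$ use
  deterministic half-up rounding.
* **Seed streams.** One user seed derives three independent streams
  (landscape, focal assignment, link draws), so components can be varied
  independently and every sweep row can be regenerated in isolation from
  `(base_seed, combination, replicate)`.
* **Clustering convention.** Local clustering of degree-0/1 nodes is counted
  as 0 and included in the average, keeping the measure defined when
  isolated nodes exist; `isolates = "exclude"` gives the alternative
  convention. Undefined assortativity (zero degree variance at edge ends) is
  propagated as `NA`, never as 0, and such rows are dropped (and counted)
  by the sweep quantiles and ANOVA.
* **ANOVA denominator.** Each term's share is its mean square divided by the
  summed mean squares of all model terms (five main effects plus all two-way
  interactions), residual excluded; interactions are additionally pooled
  into a single "combinations" share. On the balanced full factorial the
  decomposition is order-invariant; the function warns if balance is broken
  (e.g. after dropping undefined assortativity rows).
* **Quantiles.** Linear interpolation (`type = 7`).
* **Fit error.** The regeneration fitter scores candidates by the unweighted
  sum of absolute errors over clustering, assortativity and fragmentation;
  mean degree is excluded (it is matched by construction through `n` and
  `l_d`) but included in the reported 4-measure match correlation; both the
  3- and 4-measure correlations are reported because the composition of the
  published summary correlation is ambiguous.

## The configuration-model comparator

`cmext_generate()` realises a degree sequence non-spatially, first building
triangles toward a clustering target one at a time (a failed placement —
duplicate edge or stub shortage — counts against a 1000-trial budget), then
pairing remaining stubs uniformly at random with self-loop and duplicate
rejections, restarting the matching until every stub is placed or the budget
is exhausted. Results are flagged `complete` only when realised degrees equal
the targets; partial realisations warn and report what was achieved. This is
a deliberately simple rendition of the published extended-configuration-model
idea: the precise triangle bookkeeping of the original lives in its own
literature, and this comparator is judged on its stated contracts (simple
graph, degree preservation when feasible, isolated nodes kept, best-effort
clustering).

## The synthetic study conditions

The sweep defaults are the study grid: $l_d \in \{0.01, 0.05, 0.1\}$,
$\gamma \in \{0, 0.5, 1, 1.5, 2\}$, $\sigma \in \{0.01, 0.1, 0.2, 0.3\}D$,
$Fsf \in \{10, 100, 1000\}$, $F \in \{0, 0.05, 0.1, 0.15, 0.2\}$ — 900
combinations at $n = 500$, $L_{size} = 100$, $\kappa = 10/3$. The original
experiment used 50 replicates (45,000 networks); the test suite runs 3
replicates (2,700 networks, a few minutes on one CPU), which stabilises
medians and deciles but biases *extremes* toward the centre — the tests
therefore check tail quantiles only as brackets. The regeneration checks use
the published swine-transport parameter sets ($n = 2539$, $L_{size} = 175$,
$\gamma = 1.3247$ as estimated from the empirical data; 25–50 replicates
instead of the original 200).

What the generator does *not* emulate about real transport data: directed
or repeated movements, temporal ordering, edge weights (animal counts), and
any covariate structure on nodes beyond position and the binary focal class.
Passing tests show that the structural measures of the synthetic networks
behave as published, not that any particular empirical network is captured
beyond those measures.

## Known limitations

* At the published regeneration parameter sets our replicate means fall
  inside the published across-combination ranges but not exactly on the
  published best rows (e.g. slaughterhouse assortativity ≈ −0.37 here vs
  −0.42 printed): the original regeneration searched an unpublished grid of
  parameter combinations with an implementation whose kernel-width and
  frequency conventions are not fully specified in print. The agreement of
  the full sweep statistics suggests the core algorithm is faithful; the
  residual gap is confined to those best-row comparisons.
* Pair weights are dense ($O(n^2)$ memory): $n = 2539$ needs ~150 MB of
  transient arrays; n beyond ~10⁴ would need a sparsified kernel cutoff.
* The comparator makes no attempt at degree-*dependent* assortativity
  spectra; it targets the global measures only.
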