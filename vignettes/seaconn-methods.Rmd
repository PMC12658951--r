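---
title: "Seascape connectivity, vulnerability to isolation, and MPA prioritization: models and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seascape connectivity methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seaconn)
```

seaconn models demographic connectivity for coastal species that disperse by
active movement through water — typical of most coastal fish in archipelago
seascapes, whose short larval phases make hydrodynamic transport a minor
factor — and builds three conservation-planning analyses on top of it:
habitat importance for network connectivity, vulnerability to isolation
under anthropogenic disturbance, and budgeted prioritization of cells for
protected-area expansion. This vignette documents the models, their
assumptions, the tunable parameters, and the numerical choices made where
the design was genuinely open.

## The traversal graph and least-cost distances

All layers live on one raster grid (`seascape_grid`). Water cells are nodes
of an undirected graph; land is an absolute obstacle and has no nodes. Edges
join 8-neighbouring water cells with cost

$$w_{uv} = \frac{\ell_{uv}}{(c_u + c_v)/2},$$

where $\ell_{uv}$ is the cell resolution for orthogonal moves and
$\sqrt{2}\times$ resolution for diagonal moves, and $c$ is the per-cell
conductance (inverse of traversal cost). Three conventions are ours, fixed
here and enforced by tests:

* **8-connectivity with $\sqrt2$ diagonals.** 4-connectivity overestimates
  around-island distances by up to 41%; 8-connectivity with chamfer
  weighting is the standard raster choice and, on open water with uniform
  conductance, reproduces the chamfer metric exactly.
* **Mean-conductance edge costs.** The method fixes per-cell conductances
  but not how two cells' conductances combine along a step; we use the
  arithmetic mean, mirroring the usual transition-layer convention in
  raster least-cost tooling.
* **No corner-cutting.** A diagonal edge is dropped when both orthogonal
  cells flanking the shared corner are land: a disperser cannot pass
  through the meeting point of two land cells, and one-cell-wide barriers
  must not leak.

Distances between habitat cells are exact Dijkstra shortest paths
(`least_cost_distances()`), computed from cell centre to cell centre, with
$d_{ii} = 0$, truncated at the species' maximum dispersal distance
$d_{\max}$. Truncation is applied to whichever graph is in use — baseline or
disturbed — with the same $d_{\max}$: a pair pushed beyond $d_{\max}$ by
disturbance is severed outright, which is what lets disturbance isolate
habitat completely rather than merely attenuate it.

Undisturbed water has conductance 1 everywhere. Disturbance zones 1–5
(marinas, piers, dredging and similar pressures, graded by intensity) map to
conductances 0.5, 0.4, 0.3, 0.2, 0.1. These are relative weights, not
measured passage probabilities; the mapping is configurable
(`zones_to_conductance()`), and nothing downstream depends on its exact
values beyond monotonicity.

## Dispersal kernel and connectivity matrices

Connectivity export from habitat cell $i$ to habitat cell $j$ is a
negative-exponential kernel of least-cost distance, scaled by the donor
cell's habitat quality $s_i \in \{0.5, 1\}$:

$$k_{ij} = \begin{cases} s_i\, e^{-d_{ij} / (\alpha\, d_{\max})} & d_{ij} \le d_{\max} \\ 0 & d_{ij} > d_{\max}. \end{cases}$$

$\alpha$ (default 0.3, dimensionless) sets the steepness of the decay; at
$\alpha = 0.3$ the kernel falls to $e^{-1/0.3} \approx 0.036$ at $d_{\max}$,
a moderately steep decline consistent with mark–recapture evidence that
coastal fish usually move short distances and occasionally far. Habitat
quality scales **rows only** (exports), so the matrix is symmetric under
uniform quality and row-scaled otherwise.

`build_connectivity_matrix()` assembles the sparse donor × recipient matrix
$K$; `generational_matrix()` raises it to the $g$-th matrix power.
$K^g$ accumulates connectivity over $g$ successive dispersal events and
captures stepping-stone routes: cells beyond each other's $d_{\max}$ gain
positive entries when intermediate habitat links them. $g = 3$ is the
headline setting for short-term demographic connectivity; $g = 1, 2$ are
also exposed.

Two genuinely open choices are fixed as follows:

* **Zero diagonal.** Exports are defined to *other* habitat cells, so
  $k_{ii} = 0$. A consequence worth knowing: with no self-retention, $K^g$
  holds paths of *exactly* $g$ dispersal events, so on a bare chain
  A—B—C the stepping-stone link A→C appears in $K^2$ but not in $K^3$
  (path parity); on a four-node chain it appears in $K^3$. With a nonzero
  diagonal ("waiting" allowed), $K^g$ would instead accumulate all paths up
  to length $g$. Both conventions are defensible; the zero diagonal is the
  stricter reading and is what the tests pin down.
* **$K^3$, not $K^4$.** "Three generations" is implemented as the third
  matrix power — three dispersal events.

Per-cell summaries: **exports** are row sums of $K^g$ (source importance for
the metapopulation), **imports** are column sums (external recruitment and
recolonization potential).

## Vulnerability to isolation

For each species, two generational matrices are built on the same grid and
cell ordering: Matrix A from the baseline graph and Matrix B from the
disturbance-bearing graph. The vulnerability of a habitat cell is

$$v_j = \left| \sum_i (A^g)_{ij} - \sum_i (B^g)_{ij} \right|,$$

the absolute loss of generational imports. Disturbance only lowers
conductance, so it can only lengthen least-cost paths; $B \le A$ entrywise,
imports under disturbance never exceed baseline imports, and the absolute
value equals the plain difference — the tests verify this rather than assume
it. Habitat quality is never modified by disturbance: A and B differ only
through distances. The score is a relative spatial index; it is not a
demographic rate and the package makes no attempt to convert it into one.

## MPA-network assessment

MPA polygons are rasterized by the cell-centre rule (a cell is protected
when its centre lies in at least one polygon), and overlapping designations
resolve to the strictest present — strict regulations are not overridden by
an overlapping non-strict MPA. Strict means IUCN category Ia, Ib or II; any
other or missing designation counts as non-strict. The cell-centre rule is
our convention: at a fixed 250 m grid, partial-coverage weighting is not
worth the loss of determinism.

For every feature (habitat, exports, vulnerable imports; one per species)
and each network (full, strict), `protection_fraction()` is the
amount-weighted share of the feature inside counted cells. The benchmark is
`random_expectation()`: the network's area fraction of the study area,
defined here as **all water cells** (the method never defines behaviour on
land). Randomly relocated MPAs of the same extent would on average cover
that fraction of any feature, so protection above it indicates positive
siting bias, below it residual reservation bias. The across-species summary
is an unweighted mean. The random expectation is analytic; a Monte-Carlo
test confirms it (mean protection over 1,000 random masks at coverage $p$
matches $p$ within three standard errors).

## Prioritization for network expansion

Planning units are all water cells at cost 1 each; targets are 100% of
every feature's total; existing MPAs are locked in and consume budget. The
objective is minimum shortfall:

$$\min_S \sum_f \frac{\max(0,\; T_f - \mathrm{held}_f(S))}{T_f}, \qquad |S| \le B,\; L \subseteq S.$$

The reference approach solves this with an exact integer programme; seaconn
substitutes a deterministic greedy that repeatedly adds the cell with the
largest marginal shortfall decrease, ties broken by cell index. Below
saturation the objective is modular, where greedy is exactly optimal — an
exhaustive-search oracle confirms equality on randomized small instances —
and with saturation it remains single-swap stable in tests. The greedy is
incremental, so solutions at growing budgets are **nested by construction**,
which cleanly resolves how to rank cells across budget increments (an
exact solver can shuffle cells between independent solves).

`incremental_ranking()` re-solves at budgets from 11% of the planning units
in 1% steps until all targets are met, ranking each cell by the first
increment that includes it; locked-in cells are part of every solution and
carry no rank. It also emits the mean-protection curve, including the
locked-in-only baseline point. On the default synthetic scenario the curve
is non-decreasing and reaches 1.0 at the final increment (asserted in
tests). It shows broadly diminishing returns, but is *not* reliably concave
even after smoothing — synthetic habitat is more dispersed and less
spatially congruent across species than real nursery-habitat maps, and
mid-curve convex stretches occur at some seeds — so strict concavity is
deliberately not asserted.

## The synthetic archipelago generator

Every analysis is exercised end-to-end on seeded synthetic seascapes
(`generate_scenario()`), with no external data. The generator emulates the
statistical structure the method assumes:

* **Land**: a Gaussian random field smoothed at the scenario's
  autocorrelation length and thresholded at the land-fraction quantile —
  clumped islands with an exact land fraction; draws are retried on
  deterministic sub-seeds until ≥ 80% of water forms one component.
* **Habitat**: an independent smoothed field per species plus a
  shore-proximity bias (obtained by smoothing the land indicator),
  quantile-thresholded into the three quality classes.
* **Disturbance**: the most shore-bound water cells (proximity + noise),
  with zones 1–5 assigned by rank at shares 35/25/18/13/9% of disturbed
  cells, so higher zones are rarer.
* **MPAs**: irregular blob polygons accumulated until rasterized water
  coverage hits the target fraction, categories split so that roughly the
  requested share of covered area is strict, plus one deliberate
  non-strict blob inside a strict polygon to exercise the
  strictest-designation rule.

Defaults (100 × 100 cells at 250 m, land fraction 0.25, four species with
$d_{\max}$ ~ U(1, 10) km, habitat on 15% of water per species — 10% good,
5% very good — disturbance on 15% of water, MPAs on 10.5% of water with 27%
of that strict) echo a coastal-archipelago case in which a 10.5%-protected
study area contains 2.8% strict protection. Where no reference value
existed (habitat extent, disturbance intensity, autocorrelation length,
zone shares) a single plausible value was chosen and not revisited.

What the generator does **not** emulate: bathymetry, wave exposure,
salinity/temperature gradients, realistic species-distribution structure,
or the strong spatial congruence of real nursery habitats across species.
Passing tests therefore demonstrate correctness of the algorithms under the
assumed statistical structure, not predictive realism for any real
seascape.

## Numerical and degenerate-input choices

* Generation is a pure function of (seed, parameters); per-layer substreams
  derive deterministically from the master seed.
* Distance tables store `Inf` for pairs beyond cutoff or separated by land;
  the kernel maps both to zero connectivity.
* Matrix powers are computed sparse × sparse with no thresholding of small
  entries; the $d_{\max}$ cutoff already bounds fill-in.
* Greedy ties break on the lowest cell index; budgets convert from
  fractions by rounding half up.
* Degenerate inputs: an empty MPA set rasterizes to all-unprotected (not an
  error); a zero-total feature is a hard error in assessment and
  prioritization, and the pipeline drops such features with a log line
  (e.g. vulnerability when no disturbance exists); a single habitat cell
  yields a 1 × 1 zero matrix; land sources in distance queries are errors.
* Test and acceptance problem sizes — 15 × 15 oracle fields, 50-cell
  matrix-power checks, ≤ 16-unit exhaustive prioritization instances, and
  the 100 × 100 default scenario — were chosen so each suite documents the
  property at the smallest scale where it is non-trivial.

## Known limitations

* The greedy heuristic is optimal only below target saturation; near full
  coverage it can differ from an exact solver, though nestedness (which the
  ranking needs) then comes for free.
* Vulnerability depends on the assumed zone→conductance mapping; only its
  ordering is principled.
* The kernel treats $d_{\max}$ as a hard wall; real dispersal tails are
  smoother.
* Connectivity is purely distance-based; no directional currents, no
  density dependence, no demography.
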