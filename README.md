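# seaconn

Seascape connectivity, vulnerability to isolation, and marine protected
area (MPA) prioritization for coastal species that disperse actively
through water.

Expanding PA networks toward 30×30 targets raises two coupled questions:
which habitats matter most for keeping a species' habitat network
connected, and which habitats are at risk of being cut off by human
pressures — marinas, piers, dredging — that impede movement? seaconn
implements a graph-based answer for raster seascapes and carries it
through to systematic conservation planning: it assesses how well an
existing MPA network protects connectivity, and ranks candidate cells for
network expansion. It is aimed at conservation planners and spatial
ecologists working with classified habitat maps in archipelago or coastal
settings.

## The model

Water cells form an undirected graph (land is impassable); an edge between
8-neighbouring cells costs `step_length / mean(c_u, c_v)`, where
conductance `c` is 1 in open water and drops to 0.5…0.1 in anthropogenic
disturbance zones 1…5. Connectivity export from habitat cell *i* to cell
*j* is a negative-exponential kernel of the least-cost distance d_ij:

    k_ij = s_i · exp(−d_ij / (α · d_max))   for d_ij ≤ d_max, else 0

with donor habitat quality s_i ∈ {0.5, 1}, kernel steepness α (default
0.3), and species maximum dispersal distance d_max. The sparse matrix
K = (k_ij) is raised to the g-th power (default g = 3) for connectivity
over g dispersal events, capturing stepping-stone routes. Row sums of K^g
are **exports** (source importance); column sums are **imports**
(recolonization potential). A cell's **vulnerability to isolation** is the
absolute loss of imports when disturbance-derived conductances enter the
graph: `|colsums(A^g) − colsums(B^g)|` for baseline matrix A and disturbed
matrix B.

Protection of each feature (habitat, exports, vulnerable imports; per
species) is assessed in the full and strict (IUCN Ia/Ib/II) MPA networks
against the random-allocation expectation (the network's water-area
fraction). Expansion priorities come from a budgeted **minimum-shortfall**
selection — targets of 100% per feature, unit cost per cell, existing MPAs
locked in — solved by a deterministic nested greedy and re-run at growing
budgets (11%, 12%, … of the study area) to rank cells by the increment
that first selects them.

## Worked example

Two adjacent habitat cells, 250 m apart on a 1 × 5 water strip, quality 1,
d_max = 1 km; the second cell sits in disturbance zone 1:

```r
library(seaconn)
grid    <- seascape_grid(1, 5, 250)
quality <- matrix(0, 1, 5); quality[1, 1:2] <- 1
sp      <- species_profile("perch", habitat_layer(grid, quality), d_max = 1000)

baseline <- build_traversal_graph(grid)
zones    <- matrix(0L, 1, 5); zones[1, 2] <- 1L
disturbed <- build_traversal_graph(grid,
  zones_to_conductance(disturbance_layer(grid, zones)))

d <- least_cost_distances(baseline, habitat_cells(sp$habitat), cutoff = 1000)
K <- build_connectivity_matrix(sp, d)
round(as.matrix(K$K), 5)
#>        [,1]   [,2]
#> [1,] 0.0000 0.4346
#> [2,] 0.4346 0.0000

v <- vulnerability_scores(sp, baseline, disturbed, g = 3)
round(layer_values_at(v, c(0, 1)), 6)
#> [1] 0.046411 0.046411
```

The off-diagonal 0.4346 is `exp(−250/300)`: one 250 m step at α·d_max =
300 m. Zone 1 halves the conductance of the recipient cell, stretching the
effective step to 333 m and the kernel to 0.32919; over three generations
each cell loses `0.4346³ − 0.32919³ ≈ 0.0464` of its imports — its
vulnerability score.

The full workflow runs from one config (here a synthetic 60 × 60
archipelago; `run_pipeline()` writes rasters, CSV tables and a JSON
manifest as a side effect):

```r
res <- run_pipeline(list(scenario = list(seed = 1, n_rows = 60, n_cols = 60)))
res$assessment$summary
#>         feature_kind network mean_protection
#> 1            exports    full         0.01587
#> 2            habitat    full         0.02361
#> 3 vulnerable_imports    full         0.00972
#> 4            exports  strict         0.00664
#> 5            habitat  strict         0.01111
#> 6 vulnerable_imports  strict         0.00936
head(res$ranking$curve, 4)
#>   budget_fraction budget_cells mean_protection
#> 1           0.104          281          0.0164
#> 2           0.110          297          0.0730
#> 3           0.120          324          0.1580
#> 4           0.130          351          0.2348
```

At this seed the MPAs cover 10.4% of the water but protect only 1–2% of
each feature — the generator places MPAs without regard to habitat, a
residual-reservation pattern — and the first two expansion increments
already quadruple mean protection. The curve continues until every feature
is fully protected.

A thin CLI wraps the same functions:

```sh
exec/seaconn simulate --seed 1 --out demo/
exec/seaconn run-all --config demo/config.yml
```

## Package layout

- `R/` — grid/layer types and text-format I/O (ESRI ASCII grids, GeoJSON
  MPAs), synthetic-archipelago generator, traversal graph and least-cost
  distances, connectivity matrices, vulnerability, assessment,
  prioritization, pipeline.
- `exec/seaconn` — CLI subcommands (`simulate`, `run-all`, stage names).
- `vignettes/seaconn-methods.Rmd` — models, assumptions, parameter
  defaults, numerical choices, limitations.
- `tests/testthat/` — unit and property tests with independent oracles
  (Bellman-Ford shortest paths, dense matrix algebra, exhaustive reserve
  selection).
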