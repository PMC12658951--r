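## Habitat vulnerability to connectivity decline and isolation: the loss
## of generational connectivity imports when anthropogenic disturbance is
## added to the traversal graph.

#' Vulnerability of habitat cells to isolation
#'
#' Builds two generational connectivity matrices for a species — Matrix A
#' from the baseline (undisturbed) traversal graph and Matrix B from the
#' graph with disturbance-derived conductances — and returns the absolute
#' difference of their column sums per habitat cell:
#' `|imports_A - imports_B|`. Disturbance only lowers conductance, so it
#' can only lengthen least-cost paths; imports under disturbance never
#' exceed baseline imports and the absolute value equals the plain loss.
#' The result is a relative spatial index, not a demographic rate.
#'
#' Habitat quality is unaffected by disturbance: Matrix B differs from A
#' only through the least-cost path distances. The same generation count
#' is applied to both matrices, and the same `d_max` cutoff: when
#' disturbance pushes a pair's least-cost distance beyond `d_max` the
#' connection is severed entirely.
#'
#' @param species A `species_profile`.
#' @param baseline_graph A `traversal_graph` built with uniform conductance.
#' @param disturbed_graph A `traversal_graph` built from
#'   [zones_to_conductance()], same grid.
#' @param g Generation count (default 3).
#' @return A `feature_layer` of kind `"vulnerable_imports"`.
#' @export
vulnerability_scores <- function(species, baseline_graph, disturbed_graph,
                                 g = 3L) {
  stopifnot(inherits(species, "species_profile"),
            inherits(baseline_graph, "traversal_graph"),
            inherits(disturbed_graph, "traversal_graph"))
  if (!same_geometry(baseline_graph$grid, disturbed_graph$grid))
    stop_geometry_mismatch(baseline_graph$grid, disturbed_graph$grid)
  cells <- habitat_cells(species$habitat)
  dA <- least_cost_distances(baseline_graph, cells, cutoff = species$d_max)
  dB <- least_cost_distances(disturbed_graph, cells, cutoff = species$d_max)
  A <- generational_matrix(build_connectivity_matrix(species, dA), g)
  B <- generational_matrix(build_connectivity_matrix(species, dB,
                                                     disturbed = TRUE), g)
  vulnerability_from_matrices(A, B, species$habitat$grid)
}

#' Vulnerability from precomputed matrices
#'
#' @param A,B Generational `connectivity_matrix` objects (baseline and
#'   disturbed) with identical cell orderings and generation counts.
#' @param grid The shared `seascape_grid`.
#' @return A `feature_layer` of kind `"vulnerable_imports"`.
#' @export
vulnerability_from_matrices <- function(A, B, grid) {
  stopifnot(inherits(A, "connectivity_matrix"),
            inherits(B, "connectivity_matrix"))
  if (!identical(A$cells, B$cells))
    stop("Matrix A and Matrix B index different habitat cells")
  if (A$generations != B$generations)
    stop("Matrix A and Matrix B have different generation counts")
  loss <- abs(imports(A) - imports(B))
  amt <- matrix(0, grid$n_rows, grid$n_cols)
  amt[cell_to_rc(grid, A$cells)] <- loss
  feature_layer(grid, amt, A$species, "vulnerable_imports")
}
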