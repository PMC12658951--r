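## Dispersal kernel, per-species connectivity matrices, multi-generation
## powers, and the per-cell export/import summaries derived from them.

#' Negative-exponential dispersal kernel
#'
#' Connectivity export from habitat cell i to cell j as a function of the
#' least-cost distance between them:
#' `k = s_i * exp(-d / (alpha * d_max))` for `d <= d_max`, and 0 beyond the
#' maximum dispersal distance (a hard cutoff, whatever the reason the path
#' is long). `alpha` sets the steepness of the decay and `s_i` is the
#' donor cell's habitat quality, which scales exports only.
#'
#' @param d Distance(s) in metres along the least-cost path; `Inf` allowed
#'   (unreachable pairs).
#' @param alpha Kernel steepness (positive, dimensionless).
#' @param d_max Maximum dispersal distance in metres (positive).
#' @param s Donor habitat quality in [0, 1] (default 1).
#' @return Kernel value(s) in [0, s].
#' @export
dispersal_kernel <- function(d, alpha, d_max, s = 1) {
  if (any(is.na(d)) || any(d < 0)) stop("distances must be nonnegative")
  stopifnot(alpha > 0, d_max > 0, all(s >= 0), all(s <= 1))
  k <- s * exp(-d / (alpha * d_max))
  k[d > d_max] <- 0
  k
}

#' Per-species connectivity matrix (one generation)
#'
#' Entry (i, j) is the kernel value for the least-cost distance from
#' habitat cell i (donor) to habitat cell j (recipient), scaled by the
#' donor's habitat quality: rows are donors (exports), columns recipients
#' (imports). The diagonal is zero — exports are to *other* habitat cells,
#' so there is no self-connectivity. With uniform habitat quality the
#' matrix is symmetric because the underlying distances are; varying
#' quality scales rows only and breaks the symmetry.
#'
#' @param species A `species_profile`.
#' @param distances A `distance_table` over the species' habitat cells,
#'   computed with `cutoff = species$d_max`.
#' @param disturbed Flag recording whether the distances came from the
#'   disturbance-bearing graph (Matrix B) rather than the baseline
#'   (Matrix A).
#' @return A `connectivity_matrix`: sparse matrix `K` plus the ordered
#'   habitat-cell ids, the species name, the generation count (1), and the
#'   `disturbed` flag.
#' @export
build_connectivity_matrix <- function(species, distances, disturbed = FALSE) {
  stopifnot(inherits(species, "species_profile"),
            inherits(distances, "distance_table"))
  if (!isTRUE(all.equal(distances$cutoff, species$d_max)))
    stop("distance table cutoff (", distances$cutoff,
         ") does not match the species d_max (", species$d_max, ")")
  cells <- distances$cells
  s <- layer_values_at(species$habitat, cells)
  if (any(s <= 0)) stop("distance table contains non-habitat cells")
  n <- length(cells)
  ij <- which(is.finite(distances$dist), arr.ind = TRUE)
  ij <- ij[ij[, 1] != ij[, 2], , drop = FALSE] # zero diagonal
  k <- dispersal_kernel(distances$dist[ij], species$alpha, species$d_max,
                        s = s[ij[, 1]])
  K <- Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2], x = k, dims = c(n, n))
  new_connectivity_matrix(K, cells, species$name, 1L, disturbed)
}

new_connectivity_matrix <- function(K, cells, species, generations, disturbed) {
  structure(list(K = K, cells = as.integer(cells), species = species,
                 generations = as.integer(generations),
                 disturbed = isTRUE(disturbed)),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s: %d habitat cells, %d links, g = %d%s\n",
              x$species, length(x$cells), Matrix::nnzero(x$K), x$generations,
              if (x$disturbed) ", disturbed" else ""))
  invisible(x)
}

#' Connectivity over multiple generations
#'
#' Raises a one-generation connectivity matrix to the g-th matrix power,
#' giving connectivity accumulated over g successive dispersal events.
#' This captures stepping-stone habitats: cells beyond each other's
#' maximum dispersal distance acquire positive connectivity at g > 1 when
#' an intermediate habitat links them. g = 3 is the headline setting for
#' short-term demographic connectivity; g = 1 and 2 are also useful.
#'
#' @param K A `connectivity_matrix` with `generations == 1`.
#' @param g Number of generations (integer >= 1).
#' @return A `connectivity_matrix` with the same cells and `generations = g`.
#' @export
generational_matrix <- function(K, g) {
  stopifnot(inherits(K, "connectivity_matrix"))
  if (K$generations != 1L) stop("generational_matrix expects a g = 1 matrix")
  g <- as.integer(g)
  if (is.na(g) || g < 1L) stop("g must be an integer >= 1")
  Kg <- K$K
  if (g > 1L) for (i in seq_len(g - 1L)) Kg <- Kg %*% K$K
  new_connectivity_matrix(Kg, K$cells, K$species, g, K$disturbed)
}

#' Connectivity exports per habitat cell
#'
#' Row sums of the generational connectivity matrix: the kernel-weighted
#' outflow from each habitat cell to all reachable habitat cells, a proxy
#' for a source habitat's contribution to metapopulation recruitment.
#'
#' @param Kg A `connectivity_matrix` (any generation count).
#' @param grid The shared `seascape_grid` (for the output layer).
#' @return A `feature_layer` of kind `"exports"`.
#' @export
exports <- function(Kg, grid) {
  stopifnot(inherits(Kg, "connectivity_matrix"))
  amt <- matrix(0, grid$n_rows, grid$n_cols)
  amt[cell_to_rc(grid, Kg$cells)] <- Matrix::rowSums(Kg$K)
  feature_layer(grid, amt, Kg$species, "exports")
}

#' Connectivity imports per habitat cell
#'
#' Column sums of the generational connectivity matrix: the kernel-weighted
#' inflow each habitat cell receives, a proxy for external recruitment and
#' recolonization potential.
#'
#' @param Kg A `connectivity_matrix`.
#' @return Named numeric vector of imports, one per habitat cell, in the
#'   matrix's cell order (names are 0-based cell ids).
#' @export
imports <- function(Kg) {
  stopifnot(inherits(Kg, "connectivity_matrix"))
  stats::setNames(Matrix::colSums(Kg$K), Kg$cells)
}

#' Habitat amounts as a feature layer
#'
#' The habitat-quality map itself, used as the third biodiversity feature
#' (habitats matter ecologically regardless of their connectivity role).
#'
#' @param species A `species_profile`.
#' @return A `feature_layer` of kind `"habitat"`.
#' @export
habitat_feature <- function(species) {
  stopifnot(inherits(species, "species_profile"))
  feature_layer(species$habitat$grid, species$habitat$values,
                species$name, "habitat")
}
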