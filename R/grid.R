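#' Seascape grid geometry
#'
#' A `seascape_grid` holds the raster geometry shared by every layer in an
#' analysis: number of rows and columns, cell edge length in metres, the
#' planar coordinate of the grid's upper-left corner, and a land/water mask.
#' All coordinates are planar metres (a projected CRS is assumed); the
#' methods only ever use relative distances, so no geodesic corrections are
#' applied.
#'
#' Cells are indexed row-major and 0-based: cell id `r * n_cols + c` for row
#' `r` and column `c` (both 0-based, row 0 at the top). The centre of cell
#' `(r, c)` lies at `origin + ((c + 0.5) * resolution, -(r + 0.5) * resolution)`.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param resolution Cell edge length in metres (positive).
#' @param origin Numeric length-2: x and y of the upper-left corner.
#' @param water Logical matrix `n_rows x n_cols`, `TRUE` for water cells.
#'   Defaults to all-water.
#' @return An object of class `seascape_grid`.
#' @export
seascape_grid <- function(n_rows, n_cols, resolution, origin = c(0, 0),
                          water = NULL) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) stop("grid must have at least one row and column")
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    stop("resolution must be a single positive number (metres)")
  if (length(origin) != 2L || !is.numeric(origin))
    stop("origin must be a numeric (x, y) pair")
  if (is.null(water)) water <- matrix(TRUE, n_rows, n_cols)
  if (!is.logical(water) || !identical(dim(water), c(n_rows, n_cols)))
    stop("water mask must be a logical ", n_rows, " x ", n_cols, " matrix")
  structure(
    list(n_rows = n_rows, n_cols = n_cols,
         resolution = as.numeric(resolution),
         origin = as.numeric(origin), water = water),
    class = "seascape_grid")
}

#' @export
print.seascape_grid <- function(x, ...) {
  cat(sprintf("<seascape_grid> %d x %d @ %g m, origin (%g, %g), %d water / %d cells\n",
              x$n_rows, x$n_cols, x$resolution, x$origin[1], x$origin[2],
              sum(x$water), x$n_rows * x$n_cols))
  invisible(x)
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

#' Convert between cell ids and row/column indices
#'
#' Cell ids are 0-based row-major; `rc` is 1-based (R matrix convention).
#'
#' @param grid A `seascape_grid`.
#' @param cell Integer vector of 0-based cell ids.
#' @return `cell_to_rc`: a two-column matrix of 1-based (row, col);
#'   `rc_to_cell`: an integer vector of 0-based cell ids.
#' @export
cell_to_rc <- function(grid, cell) {
  cell <- as.integer(cell)
  if (any(cell < 0L | cell >= n_cells(grid))) stop("cell id out of range")
  cbind(row = cell %/% grid$n_cols + 1L, col = cell %% grid$n_cols + 1L)
}

#' @rdname cell_to_rc
#' @param row,col 1-based row and column indices.
#' @export
rc_to_cell <- function(grid, row, col) {
  if (any(row < 1L | row > grid$n_rows | col < 1L | col > grid$n_cols))
    stop("row/col out of range")
  as.integer((row - 1L) * grid$n_cols + (col - 1L))
}

#' Planar coordinates of cell centres
#'
#' @inheritParams cell_to_rc
#' @return Two-column matrix of x, y centre coordinates in metres.
#' @export
cell_xy <- function(grid, cell) {
  rc <- cell_to_rc(grid, cell)
  cbind(x = grid$origin[1] + (rc[, "col"] - 0.5) * grid$resolution,
        y = grid$origin[2] - (rc[, "row"] - 0.5) * grid$resolution)
}

same_geometry <- function(a, b) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    isTRUE(all.equal(a$resolution, b$resolution)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

describe_geometry <- function(g) {
  sprintf("%dx%d @ %g m, origin (%g, %g)", g$n_rows, g$n_cols, g$resolution,
          g$origin[1], g$origin[2])
}

stop_geometry_mismatch <- function(a, b) {
  stop("raster geometry mismatch: ", describe_geometry(a), " vs ",
       describe_geometry(b), call. = FALSE)
}

## ---- layers -------------------------------------------------------------

new_layer <- function(grid, values, class) {
  if (!identical(dim(values), c(grid$n_rows, grid$n_cols)))
    stop("layer dimensions do not match the grid")
  structure(list(grid = grid, values = values),
            class = c(class, "seascape_layer"))
}

#' Three-class habitat-quality layer
#'
#' Habitat suitability per cell with the three permitted quality classes
#' 0.0 (absent), 0.5 (good), and 1.0 (very good). Positive quality is only
#' allowed on water cells. The kernel itself accepts any quality in [0, 1];
#' the three-class restriction reflects the classified habitat maps the
#' method takes as input and can be relaxed with `strict = FALSE`.
#'
#' @param grid A `seascape_grid`.
#' @param quality Numeric matrix of per-cell habitat quality.
#' @param strict Enforce the three-class value set (default `TRUE`).
#' @return A `habitat_layer`.
#' @export
habitat_layer <- function(grid, quality, strict = TRUE) {
  quality <- as_matrix_on(grid, quality)
  if (strict) {
    bad <- setdiff(unique(as.vector(quality)), c(0, 0.5, 1))
    if (length(bad))
      stop("illegal habitat quality values: ",
           paste(utils::head(bad, 10), collapse = ", "),
           " (permitted: 0, 0.5, 1)", call. = FALSE)
  } else if (any(quality < 0 | quality > 1)) {
    stop("habitat quality must lie in [0, 1]")
  }
  if (any(quality > 0 & !grid$water))
    stop("positive habitat quality on land cells")
  new_layer(grid, quality, "habitat_layer")
}

#' Anthropogenic disturbance-zone layer
#'
#' Integer disturbance zones 0-5 per cell; 0 means no disturbance and 5 the
#' strongest obstruction of movement. Zones feed the conductance mapping of
#' [zones_to_conductance()].
#'
#' @param grid A `seascape_grid`.
#' @param zone Integer matrix of zones in 0..5.
#' @return A `disturbance_layer`.
#' @export
disturbance_layer <- function(grid, zone) {
  zone <- as_matrix_on(grid, zone)
  bad <- setdiff(unique(as.vector(zone)), 0:5)
  if (length(bad))
    stop("illegal disturbance zone values: ",
         paste(utils::head(bad, 10), collapse = ", "),
         " (permitted: integers 0-5)", call. = FALSE)
  storage.mode(zone) <- "integer"
  new_layer(grid, zone, "disturbance_layer")
}

#' Protection-status constants
#'
#' Cell protection status is coded 0 = unprotected, 1 = protected in a
#' non-strict MPA, 2 = protected in a strict MPA (IUCN category Ia, Ib or II).
#' @export
MPA_UNPROTECTED <- 0L
#' @rdname MPA_UNPROTECTED
#' @export
MPA_NONSTRICT <- 1L
#' @rdname MPA_UNPROTECTED
#' @export
MPA_STRICT <- 2L

#' Per-cell MPA protection status layer
#'
#' @param grid A `seascape_grid`.
#' @param status Integer matrix with values in `{0, 1, 2}` (see
#'   [MPA_UNPROTECTED]).
#' @return An `mpa_status_layer`.
#' @export
mpa_status_layer <- function(grid, status) {
  status <- as_matrix_on(grid, status)
  bad <- setdiff(unique(as.vector(status)), 0:2)
  if (length(bad))
    stop("illegal MPA status values: ", paste(bad, collapse = ", "))
  storage.mode(status) <- "integer"
  new_layer(grid, status, "mpa_status_layer")
}

#' Per-cell biodiversity feature layer
#'
#' Nonnegative amount of one biodiversity feature (habitat quality,
#' connectivity exports, or vulnerable connectivity imports) for one
#' species. Amounts are zero outside habitat cells.
#'
#' @param grid A `seascape_grid`.
#' @param amount Nonnegative numeric matrix.
#' @param species Species identifier.
#' @param kind One of `"habitat"`, `"exports"`, `"vulnerable_imports"`.
#' @return A `feature_layer`.
#' @export
feature_layer <- function(grid, amount, species,
                          kind = c("habitat", "exports", "vulnerable_imports")) {
  kind <- match.arg(kind)
  amount <- as_matrix_on(grid, amount)
  if (any(amount < 0)) stop("feature amounts must be nonnegative")
  l <- new_layer(grid, amount, "feature_layer")
  l$species <- as.character(species)
  l$kind <- kind
  l
}

as_matrix_on <- function(grid, values) {
  if (is.null(dim(values)) && length(values) == n_cells(grid))
    values <- matrix(values, grid$n_rows, grid$n_cols, byrow = TRUE)
  if (!is.matrix(values) || !identical(dim(values), c(grid$n_rows, grid$n_cols)))
    stop("values must be an ", grid$n_rows, " x ", grid$n_cols,
         " matrix (or a row-major vector of that length)")
  values
}

#' Species dispersal profile
#'
#' Bundles a species' habitat layer with its dispersal parameters: the
#' maximum dispersal distance `d_max` (metres) beyond which connectivity is
#' zero, and the dimensionless kernel steepness `alpha`. The default
#' `alpha = 0.3` gives a moderately steep negative-exponential decline
#' (the kernel falls to exp(-1/0.3), about 0.036, at `d_max`), consistent
#' with mark-recapture evidence that coastal fish mostly move short
#' distances but occasionally travel far.
#'
#' @param name Species identifier.
#' @param habitat A `habitat_layer`.
#' @param d_max Maximum dispersal distance in metres (positive).
#' @param alpha Kernel steepness (positive, default 0.3).
#' @return A `species_profile`.
#' @export
species_profile <- function(name, habitat, d_max, alpha = 0.3) {
  stopifnot(inherits(habitat, "habitat_layer"))
  if (!is.numeric(d_max) || length(d_max) != 1L || d_max <= 0)
    stop("d_max must be a single positive distance in metres")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("alpha must be a single positive number")
  structure(list(name = as.character(name), habitat = habitat,
                 d_max = as.numeric(d_max), alpha = as.numeric(alpha)),
            class = "species_profile")
}

#' @export
print.species_profile <- function(x, ...) {
  cat(sprintf("<species_profile> %s: %d habitat cells, d_max = %g m, alpha = %g\n",
              x$name, length(habitat_cells(x$habitat)), x$d_max, x$alpha))
  invisible(x)
}

#' Cell ids of positive-quality habitat cells
#'
#' @param habitat A `habitat_layer`.
#' @return Sorted integer vector of 0-based cell ids with quality > 0.
#' @export
habitat_cells <- function(habitat) {
  idx <- which(t(habitat$values) > 0) # t(): row-major order
  sort(as.integer(idx - 1L))
}

#' Extract per-cell values for a set of cell ids
#' @param layer A seascape layer.
#' @param cells 0-based cell ids.
#' @return Numeric vector of the layer's values at those cells.
#' @export
layer_values_at <- function(layer, cells) {
  rc <- cell_to_rc(layer$grid, cells)
  layer$values[rc]
}
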