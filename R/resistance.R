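## Water-traversal graph and least-cost distances. Land is an obstacle and
## cannot be travelled through; anthropogenic disturbance lowers the
## conductance of water cells, lengthening least-cost paths.

#' Default disturbance-zone to conductance mapping
#'
#' Zones 1-5 correspond to assumed probabilities of successful passage of
#' 50%, 40%, 30%, 20% and 10%, expressed as conductances (the inverse of
#' cost); zone 0 (no disturbance) is unimpeded water. These are relative
#' values, not real-world probabilities.
#' @export
DEFAULT_ZONE_CONDUCTANCE <- c(`0` = 1.0, `1` = 0.5, `2` = 0.4, `3` = 0.3,
                              `4` = 0.2, `5` = 0.1)

#' Convert disturbance zones to a conductance field
#'
#' @param zones A `disturbance_layer`.
#' @param mapping Named numeric vector giving the conductance for zones
#'   0-5; defaults to [DEFAULT_ZONE_CONDUCTANCE].
#' @return A `conductance_field`: matrix of conductances in (0, 1] on
#'   water cells, `NA` on land.
#' @export
zones_to_conductance <- function(zones, mapping = DEFAULT_ZONE_CONDUCTANCE) {
  stopifnot(inherits(zones, "disturbance_layer"))
  if (!all(as.character(0:5) %in% names(mapping)))
    stop("conductance mapping must name zones 0-5")
  if (any(mapping <= 0 | mapping > 1)) stop("conductances must lie in (0, 1]")
  cond <- matrix(mapping[as.character(zones$values)],
                 zones$grid$n_rows, zones$grid$n_cols)
  cond[!zones$grid$water] <- NA_real_
  structure(list(grid = zones$grid, conductance = cond),
            class = "conductance_field")
}

#' Uniform (undisturbed) conductance field
#'
#' The baseline traversal medium: conductance 1 on every water cell.
#'
#' @param grid A `seascape_grid`.
#' @return A `conductance_field`.
#' @export
uniform_conductance <- function(grid) {
  cond <- matrix(1, grid$n_rows, grid$n_cols)
  cond[!grid$water] <- NA_real_
  structure(list(grid = grid, conductance = cond),
            class = "conductance_field")
}

#' Build the water-traversal graph
#'
#' Nodes are water cells; edges join 8-neighbouring water cells. The cost
#' of a step between cells u and v is `step_length / mean(c_u, c_v)` where
#' `step_length` is the resolution for orthogonal moves and
#' `resolution * sqrt(2)` for diagonal moves. A diagonal edge is omitted
#' when both orthogonal cells flanking the shared corner are land, so a
#' disperser can never slip through the meeting point of two land cells.
#'
#' @param grid A `seascape_grid`.
#' @param conductance A `conductance_field` on the same grid; defaults to
#'   the uniform baseline.
#' @return A `traversal_graph`: list with the `igraph` object, the 0-based
#'   cell ids of its nodes (`cells`), and the grid.
#' @export
build_traversal_graph <- function(grid, conductance = uniform_conductance(grid)) {
  stopifnot(inherits(conductance, "conductance_field"))
  if (!same_geometry(grid, conductance$grid))
    stop_geometry_mismatch(grid, conductance$grid)
  nr <- grid$n_rows; nc <- grid$n_cols
  water <- grid$water
  cond <- conductance$conductance
  if (any(!is.na(cond) & water & (cond <= 0)))
    stop("conductance must be positive on water cells")
  node_of <- matrix(NA_integer_, nr, nc)
  wc <- which(water)
  node_of[wc] <- seq_along(wc)

  edges <- list(); k <- 0L
  add_edges <- function(r1, c1, r2, c2, step, extra_ok = NULL) {
    ok <- water[cbind(r1, c1)] & water[cbind(r2, c2)]
    if (!is.null(extra_ok)) ok <- ok & extra_ok
    if (!any(ok)) return(invisible())
    r1 <- r1[ok]; c1 <- c1[ok]; r2 <- r2[ok]; c2 <- c2[ok]
    w <- step / ((cond[cbind(r1, c1)] + cond[cbind(r2, c2)]) / 2)
    k <<- k + 1L
    edges[[k]] <<- cbind(node_of[cbind(r1, c1)], node_of[cbind(r2, c2)], w)
    invisible()
  }
  res <- grid$resolution
  if (nc > 1L) { # east
    g <- expand.grid(r = seq_len(nr), c = seq_len(nc - 1L))
    add_edges(g$r, g$c, g$r, g$c + 1L, res)
  }
  if (nr > 1L) { # south
    g <- expand.grid(r = seq_len(nr - 1L), c = seq_len(nc))
    add_edges(g$r, g$c, g$r + 1L, g$c, res)
  }
  if (nr > 1L && nc > 1L) {
    g <- expand.grid(r = seq_len(nr - 1L), c = seq_len(nc - 1L))
    # south-east diagonal; flanking cells are (r, c+1) and (r+1, c)
    flank_ok <- water[cbind(g$r, g$c + 1L)] | water[cbind(g$r + 1L, g$c)]
    add_edges(g$r, g$c, g$r + 1L, g$c + 1L, res * sqrt(2), flank_ok)
    # south-west diagonal from (r, c+1) to (r+1, c); same flanking cells
    flank_ok <- water[cbind(g$r, g$c)] | water[cbind(g$r + 1L, g$c + 1L)]
    add_edges(g$r, g$c + 1L, g$r + 1L, g$c, res * sqrt(2), flank_ok)
  }
  em <- if (k) do.call(rbind, edges) else matrix(numeric(0), 0, 3)
  g <- igraph::make_empty_graph(n = length(wc), directed = FALSE)
  if (nrow(em))
    g <- igraph::add_edges(g, t(em[, 1:2]), weight = em[, 3])
  rc <- arrayInd(wc, c(nr, nc))
  structure(list(graph = g,
                 cells = rc_to_cell(grid, rc[, 1], rc[, 2]),
                 grid = grid),
            class = "traversal_graph")
}

#' @export
print.traversal_graph <- function(x, ...) {
  cat(sprintf("<traversal_graph> %d water nodes, %d edges\n",
              length(x$cells), igraph::ecount(x$graph)))
  invisible(x)
}

#' Least-cost distances between habitat cells
#'
#' Exact Dijkstra shortest-path distances through the water graph between
#' all pairs of source cells, truncated at `cutoff` (a species' maximum
#' dispersal distance). Pairs farther apart than the cutoff, and pairs
#' separated by land, are unreachable and stored as `Inf`; the dispersal
#' kernel treats both as zero connectivity.
#'
#' @param graph A `traversal_graph`.
#' @param sources Integer vector of 0-based cell ids (must be water cells).
#' @param cutoff Maximum distance in metres to retain (`d_max`).
#' @return A `distance_table`: list with `cells` (the sources, in input
#'   order), `dist` (matrix, metres, `Inf` beyond cutoff or unreachable),
#'   and `cutoff`.
#' @export
least_cost_distances <- function(graph, sources, cutoff = Inf) {
  stopifnot(inherits(graph, "traversal_graph"))
  idx <- match(sources, graph$cells)
  if (anyNA(idx))
    stop("source cells on land (not in the traversal graph): ",
         paste(utils::head(sources[is.na(idx)], 10), collapse = ", "))
  d <- igraph::distances(graph$graph, v = idx, to = idx,
                         algorithm = "dijkstra")
  dimnames(d) <- NULL
  d[d > cutoff] <- Inf
  structure(list(cells = as.integer(sources), dist = d,
                 cutoff = as.numeric(cutoff)),
            class = "distance_table")
}

#' @export
print.distance_table <- function(x, ...) {
  n <- length(x$cells)
  cat(sprintf("<distance_table> %d cells, %d finite pairs, cutoff %g m\n",
              n, sum(is.finite(x$dist)) - n, x$cutoff))
  invisible(x)
}
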