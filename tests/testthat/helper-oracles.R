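# Independent oracles used to validate the implementation. These are
# deliberately written from the stated rules with naive algorithms
# (Bellman-Ford relaxation, dense matrix algebra, exhaustive search) and
# share no code with the package internals they check.

# Edge list of the water-traversal graph, built directly from the rules:
# 8-neighbour water cells, cost = step / mean conductance, diagonals
# blocked when both flanking orthogonal cells are land. Returns both
# directions of every edge. Nodes are 1-based column-major indices into
# the water matrix (all cells, land nodes simply have no edges).
oracle_edges <- function(water, cond, res) {
  nr <- nrow(water); nc <- ncol(water)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  id <- function(r, c) (c - 1L) * nr + r
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!water[r, c]) next
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (!water[r2, c2]) next
      if (dr != 0 && dc != 0) {
        if (!water[r, c2] && !water[r2, c]) next # corner blocked
        step <- res * sqrt(2)
      } else step <- res
      from <- c(from, id(r, c)); to <- c(to, id(r2, c2))
      w <- c(w, step / ((cond[r, c] + cond[r2, c2]) / 2))
    }
  }
  list(from = from, to = to, w = w)
}

# Single-source shortest distances by Bellman-Ford relaxation sweeps.
oracle_sssp <- function(edges, n, src) {
  d <- rep(Inf, n)
  d[src] <- 0
  repeat {
    cand <- d[edges$from] + edges$w
    best <- tapply(cand, edges$to, min)
    nd <- d
    idx <- as.integer(names(best))
    nd[idx] <- pmin(nd[idx], best)
    if (identical(nd, d)) break
    d <- nd
  }
  d
}

# Random water/conductance field for oracle comparisons.
random_field <- function(nr, nc, p_land = 0.3, disturb = TRUE) {
  water <- matrix(stats::runif(nr * nc) > p_land, nr, nc)
  if (!any(water)) water[1] <- TRUE
  cond <- matrix(1, nr, nc)
  if (disturb) {
    zones <- matrix(sample(0:5, nr * nc, replace = TRUE,
                           prob = c(0.6, 0.1, 0.1, 0.08, 0.07, 0.05)), nr, nc)
    cond <- matrix(c(1, 0.5, 0.4, 0.3, 0.2, 0.1)[zones + 1L], nr, nc)
  }
  cond[!water] <- NA
  list(water = water, cond = cond)
}

# Exhaustive minimum-shortfall optimum: best objective over all
# selections of exactly `budget` non-locked cells (plus the locked set).
oracle_best_shortfall <- function(amounts, targets, budget, locked = integer(0)) {
  n <- nrow(amounts)
  free <- setdiff(seq_len(n), locked)
  held0 <- if (length(locked)) colSums(amounts[locked, , drop = FALSE])
           else numeric(ncol(amounts))
  k <- budget - length(locked)
  if (k <= 0) return(sum(pmax(0, targets - held0) / targets))
  combos <- utils::combn(free, min(k, length(free)))
  best <- Inf
  for (j in seq_len(ncol(combos))) {
    held <- held0 + colSums(amounts[combos[, j], , drop = FALSE])
    best <- min(best, sum(pmax(0, targets - held) / targets))
  }
  best
}

# Tiny deterministic seascape used across tests: a strip grid with
# habitat at chosen cells.
strip_species <- function(n_cells_strip, habitat_at, d_max, res = 250,
                          quality = NULL, alpha = 0.3) {
  grid <- seascape_grid(1, n_cells_strip, res)
  q <- matrix(0, 1, n_cells_strip)
  if (is.null(quality)) quality <- rep(1, length(habitat_at))
  q[1, habitat_at + 1L] <- quality
  species_profile("strip", habitat_layer(grid, q), d_max = d_max,
                  alpha = alpha)
}

# Square polygon (counter-clockwise ring) from x/y bounds.
square_ring <- function(x0, y0, x1, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}
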