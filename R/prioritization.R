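## Budgeted minimum-shortfall reserve selection and incremental priority
## ranking for MPA-network expansion. Planning units are water cells with
## homogeneous cost 1; targets are 100% of every feature's total amount;
## existing MPAs are locked in and consume budget. The selection heuristic
## is a deterministic greedy: it repeatedly adds the cell with the largest
## marginal decrease in shortfall, which makes growing-budget solutions
## nested by construction.

#' Define a reserve-selection planning problem
#'
#' @param features List of `feature_layer` objects, each with positive
#'   total amount (3 kinds x n species in the full workflow).
#' @param locked_in Integer vector of 0-based cell ids forced into every
#'   solution (existing MPAs); must be water cells.
#' @return A `planning_problem`: planning units (all water cells, 0-based
#'   ids, ascending), sparse amount matrix `A` (units x features), targets
#'   (feature totals), unit cost 1, and the locked-in set.
#' @export
planning_problem <- function(features, locked_in = integer(0)) {
  stopifnot(length(features) >= 1L)
  grid <- features[[1L]]$grid
  units <- sort(which(t(grid$water)) - 1L) # 0-based row-major ids of water cells
  locked_in <- sort(unique(as.integer(locked_in)))
  if (!all(locked_in %in% units))
    stop("locked-in cells must be water planning units")
  cols <- lapply(features, function(f) {
    if (!same_geometry(f$grid, grid)) stop_geometry_mismatch(f$grid, grid)
    layer_values_at(f, units)
  })
  A <- Matrix::Matrix(do.call(cbind, cols), sparse = TRUE)
  A <- methods::as(methods::as(A, "generalMatrix"), "CsparseMatrix")
  targets <- Matrix::colSums(A)
  zero <- which(targets <= 0)
  if (length(zero))
    stop("feature(s) with zero total amount: ",
         paste(vapply(features[zero], function(f)
           paste0(f$species, "/", f$kind), ""), collapse = ", "))
  colnames(A) <- vapply(features, function(f) paste0(f$species, ":", f$kind), "")
  structure(list(units = units, A = A, targets = targets,
                 locked_in = locked_in, grid = grid),
            class = "planning_problem")
}

#' @export
print.planning_problem <- function(x, ...) {
  cat(sprintf("<planning_problem> %d planning units, %d features, %d locked in\n",
              length(x$units), ncol(x$A), length(x$locked_in)))
  invisible(x)
}

#' Minimum-shortfall objective
#'
#' `sum_f max(0, target_f - held_f) / target_f` over all features, where
#' `held_f` is the feature amount inside the selection. Lower is better;
#' 0 means every feature is fully protected.
#'
#' @param selection Integer vector of selected 0-based cell ids (must
#'   include the locked-in set).
#' @param problem A `planning_problem`.
#' @return Nonnegative score.
#' @export
shortfall_objective <- function(selection, problem) {
  stopifnot(inherits(problem, "planning_problem"))
  selection <- unique(as.integer(selection))
  if (!all(problem$locked_in %in% selection))
    stop("selection must contain every locked-in cell")
  idx <- match(selection, problem$units)
  if (anyNA(idx)) stop("selection contains cells outside the planning units")
  held <- Matrix::colSums(problem$A[idx, , drop = FALSE])
  sum(pmax(0, problem$targets - held) / problem$targets)
}

## Greedy order of additions after the locked-in set. Marginal gains are
## maintained incrementally; a feature's per-cell contributions only need
## recomputing once its remaining shortfall drops below the largest single
## amount (before that the objective is modular in the selection).
greedy_fill <- function(problem, tol = 1e-12) {
  A <- problem$A
  n <- nrow(A); m <- ncol(A)
  Tf <- problem$targets
  Ar <- methods::as(A, "RsparseMatrix")
  col_rows <- function(j) { # 1-based unit rows and amounts of column j
    k <- (A@p[j] + 1L):A@p[j + 1L]
    if (A@p[j] == A@p[j + 1L]) return(NULL)
    list(rows = A@i[k] + 1L, x = A@x[k])
  }
  max_amount <- vapply(seq_len(m), function(j) {
    cr <- col_rows(j); if (is.null(cr)) 0 else max(cr$x)
  }, 0)

  locked_idx <- match(problem$locked_in, problem$units)
  held <- if (length(locked_idx))
    Matrix::colSums(A[locked_idx, , drop = FALSE]) else numeric(m)
  R <- pmax(0, Tf - held)
  shortfall <- sum(R / Tf)

  gain <- numeric(n)
  for (j in seq_len(m)) {
    cr <- col_rows(j)
    if (!is.null(cr))
      gain[cr$rows] <- gain[cr$rows] + pmin(cr$x, R[j]) / Tf[j]
  }
  gain[locked_idx] <- -Inf

  order <- integer(n); sf_after <- numeric(n); taken <- 0L
  while (shortfall > tol) {
    i <- which.max(gain) # first max = lowest cell index on ties
    if (gain[i] <= 0) break
    taken <- taken + 1L
    order[taken] <- i
    gain[i] <- -Inf
    k <- (Ar@p[i] + 1L):Ar@p[i + 1L]
    if (Ar@p[i] < Ar@p[i + 1L]) {
      for (kk in k) {
        j <- Ar@j[kk] + 1L
        a <- Ar@x[kk]
        R_old <- R[j]
        if (R_old <= 0) next
        R_new <- max(0, R_old - a)
        R[j] <- R_new
        shortfall <- shortfall - (R_old - R_new) / Tf[j]
        if (R_old < max_amount[j] || R_new < max_amount[j]) {
          cr <- col_rows(j)
          delta <- (pmin(cr$x, R_new) - pmin(cr$x, R_old)) / Tf[j]
          gain[cr$rows] <- gain[cr$rows] + delta
        }
      }
    }
    sf_after[taken] <- max(shortfall, 0)
  }
  list(order_idx = order[seq_len(taken)],
       order_cells = problem$units[order[seq_len(taken)]],
       shortfall_after = sf_after[seq_len(taken)],
       shortfall_start = sum(pmax(0, Tf - held) / Tf))
}

#' Greedy minimum-shortfall selection under a budget
#'
#' Starts from the locked-in set and repeatedly adds the planning unit
#' with the largest marginal decrease in [shortfall_objective()] per unit
#' cost (cost is 1 everywhere) until the budget is exhausted or the
#' shortfall reaches zero. Ties are broken by cell index, so the result is
#' deterministic, and solutions at growing budgets are nested.
#'
#' @param problem A `planning_problem`.
#' @param budget Total number of cells that may be selected, including the
#'   locked-in cells.
#' @return Integer vector of selected 0-based cell ids (locked-in first,
#'   then greedy additions in selection order).
#' @export
solve_min_shortfall <- function(problem, budget) {
  stopifnot(inherits(problem, "planning_problem"))
  budget <- as.integer(budget)
  n_locked <- length(problem$locked_in)
  if (budget < n_locked)
    stop("budget (", budget, ") is smaller than the locked-in set (",
         n_locked, " cells)")
  fill <- greedy_fill(problem)
  n_add <- min(budget - n_locked, length(fill$order_cells))
  c(problem$locked_in, fill$order_cells[seq_len(n_add)])
}

round_half_up <- function(x) floor(x + 0.5)

#' Incremental priority ranking for network expansion
#'
#' Re-solves the minimum-shortfall problem at budgets growing from
#' `start_fraction` of the planning units in steps of `step`, until every
#' feature is fully protected. Because the greedy solutions are nested,
#' each cell is ranked by the first increment in which it enters the
#' solution (rank 1 = selected at the starting budget). Locked-in cells
#' are part of every solution and carry no rank. Also returns the mean
#' protected fraction across all features after each increment, including
#' the locked-in-only baseline point.
#'
#' @param problem A `planning_problem`.
#' @param start_fraction First budget as a fraction of planning units
#'   (default 0.11).
#' @param step Budget increment per iteration (default 0.01).
#' @param max_increments Safety cap on the number of increments.
#' @return A `priority_ranking`: `rank` (integer vector over planning
#'   units, `NA` for locked-in or never-selected cells), `curve`
#'   (data.frame: budget_fraction, budget_cells, mean_protection),
#'   `budgets`, `order_cells`, `locked_in`, and the problem's grid.
#' @export
incremental_ranking <- function(problem, start_fraction = 0.11, step = 0.01,
                                max_increments = 1000L) {
  stopifnot(inherits(problem, "planning_problem"))
  n <- length(problem$units)
  n_locked <- length(problem$locked_in)
  b1 <- round_half_up(n * start_fraction)
  if (b1 < n_locked)
    stop("starting budget (", b1, " cells) is smaller than the locked-in set")
  fill <- greedy_fill(problem)
  n_total <- n_locked + length(fill$order_cells) # selection achieving zero shortfall

  mean_prot <- function(k_add) { # mean held fraction after k_add greedy additions
    sel_idx <- match(c(problem$locked_in, fill$order_cells[seq_len(k_add)]),
                     problem$units)
    held <- Matrix::colSums(problem$A[sel_idx, , drop = FALSE])
    mean(pmin(1, held / problem$targets))
  }

  budgets <- integer(0); fractions <- numeric(0)
  r <- 0L
  repeat {
    r <- r + 1L
    if (r > max_increments) break
    frac <- start_fraction + (r - 1L) * step
    b <- min(round_half_up(n * frac), n)
    budgets <- c(budgets, b)
    fractions <- c(fractions, frac)
    if (b >= n_total || b >= n) break
  }

  rank <- rep(NA_integer_, n)
  for (r in rev(seq_along(budgets))) {
    n_add <- min(budgets[r] - n_locked, length(fill$order_cells))
    if (n_add > 0)
      rank[match(fill$order_cells[seq_len(n_add)], problem$units)] <- r
  }

  curve <- data.frame(
    budget_fraction = c(n_locked / n, fractions),
    budget_cells = c(n_locked, budgets),
    mean_protection = c(mean_prot(0L), vapply(budgets, function(b)
      mean_prot(min(b - n_locked, length(fill$order_cells))), 0)))

  structure(list(rank = rank, curve = curve, budgets = budgets,
                 fractions = fractions, order_cells = fill$order_cells,
                 shortfall_after = fill$shortfall_after,
                 locked_in = problem$locked_in, units = problem$units,
                 grid = problem$grid),
            class = "priority_ranking")
}

#' @export
print.priority_ranking <- function(x, ...) {
  cat(sprintf("<priority_ranking> %d increments, %d ranked cells, %d locked in\n",
              length(x$budgets), sum(!is.na(x$rank)), length(x$locked_in)))
  invisible(x)
}

#' Priority ranking as a raster matrix
#'
#' 0 = locked-in or no score, 1..R = rank (1 highest priority); land is NA.
#'
#' @param ranking A `priority_ranking`.
#' @return Numeric matrix on the ranking's grid.
#' @export
ranking_raster <- function(ranking) {
  grid <- ranking$grid
  out <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  out[cell_to_rc(grid, ranking$units)] <- 0
  ranked <- !is.na(ranking$rank)
  out[cell_to_rc(grid, ranking$units[ranked])] <- ranking$rank[ranked]
  out[cell_to_rc(grid, ranking$locked_in)] <- 0
  out
}
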