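## Seeded generator of synthetic archipelago scenarios: clumped land,
## spatially autocorrelated three-class habitat biased toward the shore,
## disturbance concentrated near coasts, and overlapping MPA polygons of
## mixed IUCN categories. Every layer is a pure function of (seed,
## parameters), so the whole workflow is testable without external data.

#' Synthetic seascape scenario parameters
#'
#' Defaults define the package's standard test seascape: a 100 x 100 grid
#' at 250 m resolution with a quarter of the area as land, four species
#' with maximum dispersal distances between 1 and 10 km, MPAs covering
#' 10.5% of the water with 27% of that area strictly protected (echoing a
#' network where 2.8% of a 10.5%-protected study area is strict).
#'
#' @param seed Integer master seed; per-layer substreams are derived from
#'   it deterministically.
#' @param n_rows,n_cols Grid dimensions.
#' @param resolution Cell size in metres.
#' @param land_fraction Fraction of cells that are land, in [0, 1).
#' @param autocorrelation_length Smoothing scale of the underlying random
#'   fields, in metres.
#' @param n_species Number of species to generate.
#' @param d_max_range Min and max of the uniform draw for per-species
#'   maximum dispersal distance (metres).
#' @param habitat_fractions Fractions of water cells in the good (0.5) and
#'   very good (1.0) habitat classes, per species.
#' @param disturbance_intensity Fraction of water cells with a nonzero
#'   disturbance zone, in [0, 1].
#' @param mpa_fraction Fraction of water cells covered by MPAs, in [0, 1).
#' @param strict_fraction Fraction of the MPA-covered area that is
#'   strictly protected (IUCN Ia/Ib/II), in [0, 1].
#' @return A `seascape_scenario` parameter list.
#' @export
seascape_scenario <- function(seed = 1L, n_rows = 100L, n_cols = 100L,
                              resolution = 250,
                              land_fraction = 0.25,
                              autocorrelation_length = 1500,
                              n_species = 4L,
                              d_max_range = c(1000, 10000),
                              habitat_fractions = c(good = 0.10, very_good = 0.05),
                              disturbance_intensity = 0.15,
                              mpa_fraction = 0.105,
                              strict_fraction = 0.27) {
  stopifnot(land_fraction >= 0, land_fraction < 1,
            disturbance_intensity >= 0, disturbance_intensity <= 1,
            mpa_fraction >= 0, mpa_fraction < 1,
            strict_fraction >= 0, strict_fraction <= 1,
            length(d_max_range) == 2L, all(d_max_range > 0),
            d_max_range[1] <= d_max_range[2],
            sum(habitat_fractions) < 1, all(habitat_fractions > 0),
            autocorrelation_length > 0, n_species >= 1L)
  structure(list(seed = as.integer(seed), n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols), resolution = resolution,
                 land_fraction = land_fraction,
                 autocorrelation_length = autocorrelation_length,
                 n_species = as.integer(n_species),
                 d_max_range = as.numeric(d_max_range),
                 habitat_fractions = habitat_fractions,
                 disturbance_intensity = disturbance_intensity,
                 mpa_fraction = mpa_fraction,
                 strict_fraction = strict_fraction),
            class = "seascape_scenario")
}

## Evaluate code under a temporary RNG state; restores the caller's state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

## Deterministic substream seeds below 2^31.
substream <- function(scenario, offset) {
  as.integer((as.numeric(scenario$seed) * 1000003 + offset) %% 2147483629)
}

## Isotropic Gaussian smoothing of a matrix with edge renormalization,
## done separably with dense band matrices (grids here are small).
smooth_field <- function(mat, sigma_cells) {
  if (sigma_cells <= 0) return(mat)
  band <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    K <- exp(-d^2 / (2 * sigma_cells^2))
    K[d > 4 * sigma_cells] <- 0
    K / rowSums(K)
  }
  band(nrow(mat)) %*% mat %*% t(band(ncol(mat)))
}

scale01 <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(x * 0)
  (x - rng[1]) / diff(rng)
}

#' Generate the archipelago land/water mask
#'
#' Thresholds a smoothed Gaussian random field at the land-fraction
#' quantile, which yields spatially contiguous land clumps and an exact
#' land fraction up to rounding. Draws are retried (on deterministic
#' sub-seeds) until at least 80% of the water cells form one connected
#' component, so the seascape behaves like an archipelago rather than a
#' set of disconnected basins.
#'
#' @param scenario A `seascape_scenario`.
#' @return A `seascape_grid` with the generated water mask.
#' @export
generate_land_mask <- function(scenario) {
  stopifnot(inherits(scenario, "seascape_scenario"))
  if (scenario$land_fraction >= 1) stop("land_fraction must leave some water")
  nr <- scenario$n_rows; nc <- scenario$n_cols
  sigma <- scenario$autocorrelation_length / scenario$resolution
  for (attempt in 1:20) {
    z <- with_seed(substream(scenario, attempt), {
      smooth_field(matrix(stats::rnorm(nr * nc), nr, nc), sigma)
    })
    if (scenario$land_fraction == 0) {
      water <- matrix(TRUE, nr, nc)
    } else {
      thr <- stats::quantile(z, 1 - scenario$land_fraction, names = FALSE)
      water <- z < thr
    }
    grid <- seascape_grid(nr, nc, scenario$resolution, c(0, nr * scenario$resolution),
                          water = water)
    if (water_connected_enough(grid)) return(grid)
  }
  grid # last attempt, even if fragmented
}

water_connected_enough <- function(grid, min_fraction = 0.8) {
  tg <- build_traversal_graph(grid)
  comp <- igraph::components(tg$graph)
  max(comp$csize) >= min_fraction * length(tg$cells)
}

## Shore-proximity field: smoothing the land indicator gives a smooth
## surface that is high near (and on) land and decays seaward.
shore_proximity <- function(grid, sigma_cells) {
  land <- matrix(0, grid$n_rows, grid$n_cols)
  land[!grid$water] <- 1
  smooth_field(land, sigma_cells)
}

#' Generate a species' habitat layer and dispersal profile
#'
#' An independent autocorrelated random field per species, biased toward
#' near-shore cells (the shallow sheltered analogue), quantile-thresholded
#' on water cells into the three quality classes. The species' maximum
#' dispersal distance is drawn uniformly from the scenario's range.
#'
#' @param scenario A `seascape_scenario`.
#' @param grid Grid from [generate_land_mask()].
#' @param species_index Which species (1-based).
#' @param alpha Kernel steepness recorded in the profile (default 0.3).
#' @return A `species_profile` (the habitat layer is `$habitat`).
#' @export
generate_species <- function(scenario, grid, species_index, alpha = 0.3) {
  stopifnot(inherits(scenario, "seascape_scenario"),
            species_index >= 1L, species_index <= scenario$n_species)
  sigma <- scenario$autocorrelation_length / scenario$resolution
  res <- with_seed(substream(scenario, 100 + species_index), {
    z <- smooth_field(matrix(stats::rnorm(n_cells(grid)), grid$n_rows,
                             grid$n_cols), sigma)
    d_max <- stats::runif(1, scenario$d_max_range[1], scenario$d_max_range[2])
    list(z = z, d_max = d_max)
  })
  field <- scale01(res$z) + 0.75 * scale01(shore_proximity(grid, sigma))
  wv <- field[grid$water]
  hf <- scenario$habitat_fractions
  q_vg <- stats::quantile(wv, 1 - hf[["very_good"]], names = FALSE)
  q_g <- stats::quantile(wv, 1 - hf[["very_good"]] - hf[["good"]], names = FALSE)
  quality <- matrix(0, grid$n_rows, grid$n_cols)
  quality[grid$water & field >= q_g] <- 0.5
  quality[grid$water & field >= q_vg] <- 1.0
  habitat <- habitat_layer(grid, quality)
  species_profile(paste0("species_", species_index), habitat,
                  d_max = res$d_max, alpha = alpha)
}

#' Generate the anthropogenic-disturbance layer
#'
#' Nonzero zones are placed on the `disturbance_intensity` fraction of
#' water cells ranked highest by shore proximity plus noise (piers,
#' marinas and other structures cluster along coasts). Within disturbed
#' cells, zones 1-5 are assigned by rank with decreasing shares
#' (35/25/18/13/9% of disturbed cells), so higher zones are rarer and the
#' most shore-bound cells carry the highest obstruction.
#'
#' @param scenario A `seascape_scenario`.
#' @param grid Grid from [generate_land_mask()].
#' @return A `disturbance_layer`.
#' @export
generate_disturbance <- function(scenario, grid) {
  stopifnot(inherits(scenario, "seascape_scenario"))
  zone <- matrix(0L, grid$n_rows, grid$n_cols)
  n_water <- sum(grid$water)
  n_dist <- round_half_up(scenario$disturbance_intensity * n_water)
  if (n_dist > 0) {
    sigma <- scenario$autocorrelation_length / scenario$resolution
    field <- with_seed(substream(scenario, 2), {
      scale01(shore_proximity(grid, sigma)) +
        0.35 * scale01(smooth_field(matrix(stats::rnorm(n_cells(grid)),
                                           grid$n_rows, grid$n_cols),
                                    sigma / 2))
    })
    wi <- which(grid$water)
    ranked <- wi[order(field[wi], decreasing = TRUE)][seq_len(n_dist)]
    shares <- c(0.35, 0.25, 0.18, 0.13, 0.09) / sum(c(0.35, 0.25, 0.18, 0.13, 0.09))
    counts <- diff(c(0, round_half_up(cumsum(rev(shares)) * n_dist)))
    counts <- sort(counts) # zone 5 first (rarest), then 4, ..., 1
    z <- rep(5:1, times = counts)[seq_len(n_dist)]
    zone[ranked] <- z
  }
  disturbance_layer(grid, zone)
}

#' Generate MPA polygons with IUCN categories
#'
#' Random blob polygons are added until their rasterized coverage of the
#' water cells reaches `mpa_fraction` (within tolerance). A
#' `strict_fraction` share of the covered area is assigned strict
#' categories (Ia, Ib, II) and the rest non-strict ones (IV, V, or no
#' reported designation). One small non-strict polygon is deliberately
#' placed inside a strict one so that overlapping designations occur and
#' the strictest-designation rule is exercised.
#'
#' @param scenario A `seascape_scenario`.
#' @param grid Grid from [generate_land_mask()].
#' @return An `mpa_polygons` object (empty when `mpa_fraction` is 0).
#' @export
generate_mpas <- function(scenario, grid) {
  stopifnot(inherits(scenario, "seascape_scenario"))
  if (scenario$mpa_fraction == 0)
    return(mpa_polygons(list(), character(0)))
  res <- grid$resolution
  wi <- which(grid$water)
  n_water <- length(wi)
  rc <- arrayInd(wi, c(grid$n_rows, grid$n_cols))
  water_xy <- cell_xy(grid, rc_to_cell(grid, rc[, 1], rc[, 2]))

  with_seed(substream(scenario, 3), {
    covered <- logical(n_water)
    target <- scenario$mpa_fraction
    rings <- list(); areas <- numeric(0)
    guard <- 0L
    while (sum(covered) / n_water < target - 0.005 && guard < 500L) {
      guard <- guard + 1L
      centre <- water_xy[sample.int(n_water, 1L), ]
      radius <- stats::runif(1, 1.5, 6) * res
      for (try_shrink in 1:4) {
        poly <- blob_polygon(centre, radius)
        inside <- mgcv::in.out(rbind(poly, poly[1, ]), water_xy)
        new_cov <- sum(inside & !covered) / n_water
        if (sum(covered) / n_water + new_cov <= target + 0.004) {
          if (new_cov > 0) {
            rings[[length(rings) + 1L]] <- list(poly)
            areas <- c(areas, sum(inside & !covered))
            covered <- covered | inside
          }
          break
        }
        radius <- radius * 0.55
      }
    }
    n_poly <- length(rings)
    category <- character(n_poly)
    strict_cats <- c("Ia", "Ib", "II"); loose_cats <- c("IV", "V", NA)
    strict_area <- 0
    total_area <- sum(areas)
    # smallest polygons first, so the strict share overshoots its target
    # by at most one small polygon's area
    for (i in order(areas)) {
      if (total_area > 0 && strict_area / total_area < scenario$strict_fraction) {
        category[i] <- sample(strict_cats, 1L)
        strict_area <- strict_area + areas[i]
      } else {
        category[i] <- sample(loose_cats, 1L)
      }
    }
    # deliberate overlap: a small non-strict blob inside a strict polygon
    strict_idx <- which(is_strict_category(category))
    if (length(strict_idx) && n_poly >= 2L) {
      host <- rings[[strict_idx[1L]]][[1L]]
      centre <- colMeans(host)
      rings[[n_poly + 1L]] <- list(blob_polygon(centre, 1.2 * res))
      category <- c(category, "V")
    }
    mpa_polygons(rings, category)
  })
}

## Irregular star-convex blob around a centre: radial noise smoothed
## around the circle.
blob_polygon <- function(centre, radius, n_vertices = 16L) {
  ang <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  noise <- stats::rnorm(n_vertices)
  noise <- stats::filter(c(noise, noise, noise), rep(1 / 5, 5),
                         circular = TRUE)[(n_vertices + 1):(2 * n_vertices)]
  r <- radius * (1 + 0.35 * as.numeric(scale(noise)) * 0.5)
  r <- pmax(r, 0.3 * radius)
  cbind(centre[1] + r * cos(ang), centre[2] + r * sin(ang))
}

#' Generate a complete synthetic scenario bundle
#'
#' Runs all generators in a fixed order and returns every input the
#' analysis workflow needs.
#'
#' @param scenario A `seascape_scenario`.
#' @return List with `grid`, `species` (list of `species_profile`),
#'   `disturbance`, `mpas` (polygons), and `mpa_status` (rasterized).
#' @export
generate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "seascape_scenario"))
  grid <- generate_land_mask(scenario)
  species <- lapply(seq_len(scenario$n_species), function(i)
    generate_species(scenario, grid, i))
  disturbance <- generate_disturbance(scenario, grid)
  mpas <- generate_mpas(scenario, grid)
  list(grid = grid, species = species, disturbance = disturbance,
       mpas = mpas, mpa_status = rasterize_mpas(mpas, grid),
       scenario = scenario)
}

#' Write a scenario bundle to disk
#'
#' Writes the mask, habitat and disturbance rasters (ESRI ASCII grids),
#' the MPA polygons (GeoJSON), and a YAML config pointing at them, ready
#' for [run_pipeline()].
#'
#' @param bundle Result of [generate_scenario()].
#' @param dir Output directory (created if needed).
#' @return Path to the written config file, invisibly.
#' @export
write_scenario_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_raster_layer(bundle$grid, file.path(dir, "mask.asc"))
  for (sp in bundle$species)
    write_raster_layer(sp$habitat, file.path(dir, paste0("habitat_", sp$name, ".asc")))
  write_raster_layer(bundle$disturbance, file.path(dir, "disturbance.asc"))
  write_mpa_polygons(bundle$mpas, file.path(dir, "mpas.geojson"))
  config <- list(
    mask = "mask.asc",
    disturbance = "disturbance.asc",
    mpas = "mpas.geojson",
    species = lapply(bundle$species, function(sp)
      list(name = sp$name, habitat = paste0("habitat_", sp$name, ".asc"),
           d_max = sp$d_max, alpha = sp$alpha)),
    generations = 3L,
    prioritization = list(start_fraction = 0.11, step = 0.01),
    output_dir = "outputs")
  cfg_path <- file.path(dir, "config.yml")
  yaml::write_yaml(config, cfg_path)
  invisible(cfg_path)
}
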