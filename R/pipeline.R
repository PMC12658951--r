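## End-to-end workflow: simulate or load inputs, build connectivity and
## vulnerability features for every species, assess the MPA network, and
## rank cells for network expansion. One YAML config drives everything.

CONFIG_KEYS <- c("mask", "disturbance", "mpas", "species", "scenario",
                 "generations", "zone_conductance", "prioritization",
                 "output_dir", "seed", "category_field", "base_dir")
SPECIES_KEYS <- c("name", "habitat", "d_max", "alpha")
SCENARIO_KEYS <- c("seed", "n_rows", "n_cols", "resolution", "land_fraction",
                   "autocorrelation_length", "n_species", "d_max_range",
                   "habitat_fractions", "disturbance_intensity",
                   "mpa_fraction", "strict_fraction")
PRIORITIZATION_KEYS <- c("start_fraction", "step", "max_increments")

#' Read and validate a pipeline configuration
#'
#' The config either names input files (`mask`, `disturbance`, `mpas`,
#' per-species `habitat` rasters with `d_max`/`alpha`) or carries a
#' `scenario` block for synthetic generation. Unknown keys are rejected.
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @param base_dir Directory against which relative paths are resolved
#'   (defaults to the config file's directory).
#' @return A validated config list with `base_dir` attached.
#' @export
read_run_config <- function(config, base_dir = NULL) {
  if (is.character(config)) {
    if (is.null(base_dir)) base_dir <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
  }
  if (is.null(base_dir)) base_dir <- if (!is.null(config$base_dir))
    config$base_dir else "."
  check_keys <- function(x, allowed, where) {
    unknown <- setdiff(names(x), allowed)
    if (length(unknown))
      stop("unknown config key(s) in ", where, ": ",
           paste(unknown, collapse = ", "))
  }
  check_keys(config, CONFIG_KEYS, "config")
  if (!is.null(config$scenario)) {
    check_keys(config$scenario, SCENARIO_KEYS, "scenario")
  } else {
    for (k in c("mask", "species"))
      if (is.null(config[[k]]))
        stop("config needs either a 'scenario' block or input paths; missing '", k, "'")
    for (sp in config$species) {
      check_keys(sp, SPECIES_KEYS, "species entry")
      for (k in c("name", "habitat", "d_max"))
        if (is.null(sp[[k]])) stop("species entry missing '", k, "'")
    }
  }
  if (!is.null(config$prioritization))
    check_keys(config$prioritization, PRIORITIZATION_KEYS, "prioritization")
  if (is.null(config$generations)) config$generations <- 3L
  if (is.null(config$category_field)) config$category_field <- "iucn_cat"
  config$base_dir <- base_dir
  config
}

pipeline_log <- function(stage, ..., quiet = FALSE) {
  if (!quiet) message(sprintf("[seaconn:%s] %s", stage, paste0(...)))
}

load_pipeline_inputs <- function(config, quiet = FALSE) {
  if (!is.null(config$scenario)) {
    pipeline_log("simulate", "generating synthetic scenario", quiet = quiet)
    sc <- do.call(seascape_scenario, config$scenario)
    return(generate_scenario(sc))
  }
  pth <- function(p) file.path(config$base_dir, p)
  pipeline_log("load", "reading rasters and MPA polygons", quiet = quiet)
  grid <- read_raster_layer(pth(config$mask), "mask")
  species <- lapply(config$species, function(sp) {
    hab <- read_raster_layer(pth(sp$habitat), "habitat", grid = grid)
    species_profile(sp$name, hab, d_max = sp$d_max,
                    alpha = if (is.null(sp$alpha)) 0.3 else sp$alpha)
  })
  disturbance <- if (!is.null(config$disturbance))
    read_raster_layer(pth(config$disturbance), "disturbance", grid = grid)
  else disturbance_layer(grid, matrix(0L, grid$n_rows, grid$n_cols))
  mpas <- if (!is.null(config$mpas))
    read_mpa_polygons(pth(config$mpas), config$category_field)
  else mpa_polygons(list(), character(0))
  list(grid = grid, species = species, disturbance = disturbance,
       mpas = mpas, mpa_status = rasterize_mpas(mpas, grid))
}

#' Run the full seascape-connectivity workflow
#'
#' Executes the stages in dependency order: load or simulate inputs,
#' per-species connectivity (exports), vulnerability under disturbance,
#' MPA-network assessment, and incremental prioritization. Writes rasters
#' (ASCII grids), CSV tables, and a JSON run manifest to the output
#' directory, and returns everything invisibly for programmatic use.
#'
#' @param config Path to a YAML config or an equivalent list (see
#'   [read_run_config()]).
#' @param out_dir Output directory; overrides the config's `output_dir`.
#' @param quiet Suppress stage log messages.
#' @return (Invisibly) list with `inputs`, `features`, `assessment`,
#'   `ranking`, and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  config <- read_run_config(config)
  if (is.null(out_dir))
    out_dir <- file.path(config$base_dir,
                         if (is.null(config$output_dir)) "outputs"
                         else config$output_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- c()
  tick <- function(stage) {
    t <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t - t0, 3)
    t0 <<- t
  }

  inputs <- load_pipeline_inputs(config, quiet = quiet)
  grid <- inputs$grid
  g <- as.integer(config$generations)
  zmap <- if (is.null(config$zone_conductance)) DEFAULT_ZONE_CONDUCTANCE
          else unlist(config$zone_conductance)
  tick("inputs")

  pipeline_log("connect", "building traversal graphs", quiet = quiet)
  baseline_graph <- build_traversal_graph(grid)
  disturbed_graph <- build_traversal_graph(
    grid, zones_to_conductance(inputs$disturbance, zmap))
  features <- list()
  for (sp in inputs$species) {
    pipeline_log("connect", sp$name, ": distances, K^", g, ", exports",
                 quiet = quiet)
    cells <- habitat_cells(sp$habitat)
    dA <- least_cost_distances(baseline_graph, cells, cutoff = sp$d_max)
    A <- generational_matrix(build_connectivity_matrix(sp, dA), g)
    dB <- least_cost_distances(disturbed_graph, cells, cutoff = sp$d_max)
    B <- generational_matrix(build_connectivity_matrix(sp, dB, disturbed = TRUE), g)
    features[[paste0(sp$name, ":habitat")]] <- habitat_feature(sp)
    features[[paste0(sp$name, ":exports")]] <- exports(A, grid)
    features[[paste0(sp$name, ":vulnerable_imports")]] <-
      vulnerability_from_matrices(A, B, grid)
  }
  tick("connectivity")

  for (f in features)
    write_raster_layer(f, file.path(out_dir, paste0(f$kind, "_", f$species, ".asc")))
  write_feature_csv(features, file.path(out_dir, "features.csv"))

  # features with zero total amount carry no information for assessment or
  # prioritization (e.g. vulnerability when no disturbance is present)
  totals <- vapply(features, function(f) sum(f$values), 0)
  for (nm in names(features)[totals <= 0])
    pipeline_log("assess", "dropping zero-total feature ", nm, quiet = quiet)
  features_used <- features[totals > 0]
  if (!length(features_used)) stop("no feature has positive total amount")

  pipeline_log("assess", "MPA-network assessment", quiet = quiet)
  assessment <- assess_network(features_used, inputs$mpa_status)
  utils::write.csv(assessment$records, file.path(out_dir, "assessment.csv"),
                   row.names = FALSE)
  utils::write.csv(assessment$summary,
                   file.path(out_dir, "assessment_summary.csv"),
                   row.names = FALSE)
  tick("assessment")

  pipeline_log("prioritize", "incremental minimum-shortfall ranking",
               quiet = quiet)
  water_units <- sort(which(t(grid$water)) - 1L)
  locked <- water_units[counted_status(inputs$mpa_status, "full")[
    cell_to_rc(grid, water_units)]]
  problem <- planning_problem(features_used, locked_in = locked)
  prio <- config$prioritization
  start_fraction <- if (is.null(prio$start_fraction)) 0.11 else prio$start_fraction
  step <- if (is.null(prio$step)) 0.01 else prio$step
  # the starting budget must at least accommodate the locked-in MPAs;
  # if the existing network is larger, begin at the next step above it
  while (round_half_up(start_fraction * length(problem$units)) <
         length(problem$locked_in)) {
    start_fraction <- start_fraction + step
    pipeline_log("prioritize", sprintf(
      "locked-in MPAs exceed the starting budget; raising start to %.2f",
      start_fraction), quiet = quiet)
  }
  ranking <- incremental_ranking(
    problem,
    start_fraction = start_fraction,
    step = step,
    max_increments = if (is.null(prio$max_increments)) 1000L
                     else prio$max_increments)
  rank_raster <- ranking_raster(ranking)
  write_ascii_grid(rank_raster, grid, file.path(out_dir, "priority_rank.asc"))
  utils::write.csv(ranking$curve, file.path(out_dir, "protection_curve.csv"),
                   row.names = FALSE)
  tick("prioritization")

  manifest <- list(
    package = "seaconn",
    version = as.character(utils::packageVersion("seaconn")),
    generations = g,
    zone_conductance = as.list(zmap),
    n_species = length(inputs$species),
    species = lapply(inputs$species, function(sp)
      list(name = sp$name, d_max = sp$d_max, alpha = sp$alpha,
           n_habitat_cells = length(habitat_cells(sp$habitat)))),
    grid = list(n_rows = grid$n_rows, n_cols = grid$n_cols,
                resolution = grid$resolution, n_water = sum(grid$water)),
    scenario = config$scenario,
    input_checksums = input_checksums(config),
    stage_seconds = as.list(timings),
    outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  pipeline_log("done", "outputs in ", out_dir, quiet = quiet)
  invisible(list(inputs = inputs, features = features,
                 assessment = assessment, ranking = ranking,
                 manifest = manifest, out_dir = out_dir))
}

input_checksums <- function(config) {
  if (!is.null(config$scenario)) return(NULL)
  paths <- c(config$mask, config$disturbance, config$mpas,
             vapply(config$species, function(sp) sp$habitat, ""))
  paths <- file.path(config$base_dir, paths[!vapply(paths, is.null, TRUE)])
  sums <- tools::md5sum(paths)
  stats::setNames(as.list(unname(sums)), basename(paths))
}

## Long-format per-cell feature table (cell_id, species, feature_kind, amount),
## positive amounts only.
write_feature_csv <- function(features, path) {
  rows <- lapply(features, function(f) {
    cells <- which(t(f$values) > 0) - 1L
    if (!length(cells)) return(NULL)
    data.frame(cell_id = cells, species = f$species, feature_kind = f$kind,
               amount = layer_values_at(f, cells))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
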