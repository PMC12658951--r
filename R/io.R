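## Raster I/O: single-band ESRI ASCII grids (.asc), the plain-text raster
## interchange format. One file per layer; float for habitat/features,
## integer for zones and status. Values are written with 17 significant
## digits so a write -> read round trip is bit-exact for doubles.

#' Read an ESRI ASCII grid raster
#'
#' Low-level reader returning the raw matrix and geometry. `NODATA_value`
#' pixels come back as `NA`; interpretation (land / zero) is up to the
#' typed readers.
#'
#' @param path Path to a `.asc` file.
#' @return List with `values` (numeric matrix, row 1 = top), `n_rows`,
#'   `n_cols`, `resolution`, `origin` (upper-left x, y).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, n = 6L)
  header <- list()
  n_header <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2L && grepl("^[A-Za-z_]", parts[1])) {
      header[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_header <- n_header + 1L
    } else break
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(header)))
    stop("not an ESRI ASCII grid (missing ", paste(setdiff(need, names(header)),
         collapse = ", "), "): ", path)
  nr <- as.integer(header$nrows); nc <- as.integer(header$ncols)
  vals <- scan(path, what = double(), skip = n_header, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("expected ", nr * nc, " cells, found ", length(vals), " in ", path)
  if (!is.null(header$nodata_value))
    vals[vals == header$nodata_value] <- NA_real_
  xll <- if (!is.null(header$xllcorner)) header$xllcorner else 0
  yll <- if (!is.null(header$yllcorner)) header$yllcorner else 0
  list(values = matrix(vals, nr, nc, byrow = TRUE),
       n_rows = nr, n_cols = nc, resolution = header$cellsize,
       origin = c(xll, yll + nr * header$cellsize))
}

#' Write an ESRI ASCII grid raster
#'
#' @param values Numeric matrix (row 1 = top row). `NA` is written as the
#'   nodata value.
#' @param grid The `seascape_grid` supplying the geometry.
#' @param path Output path.
#' @param nodata Nodata sentinel (default -9999).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(values, grid, path, nodata = -9999) {
  stopifnot(is.matrix(values),
            identical(dim(values), c(grid$n_rows, grid$n_cols)))
  num <- function(x) formatC(x, digits = 17, format = "g")
  header <- c(
    paste("ncols", grid$n_cols),
    paste("nrows", grid$n_rows),
    paste("xllcorner", num(grid$origin[1])),
    paste("yllcorner", num(grid$origin[2] - grid$n_rows * grid$resolution)),
    paste("cellsize", num(grid$resolution)),
    paste("NODATA_value", num(nodata)))
  v <- values
  v[is.na(v)] <- nodata
  body <- apply(v, 1L, function(row) paste(num(row), collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a raster layer bound to a shared grid
#'
#' Typed reader for the package's raster inputs. With `what = "mask"` the
#' raster defines the study grid itself: nonzero pixels are water, zero or
#' nodata pixels are land, and a new `seascape_grid` is returned. For the
#' other types a `grid` must be supplied and the file's geometry must match
#' it exactly; nodata pixels map to 0 (no habitat / no disturbance / no
#' amount).
#'
#' @param path Path to a `.asc` raster.
#' @param what One of `"mask"`, `"habitat"`, `"disturbance"`, `"feature"`.
#' @param grid A `seascape_grid` (required except for `"mask"`).
#' @param strict For habitat: enforce the three-class value set
#'   `{0, 0.5, 1}` (default `TRUE`).
#' @return A `seascape_grid`, `habitat_layer`, `disturbance_layer`, or
#'   numeric matrix of feature amounts.
#' @export
read_raster_layer <- function(path,
                              what = c("habitat", "disturbance", "mask", "feature"),
                              grid = NULL, strict = TRUE) {
  what <- match.arg(what)
  raw <- read_ascii_grid(path)
  if (what == "mask") {
    water <- !is.na(raw$values) & raw$values != 0
    return(seascape_grid(raw$n_rows, raw$n_cols, raw$resolution, raw$origin,
                         water = water))
  }
  if (is.null(grid)) stop("a shared grid is required to read a ", what, " layer")
  file_grid <- seascape_grid(raw$n_rows, raw$n_cols, raw$resolution, raw$origin)
  if (!same_geometry(grid, file_grid)) stop_geometry_mismatch(grid, file_grid)
  vals <- raw$values
  vals[is.na(vals)] <- 0
  switch(what,
         habitat = habitat_layer(grid, vals, strict = strict),
         disturbance = disturbance_layer(grid, vals),
         feature = vals)
}

#' Write a seascape layer as an ASCII grid
#'
#' Land cells are written as nodata for value layers; the water mask itself
#' is written as 1 (water) / 0 (land).
#'
#' @param layer A `habitat_layer`, `disturbance_layer`, `feature_layer`,
#'   `mpa_status_layer`, or `seascape_grid` (mask).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raster_layer <- function(layer, path) {
  if (inherits(layer, "seascape_grid"))
    return(write_ascii_grid(layer$water * 1, layer, path))
  stopifnot(inherits(layer, "seascape_layer"))
  write_ascii_grid(layer$values, layer$grid, path)
}

## ---- MPA polygons (GeoJSON) --------------------------------------------

#' MPA polygon set
#'
#' A lightweight container for MPA boundary polygons with an IUCN-category
#' attribute. Each feature has one or more rings (closed coordinate
#' matrices; additional rings are holes under the even-odd rule) and a
#' category string (`NA` when the designation is not reported).
#'
#' @param rings List (one element per feature) of lists of two-column
#'   coordinate matrices.
#' @param category Character vector of IUCN categories, `NA` allowed.
#' @return An `mpa_polygons` object.
#' @export
mpa_polygons <- function(rings, category) {
  stopifnot(length(rings) == length(category))
  for (f in rings) for (r in f) {
    if (!is.matrix(r) || ncol(r) != 2L || nrow(r) < 3L ||
        nrow(unique(r)) < 3L || anyNA(r))
      stop("invalid polygon geometry: each ring needs >= 3 distinct finite vertices")
  }
  structure(list(rings = rings, category = as.character(category)),
            class = "mpa_polygons")
}

#' @export
print.mpa_polygons <- function(x, ...) {
  cat(sprintf("<mpa_polygons> %d features (%d strict)\n",
              length(x$rings), sum(is_strict_category(x$category))))
  invisible(x)
}

#' @export
length.mpa_polygons <- function(x) length(x$rings)

#' Is an IUCN category string a strict designation?
#'
#' Categories Ia, Ib and II count as strictly protected; any other value,
#' or a missing designation, does not.
#'
#' @param category Character vector.
#' @return Logical vector.
#' @export
is_strict_category <- function(category) {
  cat <- toupper(trimws(as.character(category)))
  !is.na(cat) & cat %in% c("IA", "IB", "II")
}

#' Read MPA polygons from GeoJSON
#'
#' Expects a FeatureCollection of Polygon / MultiPolygon features carrying
#' the IUCN category in a property column (default `iucn_cat`). Features
#' without that property, or with an empty value, are treated as having no
#' reported designation.
#'
#' @param path Path to a GeoJSON file.
#' @param category_field Property name holding the IUCN category.
#' @return An `mpa_polygons` object.
#' @export
read_mpa_polygons <- function(path, category_field = "iucn_cat") {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection: ", path)
  rings <- list(); category <- character(0)
  for (feat in gj$features) {
    geom <- feat$geometry
    if (is.null(geom)) next
    ring_list <- switch(geom$type,
      Polygon = lapply(geom$coordinates, ring_to_matrix),
      MultiPolygon = unlist(lapply(geom$coordinates,
                                   function(p) lapply(p, ring_to_matrix)),
                            recursive = FALSE),
      stop("unsupported geometry type: ", geom$type))
    cat_val <- feat$properties[[category_field]]
    cat_val <- if (is.null(cat_val) || !nzchar(trimws(as.character(cat_val))))
      NA_character_ else as.character(cat_val)
    rings[[length(rings) + 1L]] <- ring_list
    category <- c(category, cat_val)
  }
  mpa_polygons(rings, category)
}

ring_to_matrix <- function(coords) {
  m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
  storage.mode(m) <- "double"
  m
}

#' Write MPA polygons to GeoJSON
#'
#' @param polys An `mpa_polygons` object.
#' @param path Output path.
#' @param category_field Property name for the IUCN category.
#' @return `path`, invisibly.
#' @export
write_mpa_polygons <- function(polys, path, category_field = "iucn_cat") {
  feats <- lapply(seq_along(polys$rings), function(i) {
    rings <- lapply(polys$rings[[i]], function(r) {
      if (!isTRUE(all.equal(r[1, ], r[nrow(r), ]))) r <- rbind(r, r[1, ])
      lapply(seq_len(nrow(r)), function(k) c(r[k, 1], r[k, 2]))
    })
    props <- stats::setNames(
      list(if (is.na(polys$category[i])) NULL else polys$category[i]),
      category_field)
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = rings))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Rasterize MPA polygons to a protection-status layer
#'
#' A cell is protected when its centre lies inside at least one polygon
#' (even-odd rule; additional rings act as holes). Where polygons of
#' different designations overlap, the strictest status present wins:
#' strict regulations are not overridden by overlapping non-strict MPAs.
#' The result does not depend on polygon order.
#'
#' @param polys An `mpa_polygons` object (may be empty).
#' @param grid A `seascape_grid`.
#' @return An `mpa_status_layer`.
#' @export
rasterize_mpas <- function(polys, grid) {
  status <- matrix(MPA_UNPROTECTED, grid$n_rows, grid$n_cols)
  if (length(polys$rings) == 0L)
    return(mpa_status_layer(grid, status))
  centres <- cell_xy(grid, seq_len(n_cells(grid)) - 1L)
  strict <- is_strict_category(polys$category)
  for (i in seq_along(polys$rings)) {
    bnd <- do.call(rbind, lapply(polys$rings[[i]], function(r) {
      if (!isTRUE(all.equal(r[1, ], r[nrow(r), ]))) r <- rbind(r, r[1, ])
      rbind(r, c(NA, NA))
    }))
    bnd <- bnd[-nrow(bnd), , drop = FALSE] # drop trailing NA separator
    box <- apply(bnd, 2L, range, na.rm = TRUE)
    cand <- which(centres[, 1] >= box[1, 1] & centres[, 1] <= box[2, 1] &
                  centres[, 2] >= box[1, 2] & centres[, 2] <= box[2, 2])
    if (!length(cand)) next
    inside <- mgcv::in.out(bnd, centres[cand, , drop = FALSE])
    level <- if (strict[i]) MPA_STRICT else MPA_NONSTRICT
    hit <- cand[inside]
    rc <- cell_to_rc(grid, hit - 1L)
    status[rc] <- pmax(status[rc], level)
  }
  mpa_status_layer(grid, status)
}
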