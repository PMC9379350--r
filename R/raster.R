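#' Construct a georeferenced raster grid
#'
#' `raster_grid` is the unit of analysis for the whole pipeline: a 2D numeric
#' matrix with an affine geotransform (origin at the top-left corner of cell
#' `[1, 1]`), a coordinate reference system identifier, and a nodata sentinel.
#' Row 1 is the northernmost row. Internally nodata cells are stored as `NA`.
#'
#' @param values numeric matrix; row 1 = north.
#' @param xmin x coordinate of the western (left) edge.
#' @param ymax y coordinate of the northern (top) edge.
#' @param xres,yres cell size along x and y (positive, map units).
#' @param crs CRS identifier. Supported: `"geographic"` (synonyms
#'   `"EPSG:4326"`, `"WGS84"`; units decimal degrees), `"projected-m"` and
#'   `"projected-km"` (planar grids with metre / kilometre units).
#' @param nodata sentinel value used when writing to disk (cells holding this
#'   value are converted to `NA` on construction).
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, xmin, ymax, xres, yres = xres,
                        crs, nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (missing(crs) || is.null(crs) || !nzchar(crs))
    stop("raster_grid: a CRS identifier is required (no silent default)")
  crs_units(crs) # validates
  if (xres <= 0 || yres <= 0) stop("raster_grid: cell sizes must be positive")
  values[!is.na(values) & values == nodata] <- NA_real_
  structure(
    list(values = values, xmin = xmin, ymax = ymax,
         xres = xres, yres = yres, crs = crs, nodata = nodata),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("<raster_grid> %d x %d cells, res %g x %g, crs '%s'\n",
              nrow(x$values), ncol(x$values), x$xres, x$yres, x$crs))
  rng <- suppressWarnings(range(x$values, na.rm = TRUE))
  cat(sprintf("  extent x [%g, %g] y [%g, %g]; values [%g, %g]; %d nodata\n",
              x$xmin, x$xmin + ncol(x$values) * x$xres,
              x$ymax - nrow(x$values) * x$yres, x$ymax,
              rng[1], rng[2], sum(is.na(x$values))))
  invisible(x)
}

is_raster_grid <- function(x) inherits(x, "raster_grid")

# Map-unit kind for a CRS id: "degree", "m" or "km".
crs_units <- function(crs) {
  if (crs %in% c("geographic", "EPSG:4326", "WGS84")) return("degree")
  if (crs == "projected-m") return("m")
  if (crs == "projected-km") return("km")
  stop(sprintf("unknown CRS '%s': use 'geographic'/'EPSG:4326' or 'projected-m'/'projected-km'", crs))
}

crs_is_geographic <- function(crs) crs_units(crs) == "degree"

#' Test whether two grids share shape, geotransform and CRS
#'
#' @param a,b `raster_grid` objects.
#' @param tol relative tolerance on the geotransform.
#' @return logical scalar.
#' @export
same_grid <- function(a, b, tol = 1e-9) {
  near <- function(p, q) abs(p - q) <= tol * max(1, abs(p), abs(q))
  identical(dim(a$values), dim(b$values)) &&
    near(a$xmin, b$xmin) && near(a$ymax, b$ymax) &&
    near(a$xres, b$xres) && near(a$yres, b$yres) &&
    a$crs == b$crs
}

# Error unless every grid in ... is aligned with the first.
check_aligned <- function(..., what = "rasters") {
  gs <- list(...)
  if (length(gs) == 1 && is.list(gs[[1]]) && !is_raster_grid(gs[[1]])) gs <- gs[[1]]
  for (i in seq_along(gs)[-1])
    if (!same_grid(gs[[1]], gs[[i]]))
      stop(sprintf("%s are not aligned: grid %d differs in shape, transform or CRS", what, i))
  invisible(TRUE)
}

#' Cell centre coordinates
#'
#' @param grid a `raster_grid`.
#' @return data.frame with columns `x`, `y`, `row`, `col`, one row per cell in
#'   row-major order.
#' @export
cell_centers <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  xs <- grid$xmin + (seq_len(nc) - 0.5) * grid$xres
  ys <- grid$ymax - (seq_len(nr) - 0.5) * grid$yres
  data.frame(x = rep(xs, each = nr), y = rep(ys, times = nc),
             row = rep(seq_len(nr), times = nc),
             col = rep(seq_len(nc), each = nr))
}

#' Locate points on a grid
#'
#' @param grid a `raster_grid`.
#' @param x,y point coordinates in the grid CRS.
#' @return data.frame with columns `row`, `col` (`NA` for points outside the
#'   grid extent).
#' @export
xy_to_cell <- function(grid, x, y) {
  col <- floor((x - grid$xmin) / grid$xres) + 1L
  row <- floor((grid$ymax - y) / grid$yres) + 1L
  bad <- col < 1L | col > ncol(grid$values) | row < 1L | row > nrow(grid$values)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = row, col = col)
}

#' Read a raster from an ESRI ASCII grid
#'
#' Reads a single-band raster stored in the plain-text ESRI ASCII grid format
#' (`.asc`). The CRS is read from a mandatory sidecar file `<path>.crs`
#' containing the CRS identifier on one line; a missing sidecar is an error —
#' no CRS is ever assumed.
#'
#' @param path path to the `.asc` file.
#' @return a `raster_grid` with nodata cells masked to `NA`.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop(sprintf("raster file not found: %s", path))
  crs_path <- paste0(path, ".crs")
  if (!file.exists(crs_path))
    stop(sprintf("CRS sidecar missing for %s (expected %s); refusing to assume a CRS",
                 path, crs_path))
  crs <- trimws(readLines(crs_path, n = 1L, warn = FALSE))

  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows")
  if (!all(need %in% names(hdr))) stop("malformed ASCII grid header")
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  cellsize <- if (!is.null(hdr$cellsize)) hdr$cellsize else stop("cellsize missing")
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - cellsize / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - cellsize / 2

  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc) stop("ASCII grid body does not match header dimensions")
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  raster_grid(m, xmin = xll, ymax = yll + nr * cellsize,
              xres = cellsize, crs = crs, nodata = nodata)
}

#' Write a raster to an ESRI ASCII grid
#'
#' Writes the grid in plain-text ESRI ASCII format plus a `<path>.crs` sidecar
#' carrying the CRS identifier, so that [read_raster()] round-trips values,
#' transform and CRS exactly. Requires square cells (the format has a single
#' `cellsize` field).
#'
#' @param grid a `raster_grid`.
#' @param path output path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path) {
  if (abs(grid$xres - grid$yres) > 1e-12)
    stop("ESRI ASCII grids require square cells (xres == yres)")
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", grid$xmin),
    sprintf("yllcorner %.10g", grid$ymax - nr * grid$yres),
    sprintf("cellsize %.10g", grid$xres),
    sprintf("NODATA_value %.10g", grid$nodata)
  )
  v <- grid$values
  v[is.na(v)] <- grid$nodata
  body <- apply(v, 1L, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                scientific = FALSE),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  writeLines(grid$crs, paste0(path, ".crs"))
  invisible(path)
}

#' Per-cell area in square kilometres
#'
#' For projected grids this is the constant `xres * yres` converted to km².
#' For geographic grids the area of each cell is the spherical quadrangle
#' area `R^2 * dlon * (sin(lat_top) - sin(lat_bottom))` with the WGS84
#' authalic-sphere radius `R = 6371.0072` km, so it varies with latitude. All
#' km² figures reported by the pipeline flow through this equal-area
#' accounting. Cells that are nodata in `grid` are nodata in the result.
#'
#' @param grid a `raster_grid`.
#' @return a `raster_grid` of areas (km²) on the same geometry.
#' @export
cell_area_km2 <- function(grid) {
  units <- crs_units(grid$crs)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  if (units == "degree") {
    R <- 6371.0072 # authalic sphere radius, km
    lat_top <- grid$ymax - (seq_len(nr) - 1L) * grid$yres
    lat_bot <- lat_top - grid$yres
    dlon <- grid$xres * pi / 180
    row_area <- R^2 * dlon * (sin(lat_top * pi / 180) - sin(lat_bot * pi / 180))
    m <- matrix(row_area, nrow = nr, ncol = nc)
  } else {
    per_cell <- switch(units,
                       m = grid$xres * grid$yres / 1e6,
                       km = grid$xres * grid$yres)
    m <- matrix(per_cell, nrow = nr, ncol = nc)
  }
  m[is.na(grid$values)] <- NA_real_
  out <- grid
  out$values <- m
  out
}

#' Total valid-cell area in km²
#'
#' @param grid a `raster_grid` (the validity mask).
#' @param areas optional precomputed [cell_area_km2()] grid; computed from
#'   `grid` when absent.
#' @return numeric scalar, km².
#' @export
total_area_km2 <- function(grid, areas = cell_area_km2(grid)) {
  check_aligned(grid, areas, what = "grid and area layer")
  sum(areas$values[!is.na(grid$values)], na.rm = TRUE)
}

#' Construct a climate predictor stack
#'
#' A named collection of aligned raster layers (e.g. bioclimatic variables
#' `BIO1`, `BIO14`, ...) under one scenario tag.
#'
#' @param layers named list of `raster_grid` objects; names are variable codes
#'   and must be unique.
#' @param scenario_tag label, conventionally `"current"` or `"future"`.
#' @return An object of class `climate_stack`.
#' @export
climate_stack <- function(layers, scenario_tag = "current") {
  if (length(layers) == 0) stop("climate_stack: at least one layer required")
  nm <- names(layers)
  if (is.null(nm) || any(!nzchar(nm))) stop("climate_stack: all layers must be named")
  if (anyDuplicated(nm)) stop("climate_stack: layer names must be unique")
  for (g in layers) if (!is_raster_grid(g)) stop("climate_stack: layers must be raster_grid objects")
  check_aligned(layers, what = "stack layers")
  structure(list(layers = layers, scenario_tag = scenario_tag),
            class = "climate_stack")
}

#' @export
print.climate_stack <- function(x, ...) {
  cat(sprintf("<climate_stack> '%s': %d layers (%s)\n", x$scenario_tag,
              length(x$layers), paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

# Matrix of layer values at valid cells: one column per variable, plus the
# row/col index of each retained cell. Cells nodata in any layer are dropped.
stack_values <- function(stack) {
  tmpl <- stack$layers[[1]]
  valid <- !is.na(tmpl$values)
  for (g in stack$layers) valid <- valid & !is.na(g$values)
  idx <- which(valid)
  m <- vapply(stack$layers, function(g) g$values[idx], numeric(length(idx)))
  if (length(idx) == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(stack$layers)))
  list(values = m, index = idx, valid = valid)
}

#' Extract predictor values at point locations
#'
#' @param stack a `climate_stack`.
#' @param lon,lat point coordinates in the stack CRS.
#' @return data.frame with one column per stack variable; rows for points that
#'   fall outside the grid or on nodata cells are `NA`.
#' @export
extract_features <- function(stack, lon, lat) {
  tmpl <- stack$layers[[1]]
  rc <- xy_to_cell(tmpl, lon, lat)
  out <- lapply(stack$layers, function(g) {
    v <- rep(NA_real_, length(lon))
    ok <- !is.na(rc$row)
    v[ok] <- g$values[cbind(rc$row[ok], rc$col[ok])]
    v
  })
  as.data.frame(out)
}
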