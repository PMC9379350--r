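#' Stack binary suitability maps into a species-richness map
#'
#' Cell-wise count of species whose binary map marks the cell suitable. A cell
#' is nodata only where every input is nodata.
#'
#' @param binaries list of aligned binary `raster_grid`s (values 0/1/nodata),
#'   or `ensemble_prediction` objects (their `binary` grid is used).
#' @return An object of class `richness_map`: `counts` (`raster_grid`) and
#'   `n_species`.
#' @export
stack_richness <- function(binaries) {
  binaries <- lapply(binaries, function(b)
    if (inherits(b, "ensemble_prediction")) b$binary else b)
  if (length(binaries) == 0) stop("no binary maps supplied")
  check_aligned(binaries, what = "binary maps")
  tmpl <- binaries[[1]]
  acc <- matrix(0, nrow(tmpl$values), ncol(tmpl$values))
  all_na <- matrix(TRUE, nrow(tmpl$values), ncol(tmpl$values))
  for (b in binaries) {
    v <- b$values
    acc <- acc + ifelse(is.na(v), 0, v)
    all_na <- all_na & is.na(v)
  }
  acc[all_na] <- NA_real_
  counts <- tmpl
  counts$values <- acc
  structure(list(counts = counts, n_species = length(binaries)),
            class = "richness_map")
}

#' @export
print.richness_map <- function(x, ...) {
  cat(sprintf("<richness_map> %d species stacked, max count %g\n",
              x$n_species, max(x$counts$values, na.rm = TRUE)))
  invisible(x)
}

#' Extent of suitability: cells suitable for at least one species
#'
#' @param richness a `richness_map`.
#' @return boolean `raster_grid` (1 where count >= 1, else 0; nodata kept).
#' @export
extent_map <- function(richness) {
  g <- richness$counts
  g$values <- ifelse(is.na(g$values), NA_real_, as.numeric(g$values >= 1))
  g
}

#' Richness hotspots by a percentile rule
#'
#' Under the default `"top_quartile"` rule a cell is a hotspot when its
#' richness is at least the 75th percentile of richness over occupied cells
#' (count >= 1), i.e. the top quartile of the occupied-cell richness
#' distribution. The alternative `"p25"` rule cuts at the 25th percentile of
#' occupied-cell richness instead (a far more permissive reading under which
#' hotspots approach the full extent). Percentiles use linear interpolation
#' between order statistics ([stats::quantile()] type 7). The rule and the
#' numeric cutoff are recorded in the result.
#'
#' @param richness a `richness_map` with at least one occupied cell.
#' @param rule `"top_quartile"` (default) or `"p25"`.
#' @return An object of class `hotspot_map`: `mask` (`raster_grid`, 1/0),
#'   `cutoff_value`, `rule`.
#' @export
hotspot_map <- function(richness, rule = c("top_quartile", "p25")) {
  rule <- match.arg(rule)
  v <- richness$counts$values
  pos <- v[!is.na(v) & v >= 1]
  if (length(pos) == 0) stop("no occupied cells: hotspots undefined")
  p <- if (rule == "top_quartile") 0.75 else 0.25
  cutoff <- stats::quantile(pos, probs = p, type = 7, names = FALSE)
  mask <- richness$counts
  mask$values <- ifelse(is.na(v), NA_real_, as.numeric(v >= cutoff & v >= 1))
  structure(list(mask = mask, cutoff_value = cutoff, rule = rule),
            class = "hotspot_map")
}

#' @export
print.hotspot_map <- function(x, ...) {
  cat(sprintf("<hotspot_map> rule '%s', cutoff %.3f, %d hotspot cells\n",
              x$rule, x$cutoff_value, sum(x$mask$values == 1, na.rm = TRUE)))
  invisible(x)
}

# Accept a hotspot_map, an ensemble_prediction, or a bare binary raster_grid.
as_mask_grid <- function(x) {
  if (inherits(x, "hotspot_map")) return(x$mask)
  if (inherits(x, "ensemble_prediction")) return(x$binary)
  if (is_raster_grid(x)) return(x)
  stop("expected a hotspot_map, ensemble_prediction or raster_grid")
}

#' Area of a binary map in km²
#'
#' Sum of cell areas over cells where the mask equals 1.
#'
#' @param binary binary `raster_grid` (or `hotspot_map`/`ensemble_prediction`).
#' @param areas cell-area `raster_grid` from [cell_area_km2()], aligned.
#' @return numeric scalar, km².
#' @export
species_area <- function(binary, areas) {
  binary <- as_mask_grid(binary)
  check_aligned(binary, areas, what = "binary map and area layer")
  sel <- !is.na(binary$values) & binary$values == 1
  sum(areas$values[sel], na.rm = TRUE)
}

#' Recompute change columns of a zonal area table
#'
#' Takes per-zone areas under the two scenarios (e.g. a published table, or a
#' table assembled elsewhere) and (re)derives `change_km2` and `change_pct`,
#' so every change figure is computed rather than transcribed.
#'
#' @param df data.frame with columns `zone_id`, `area_current_km2`,
#'   `area_future_km2` (extra columns kept).
#' @return the data.frame with recomputed change columns, classed
#'   `zonal_change_table`.
#' @export
as_zonal_change_table <- function(df) {
  need <- c("zone_id", "area_current_km2", "area_future_km2")
  if (!all(need %in% names(df)))
    stop("need columns zone_id, area_current_km2, area_future_km2")
  df$change_km2 <- df$area_future_km2 - df$area_current_km2
  df$change_pct <- ifelse(df$area_current_km2 > 0,
                          100 * df$change_km2 / df$area_current_km2, NA_real_)
  if (!inherits(df, "zonal_change_table"))
    class(df) <- c("zonal_change_table", class(df))
  df
}

#' Zonal current-vs-future change accounting
#'
#' For each zone, sums the km² of masked (hotspot or suitable) cells under the
#' current and the future scenario and derives the change columns. Zones with
#' no current area get an undefined (NA) percent change.
#'
#' @param current,future masks for the two scenarios (`hotspot_map`,
#'   `ensemble_prediction` or binary `raster_grid`), aligned.
#' @param zones a `zone_layer`, or a zone-index `raster_grid` produced by
#'   [rasterize_zones()].
#' @param areas cell-area `raster_grid` ([cell_area_km2()]).
#' @return data.frame of class `zonal_change_table` with columns `zone_id`,
#'   `area_current_km2`, `area_future_km2`, `change_km2`, `change_pct`.
#' @export
zonal_change <- function(current, future, zones, areas) {
  cur <- as_mask_grid(current)
  fut <- as_mask_grid(future)
  zr <- if (inherits(zones, "zone_layer")) rasterize_zones(zones, areas) else zones
  check_aligned(cur, fut, zr, areas, what = "change-analysis layers")
  ids <- attr(zr, "zone_ids")
  if (is.null(ids)) ids <- as.character(sort(unique(stats::na.omit(c(zr$values)))))

  zone_area <- function(mask) {
    sel <- !is.na(mask$values) & mask$values == 1 & !is.na(zr$values)
    sums <- tapply(areas$values[sel], zr$values[sel], sum)
    out <- stats::setNames(numeric(length(ids)), seq_along(ids))
    out[names(sums)] <- sums
    out
  }
  a_cur <- zone_area(cur)
  a_fut <- zone_area(fut)
  tbl <- data.frame(zone_id = ids,
                    area_current_km2 = as.numeric(a_cur),
                    area_future_km2 = as.numeric(a_fut))
  tbl$change_km2 <- tbl$area_future_km2 - tbl$area_current_km2
  tbl$change_pct <- ifelse(tbl$area_current_km2 > 0,
                           100 * tbl$change_km2 / tbl$area_current_km2,
                           NA_real_)
  class(tbl) <- c("zonal_change_table", class(tbl))
  tbl
}
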