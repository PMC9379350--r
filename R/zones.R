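#' Construct a zone layer
#'
#' A zone layer partitions (part of) the study area into named zones —
#' ecoregions, protected areas, provinces, physiographic regions or elevation
#' bands — supplied either as polygons or as raster masks.
#'
#' @param kind one of `"ecoregion"`, `"protected_area"`, `"province"`,
#'   `"physiography"`, `"elevation_band"`, or any descriptive label.
#' @param ids character vector of unique zone identifiers.
#' @param polygons list (same length as `ids`) where each element is a list of
#'   rings, each ring a 2-column matrix of vertex coordinates (first ring
#'   outer, further rings holes, even-odd rule). `NULL` if `masks` given.
#' @param masks list of `raster_grid` membership masks (non-`NA`, non-zero =
#'   member). `NULL` if `polygons` given.
#' @return An object of class `zone_layer`.
#' @export
zone_layer <- function(kind, ids, polygons = NULL, masks = NULL) {
  ids <- as.character(ids)
  if (length(ids) == 0) stop("zone_layer: empty zone set")
  if (anyDuplicated(ids)) stop("zone_layer: zone ids must be unique")
  if (is.null(polygons) == is.null(masks))
    stop("zone_layer: supply exactly one of polygons or masks")
  src <- if (is.null(masks)) polygons else masks
  if (length(src) != length(ids))
    stop("zone_layer: ids and geometries differ in length")
  structure(list(kind = kind, ids = ids, polygons = polygons, masks = masks),
            class = "zone_layer")
}

#' @export
print.zone_layer <- function(x, ...) {
  cat(sprintf("<zone_layer> kind '%s', %d zones (%s)\n", x$kind, length(x$ids),
              if (is.null(x$masks)) "polygons" else "raster masks"))
  invisible(x)
}

#' Read zones from a GeoJSON file
#'
#' Supports FeatureCollections of Polygon and MultiPolygon features. Zone ids
#' are taken from the named property of each feature.
#'
#' @param path GeoJSON file.
#' @param kind zone kind label, see [zone_layer()].
#' @param id_property name of the feature property holding the zone id
#'   (default `"name"`).
#' @return a `zone_layer` with polygon geometry.
#' @export
read_zones_geojson <- function(path, kind, id_property = "name") {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("GeoJSON file has no features")
  ids <- character(0); polys <- list()
  ring_to_matrix <- function(ring)
    do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
  for (f in gj$features) {
    id <- f$properties[[id_property]]
    if (is.null(id)) stop(sprintf("feature lacks property '%s'", id_property))
    geom <- f$geometry
    rings <- switch(geom$type,
      Polygon = lapply(geom$coordinates, ring_to_matrix),
      MultiPolygon = unlist(lapply(geom$coordinates,
                                   function(p) lapply(p, ring_to_matrix)),
                            recursive = FALSE),
      stop(sprintf("unsupported geometry type '%s'", geom$type)))
    ids <- c(ids, as.character(id))
    polys <- c(polys, list(rings))
  }
  zone_layer(kind, ids, polygons = polys)
}

# Rings (list of 2-col matrices) -> single NA-separated boundary matrix for
# mgcv::in.out even-odd point-in-polygon testing.
rings_to_boundary <- function(rings) {
  do.call(rbind, lapply(seq_along(rings), function(i) {
    r <- rings[[i]]
    if (i == 1) r else rbind(c(NA, NA), r)
  }))
}

#' Rasterize a zone layer onto a template grid
#'
#' Cell membership is decided by the cell-centre-in-polygon rule (even-odd).
#' Where zones overlap, the first-listed zone wins and a warning is emitted.
#' Cells outside all zones are nodata.
#'
#' @param zones a `zone_layer`.
#' @param template a `raster_grid` defining the target geometry (its nodata
#'   cells stay nodata in the output).
#' @return a `raster_grid` of integer zone indices (1-based into `zones$ids`),
#'   with `zones$ids` attached as attribute `"zone_ids"`.
#' @export
rasterize_zones <- function(zones, template) {
  nr <- nrow(template$values); nc <- ncol(template$values)
  out <- matrix(NA_real_, nr, nc)
  overlap <- 0L
  if (!is.null(zones$masks)) {
    for (i in seq_along(zones$ids)) {
      m <- zones$masks[[i]]
      check_aligned(template, m, what = "template and zone mask")
      member <- !is.na(m$values) & m$values != 0
      overlap <- overlap + sum(member & !is.na(out))
      out[member & is.na(out)] <- i
    }
  } else {
    cc <- cell_centers(template)
    pts <- cbind(cc$x, cc$y)
    any_hit <- FALSE
    for (i in seq_along(zones$ids)) {
      bnd <- rings_to_boundary(zones$polygons[[i]])
      inside <- mgcv::in.out(bnd, pts)
      if (!any(inside)) {
        warning(sprintf("zone '%s' labels no cells (outside template extent?)",
                        zones$ids[i]))
        next
      }
      any_hit <- TRUE
      idx <- cbind(cc$row[inside], cc$col[inside])
      cur <- out[idx]
      overlap <- overlap + sum(!is.na(cur))
      take <- is.na(cur)
      out[idx[take, , drop = FALSE]] <- i
    }
    if (!any_hit) warning("no zone labels any cell of the template")
  }
  if (overlap > 0)
    warning(sprintf("%d cells fall in more than one zone; first-listed zone kept", overlap))
  out[is.na(template$values)] <- NA_real_
  g <- template
  g$values <- out
  attr(g, "zone_ids") <- zones$ids
  g
}

#' Build elevation-band zones from a DEM
#'
#' Bands are half-open intervals `[lower, lower + width)` aligned to multiples
#' of `width`, covering the DEM's valid range. Band ids are formatted
#' `"lower-upper"` in metres.
#'
#' @param dem a `raster_grid` of elevations (m a.s.l.).
#' @param width band width in metres (default 500).
#' @return a `zone_layer` of raster masks, kind `"elevation_band"`.
#' @export
elevation_bands <- function(dem, width = 500) {
  if (width <= 0) stop("band width must be positive")
  v <- dem$values
  rng <- range(v, na.rm = TRUE)
  lo <- floor(rng[1] / width) * width
  hi <- ceiling((rng[2] + .Machine$double.eps) / width) * width
  lowers <- seq(lo, hi - width, by = width)
  masks <- lapply(lowers, function(l) {
    g <- dem
    g$values <- ifelse(!is.na(v) & v >= l & v < l + width, 1, NA_real_)
    g
  })
  ids <- sprintf("%d-%d", as.integer(lowers), as.integer(lowers + width))
  keep <- vapply(masks, function(g) any(!is.na(g$values)), logical(1))
  zone_layer("elevation_band", ids[keep], masks = masks[keep])
}
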