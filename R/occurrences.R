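#' Construct an occurrence set
#'
#' Presence records for one species together with its reported elevation
#' range. Records are held as a data.frame with columns `species`, `lon`,
#' `lat`, `elev_m` (may be `NA`) and `source`.
#'
#' @param species_id species identifier.
#' @param records data.frame of occurrence records. Missing `elev_m`/`source`
#'   columns are added as `NA`.
#' @param elev_min_m,elev_max_m reported elevation range of the species
#'   (m a.s.l.), used by [elevation_filter()].
#' @param crs CRS of the coordinates (default `"geographic"`, in which case
#'   lon/lat are validated against decimal-degree bounds; projected
#'   coordinates from synthetic landscapes skip that check).
#' @return An object of class `occurrence_set`.
#' @export
occurrence_set <- function(species_id, records,
                           elev_min_m = NA_real_, elev_max_m = NA_real_,
                           crs = "geographic") {
  records <- as.data.frame(records)
  if (!"species" %in% names(records)) records$species <- species_id
  for (col in c("elev_m", "source"))
    if (!col %in% names(records)) records[[col]] <- NA
  need <- c("species", "lon", "lat", "elev_m", "source")
  if (!all(c("lon", "lat") %in% names(records)))
    stop("records need lon and lat columns")
  records <- records[, need]
  if (crs_is_geographic(crs) &&
      (any(records$lon < -180 | records$lon > 180, na.rm = TRUE) ||
       any(records$lat < -90 | records$lat > 90, na.rm = TRUE)))
    stop("lon/lat outside valid decimal-degree ranges")
  ev <- records$elev_m
  if (any(!is.na(ev) & (ev < -500 | ev > 9000)))
    stop("elevation outside plausible range [-500, 9000] m")
  if (!is.na(elev_min_m) && !is.na(elev_max_m) && elev_min_m > elev_max_m)
    stop("elev_min_m must not exceed elev_max_m")
  structure(list(species_id = species_id, records = records,
                 elev_min_m = elev_min_m, elev_max_m = elev_max_m, crs = crs),
            class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("<occurrence_set> '%s': %d records, reported range %s-%s m\n",
              x$species_id, nrow(x$records), x$elev_min_m, x$elev_max_m))
  invisible(x)
}

#' Read occurrence records from CSV
#'
#' Expects columns `species,lon,lat` and optionally `elev_m,source`.
#'
#' @param path CSV file.
#' @return data.frame of records (possibly several species).
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "lon", "lat") %in% names(df)))
    stop("occurrence CSV must have species, lon, lat columns")
  for (col in c("elev_m", "source")) if (!col %in% names(df)) df[[col]] <- NA
  df
}

#' Remove duplicate occurrence records
#'
#' Records identical in the key `(species, lon, lat)` are reduced to one; the
#' first record in input order is kept, so records differing only in source or
#' elevation still collapse.
#'
#' @param records data.frame of occurrence records.
#' @return the deduplicated data.frame.
#' @export
deduplicate <- function(records) {
  if (nrow(records) == 0) return(records)
  key <- paste(records$species, records$lon, records$lat, sep = "\r")
  records[!duplicated(key), , drop = FALSE]
}

#' Drop records far outside the species' reported elevation range
#'
#' A record is dubious, and removed, when its elevation lies more than
#' `tolerance_m` outside the species' reported range, i.e. it is kept iff
#' `elev_m` is in `[elev_min_m - tolerance_m, elev_max_m + tolerance_m]`
#' (boundary inclusive). Records with no elevation are kept; their count is
#' reported in a warning and in the `n_no_elevation` attribute.
#'
#' @param set an `occurrence_set` with a reported elevation range.
#' @param tolerance_m permitted excursion outside the reported range (default
#'   1000 m).
#' @return the filtered `occurrence_set`.
#' @export
elevation_filter <- function(set, tolerance_m = 1000) {
  if (tolerance_m < 0) stop("tolerance_m must be non-negative")
  if (is.na(set$elev_min_m) || is.na(set$elev_max_m))
    stop("occurrence set has no reported elevation range")
  ev <- set$records$elev_m
  no_elev <- is.na(ev)
  keep <- no_elev |
    (ev >= set$elev_min_m - tolerance_m & ev <= set$elev_max_m + tolerance_m)
  out <- set
  out$records <- set$records[keep, , drop = FALSE]
  attr(out, "n_no_elevation") <- sum(no_elev)
  if (any(no_elev))
    warning(sprintf("%s: %d records without elevation passed the filter unchecked",
                    set$species_id, sum(no_elev)))
  out
}

#' Spatially thin occurrences to one record per grid cell
#'
#' Keeps the first record (input order, stable) in each cell of the analysis
#' grid. Records falling outside the template extent are dropped with a
#' warning.
#'
#' @param set an `occurrence_set`.
#' @param template `raster_grid` defining the analysis grid.
#' @return the thinned `occurrence_set`.
#' @export
spatial_thin <- function(set, template) {
  rec <- set$records
  if (nrow(rec) == 0) return(set)
  rc <- xy_to_cell(template, rec$lon, rec$lat)
  outside <- is.na(rc$row)
  if (any(outside))
    warning(sprintf("%s: %d records outside the template extent dropped",
                    set$species_id, sum(outside)))
  cell <- (rc$row - 1L) * ncol(template$values) + rc$col
  keep <- !outside & !duplicated(cell, incomparables = NA)
  out <- set
  out$records <- rec[keep, , drop = FALSE]
  out
}

#' Full occurrence cleaning pipeline
#'
#' Applies, in this fixed order: deduplication, the elevation sanity filter,
#' and one-record-per-cell spatial thinning. Returns the cleaned set with a
#' per-rule removal report attached.
#'
#' @param set an `occurrence_set`.
#' @param template analysis grid (`raster_grid`).
#' @param tolerance_m see [elevation_filter()].
#' @return cleaned `occurrence_set`; attribute `"cleaning_report"` is a
#'   one-row data.frame of counts removed per rule.
#' @export
clean_occurrences <- function(set, template, tolerance_m = 1000) {
  n0 <- nrow(set$records)
  s1 <- set
  s1$records <- deduplicate(set$records)
  n1 <- nrow(s1$records)
  s2 <- suppressWarnings(elevation_filter(s1, tolerance_m))
  n2 <- nrow(s2$records)
  s3 <- suppressWarnings(spatial_thin(s2, template))
  n3 <- nrow(s3$records)
  attr(s3, "cleaning_report") <- data.frame(
    species = set$species_id, n_input = n0,
    removed_duplicate = n0 - n1, removed_elevation = n1 - n2,
    removed_thinning = n2 - n3, n_clean = n3)
  s3
}
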