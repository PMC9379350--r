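#' Build a per-species area bookkeeping table
#'
#' @param predictions_current,predictions_future lists of
#'   `ensemble_prediction` objects (same species, same order).
#' @param areas cell-area `raster_grid` ([cell_area_km2()]).
#' @return data.frame with columns `species`, `area_current_km2`,
#'   `area_future_km2`, `change_km2`.
#' @export
make_area_table <- function(predictions_current, predictions_future, areas) {
  stopifnot(length(predictions_current) == length(predictions_future))
  rows <- lapply(seq_along(predictions_current), function(i) {
    pc <- predictions_current[[i]]; pf <- predictions_future[[i]]
    if (!identical(pc$species_id, pf$species_id))
      stop("current/future predictions are not in matching species order")
    data.frame(species = pc$species_id,
               area_current_km2 = species_area(pc, areas),
               area_future_km2 = species_area(pf, areas))
  })
  tbl <- do.call(rbind, rows)
  tbl$change_km2 <- tbl$area_future_km2 - tbl$area_current_km2
  tbl
}

#' Summary statistics over a per-species area table
#'
#' Computes the headline numbers of a multi-species change analysis: mean
#' current and future suitable area, the aggregate percent change (change of
#' the mean — equivalently of the total — not the mean of per-species
#' changes), the count and fraction of species whose area declines, the ratio
#' of the largest to the smallest current area, and per-species percent
#' changes (`100 * (future - current) / current`). Species with zero current
#' area are excluded from per-species percent change with a warning.
#'
#' @param table data.frame with columns `species`, `area_current_km2`,
#'   `area_future_km2` (and optionally `change_km2`, recomputed regardless).
#' @return list with elements `n_species`, `mean_current_km2`,
#'   `mean_future_km2`, `mean_change_pct`, `n_declining`, `frac_declining`,
#'   `pct_change` (named per-species vector), `max_min_ratio`.
#' @export
summarize_area_table <- function(table) {
  if (nrow(table) < 1) stop("empty area table")
  cur <- table$area_current_km2
  fut <- table$area_future_km2
  change <- fut - cur
  zero <- cur == 0
  if (any(zero))
    warning(sprintf("%d species with zero current area excluded from percent change",
                    sum(zero)))
  pct <- rep(NA_real_, nrow(table))
  pct[!zero] <- 100 * change[!zero] / cur[!zero]
  names(pct) <- table$species
  list(
    n_species = nrow(table),
    mean_current_km2 = mean(cur),
    mean_future_km2 = mean(fut),
    mean_change_pct = 100 * (mean(fut) - mean(cur)) / mean(cur),
    n_declining = sum(change < 0),
    frac_declining = mean(change < 0),
    pct_change = pct,
    max_min_ratio = max(cur) / min(cur[cur > 0])
  )
}

#' Share of the total hotspot area lying inside protected areas
#'
#' @param pa_table `zonal_change_table` over protected-area zones.
#' @param total_hotspot_km2 total hotspot area of the study region, km²
#'   (must be positive).
#' @param scenario `"current"` (default) or `"future"`: which column to sum.
#' @return percent of `total_hotspot_km2` falling inside the listed zones.
#' @export
protected_area_share <- function(pa_table, total_hotspot_km2,
                                 scenario = c("current", "future")) {
  scenario <- match.arg(scenario)
  if (!is.finite(total_hotspot_km2) || total_hotspot_km2 <= 0)
    stop("total_hotspot_km2 must be positive")
  col <- if (scenario == "current") "area_current_km2" else "area_future_km2"
  if (nrow(pa_table) == 0) return(0)
  100 * sum(pa_table[[col]]) / total_hotspot_km2
}

#' Load a packaged reference table
#'
#' The package ships, as plain CSV under `extdata/`, the published reference
#' tables of the Nepal Himalaya medicinal-plant study this pipeline
#' re-implements: `"table1"` (species, reported elevation range, occurrence
#' counts), `"table2"` (per-species suitable area, current/future),
#' `"table3"` (hotspot area by protected area) and `"table4"` (hotspot area by
#' ecoregion). They serve as the exact-reproduction surface for the reporting
#' functions.
#'
#' @param name one of `"table1"`, `"table2"`, `"table3"`, `"table4"`.
#' @return data.frame.
#' @export
nichecast_table <- function(name = c("table1", "table2", "table3", "table4")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "nichecast",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write the human-readable summary report
#'
#' @param summary result of [summarize_area_table()].
#' @param path output text file; the same content is returned invisibly.
#' @return character vector of report lines, invisibly.
#' @export
write_summary_report <- function(summary, path = NULL) {
  lines <- c(
    sprintf("Species modeled: %d", summary$n_species),
    sprintf("Mean suitable area, current climate: %.0f km2", summary$mean_current_km2),
    sprintf("Mean suitable area, future climate:  %.0f km2", summary$mean_future_km2),
    sprintf("Aggregate change of the mean: %+.1f%%", summary$mean_change_pct),
    sprintf("Species declining: %d of %d (%.1f%%)", summary$n_declining,
            summary$n_species, 100 * summary$frac_declining),
    sprintf("Largest/smallest current area ratio: %.0f", summary$max_min_ratio))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
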