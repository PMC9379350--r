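#' Run the end-to-end virtual-species benchmark
#'
#' Exercises the whole pipeline against known truth: generates a synthetic
#' landscape, defines cool-niche virtual species (quadratic logistic response
#' in annual mean temperature with the optimum in the cold tail of the
#' available climate, plus optional secondary precipitation terms), samples
#' presence records, fits the full 63-run ensemble per species, projects onto
#' the current climate and onto a uniformly warmed future, and compares
#' estimated suitable areas, richness hotspots and declines against the truth.
#' The benchmark definition (landscape, niche shapes, warming shift, sample
#' sizes) lives in the versioned config file `extdata/benchmark.json`.
#'
#' Because temperature falls with elevation on the synthetic landscape, a
#' uniform warming pushes each cool niche uphill into scarcer terrain, so
#' suitable areas are expected to shrink for most species.
#'
#' @param seed single benchmark seed; all landscape, sampling and model
#'   randomness derives from it.
#' @param config path to a benchmark JSON config (default: the packaged one).
#' @param n_species optionally run only the first `n_species` configured
#'   species (all by default).
#' @param shape optionally override the configured landscape shape (smaller
#'   grids make quick checks cheaper; areas and truth scale with it).
#' @param n_pseudo_absences optionally override the configured count.
#' @return An object of class `benchmark_result`: `species` (per-species
#'   data.frame with ensemble TSS, true/estimated areas and decline flags),
#'   `ledgers` (per-species run ledgers), `hotspot_jaccard` (estimated vs true
#'   current hotspots), `frac_declining`, hotspot/extent areas per scenario,
#'   and the config used.
#' @export
synthetic_benchmark <- function(seed,
                                config = system.file("extdata", "benchmark.json",
                                                     package = "nichecast",
                                                     mustWork = TRUE),
                                n_species = NULL, shape = NULL,
                                n_pseudo_absences = NULL) {
  cfg <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.null(shape)) cfg$landscape$shape <- shape
  if (!is.null(n_pseudo_absences)) cfg$n_pseudo_absences <- n_pseudo_absences
  sp_cfg <- cfg$species
  if (!is.null(n_species)) sp_cfg <- sp_cfg[seq_len(n_species), , drop = FALSE]
  nsp <- nrow(sp_cfg)

  seeds <- derive_seeds(seed, 1 + 2 * nsp)
  land <- make_landscape(seeds[1], shape = cfg$landscape$shape,
                         variables = cfg$landscape$variables,
                         autocorr_range = cfg$landscape$autocorr_range)
  future <- shift_climate(land, scenario_shift(add = unlist(cfg$warming)))
  vars <- cfg$landscape$variables
  cur_stack <- stack_subset(land, vars)
  fut_stack <- stack_subset(future, vars)
  areas <- cell_area_km2(land$layers[[1]])

  bio1 <- land$layers$BIO1$values
  bio1_q <- function(p) stats::quantile(bio1, probs = p, na.rm = TRUE,
                                        names = FALSE)
  species_coefs <- function(row) {
    opt <- bio1_q(row$opt_quantile)
    s <- row$sharpness
    lin <- c(BIO1 = 2 * s * opt)
    quad <- c(BIO1 = -s)
    b0 <- cfg$niche_intercept - s * opt^2
    sec <- row$secondary
    if (is.data.frame(sec)) sec <- as.list(sec)
    sec <- Filter(Negate(is.na), unlist(sec))
    for (v in names(sec)) {
      xv <- land$layers[[v]]$values
      lin[v] <- sec[[v]] / stats::sd(xv, na.rm = TRUE)
      b0 <- b0 - lin[v] * mean(xv, na.rm = TRUE)
    }
    list(intercept = b0, linear = lin, quadratic = quad)
  }

  res <- vector("list", nsp)
  ledgers <- list()
  bins_cur <- list(); bins_fut <- list(); truth_cur <- list()
  for (i in seq_len(nsp)) {
    row <- sp_cfg[i, , drop = FALSE]
    coefs <- species_coefs(row)
    sp <- make_species(land, coefs, cutoff = cfg$suitability_cutoff,
                       species_id = row$id)
    sp_fut <- make_species(future, coefs, cutoff = cfg$suitability_cutoff,
                           species_id = row$id)
    occ <- sample_presences(sp, n = cfg$n_presences, seed = seeds[1 + i])
    ens <- fit_species_ensemble(occ, cur_stack,
                                n_pa = cfg$n_pseudo_absences,
                                buffer_km = cfg$buffer_km,
                                seed = seeds[1 + nsp + i])
    ledgers[[row$id]] <- ens$ledger
    if (ens$status != "ok") {
      res[[i]] <- data.frame(species = row$id, tss = NA_real_,
                             true_area_km2 = species_area(sp$true_binary, areas),
                             est_area_current_km2 = NA_real_,
                             est_area_future_km2 = NA_real_,
                             area_error_pct = NA_real_, declining = NA)
      next
    }
    pc <- predict_suitability(ens, cur_stack)
    pf <- predict_suitability(ens, fut_stack)
    bins_cur[[row$id]] <- pc$binary
    bins_fut[[row$id]] <- pf$binary
    truth_cur[[row$id]] <- sp$true_binary
    true_a <- species_area(sp$true_binary, areas)
    est_c <- species_area(pc, areas)
    est_f <- species_area(pf, areas)
    res[[i]] <- data.frame(
      species = row$id, tss = ens$ensemble_tss,
      true_area_km2 = true_a,
      true_area_future_km2 = species_area(sp_fut$true_binary, areas),
      est_area_current_km2 = est_c, est_area_future_km2 = est_f,
      area_error_pct = 100 * (est_c - true_a) / true_a,
      declining = est_f < est_c)
  }
  species_df <- do.call(rbind, res)

  out <- list(species = species_df, ledgers = ledgers, config = cfg,
              seed = seed)
  if (length(bins_cur) > 0) {
    rich_c <- stack_richness(bins_cur)
    rich_f <- stack_richness(bins_fut)
    hot_c <- hotspot_map(rich_c)
    hot_f <- hotspot_map(rich_f)
    hot_true <- hotspot_map(stack_richness(truth_cur))
    out$richness_current <- rich_c
    out$hotspot_current <- hot_c
    out$hotspot_future <- hot_f
    out$hotspot_true <- hot_true
    out$hotspot_jaccard <- mask_jaccard(hot_c, hot_true)
    out$hotspot_area_current_km2 <- species_area(hot_c, areas)
    out$hotspot_area_future_km2 <- species_area(hot_f, areas)
    out$extent_area_current_km2 <- species_area(extent_map(rich_c), areas)
    out$extent_area_future_km2 <- species_area(extent_map(rich_f), areas)
    out$frac_declining <- mean(species_df$declining, na.rm = TRUE)
  }
  structure(out, class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> seed %d: %d species\n", x$seed,
              nrow(x$species)))
  print(x$species, row.names = FALSE)
  if (!is.null(x$hotspot_jaccard))
    cat(sprintf("  hotspot Jaccard vs truth: %.3f; declining fraction %.2f\n",
                x$hotspot_jaccard, x$frac_declining))
  invisible(x)
}
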