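# Deterministic sub-seed derivation: one pipeline seed fans out to every
# stochastic step so whole runs are reproducible from a single integer.
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

# Distance (km) from each point in `a` (data.frame x/y or lon/lat) to the
# nearest point in `b`, honoring the grid CRS: great-circle on geographic
# grids, planar on projected ones.
nearest_distance_km <- function(ax, ay, bx, by, crs) {
  units <- crs_units(crs)
  if (units == "degree") {
    d <- geosphere::distm(cbind(ax, ay), cbind(bx, by),
                          fun = geosphere::distHaversine) / 1000
    apply(d, 1, min)
  } else {
    f <- if (units == "m") 1e-3 else 1
    vapply(seq_along(ax), function(i)
      min(sqrt((ax[i] - bx)^2 + (ay[i] - by)^2)) * f, numeric(1))
  }
}

#' Sample pseudo-absence points outside a presence buffer
#'
#' In the absence of true absence data, background points standing in for
#' absences are drawn uniformly at random, without replacement, from the valid
#' cells of the analysis grid that lie at least `buffer_km` from every
#' presence. Points are placed at cell centres, so they are unique per cell by
#' construction.
#'
#' @param presences an `occurrence_set` or a data.frame with `lon`, `lat`.
#' @param template `raster_grid`; nodata cells are ineligible.
#' @param n number of pseudo-absences (default 5000).
#' @param buffer_km exclusion radius around presences, km (default 10).
#'   Great-circle distance on geographic grids, planar on projected ones.
#' @param seed RNG seed; identical seeds give identical samples.
#' @return An object of class `pseudo_absence_set`: list with `points`
#'   (data.frame lon/lat), `n`, `buffer_km`, `seed`.
#' @export
sample_pseudo_absences <- function(presences, template, n = 5000,
                                   buffer_km = 10, seed) {
  if (inherits(presences, "occurrence_set")) presences <- presences$records
  cc <- cell_centers(template)
  valid <- !is.na(template$values[cbind(cc$row, cc$col)])
  cc <- cc[valid, , drop = FALSE]
  d <- nearest_distance_km(cc$x, cc$y, presences$lon, presences$lat,
                           template$crs)
  elig <- cc[d >= buffer_km, , drop = FALSE]
  if (nrow(elig) < n)
    stop(sprintf("only %d cells eligible for pseudo-absences (requested %d); lower n or buffer_km",
                 nrow(elig), n))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  pick <- elig[sample.int(nrow(elig), n), , drop = FALSE]
  structure(list(points = data.frame(lon = pick$x, lat = pick$y),
                 n = n, buffer_km = buffer_km, seed = seed),
            class = "pseudo_absence_set")
}

#' Stratified calibration/evaluation split
#'
#' Random split preserving the presence : pseudo-absence ratio; by default 70%
#' of each class calibrates the model and the held-out 30% evaluates it.
#'
#' @param points data.frame with 0/1 column `occ` plus feature columns.
#' @param train_frac calibration fraction (default 0.70).
#' @param seed RNG seed.
#' @return list with data.frames `train` and `test` (disjoint, union = input).
#' @export
split_calibration <- function(points, train_frac = 0.70, seed) {
  if (!"occ" %in% names(points)) stop("points must have an 'occ' column")
  y <- as.integer(points$occ)
  if (any(table(factor(y, levels = 0:1)) < 2))
    stop("each class needs at least 2 members to split")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  tr_idx <- integer(0)
  for (cls in c(0L, 1L)) {
    idx <- which(y == cls)
    k <- round(train_frac * length(idx))
    k <- min(max(k, 1L), length(idx) - 1L) # both sides non-empty per class
    tr_idx <- c(tr_idx, sample(idx, k))
  }
  list(train = points[sort(tr_idx), , drop = FALSE],
       test = points[-sort(tr_idx), , drop = FALSE])
}

# One fitted (or failed) ensemble member with its held-out evaluation.
model_run <- function(algorithm, pa_set_id, eval_run_id, learner = NULL,
                      tss_test = NA_real_, threshold = NA_real_,
                      test_data = NULL, status = "fitted", seed = NA_integer_) {
  structure(list(algorithm = algorithm, pa_set_id = pa_set_id,
                 eval_run_id = eval_run_id, learner = learner,
                 tss_test = tss_test, threshold = threshold,
                 test_data = test_data, status = status, seed = seed),
            class = "model_run")
}

#' Combine model runs into a TSS-weighted ensemble
#'
#' Runs with held-out TSS strictly above `tss_min` are admitted; each admitted
#' run receives weight proportional to its TSS (weights sum to 1). The
#' ensemble's binarization threshold is recomputed by [max_tss_threshold()] on
#' the ensemble's own predictions over the pooled held-out points of all
#' admitted runs, keeping the cutoff out-of-sample. If no run passes, the
#' species is flagged unmodelable and no map can be emitted.
#'
#' @param runs list of `model_run` objects (typically 63 per species).
#' @param tss_min admission threshold on held-out TSS (default 0.6, strict).
#' @return An object of class `species_ensemble`: members, weights, threshold,
#'   a 1-row-per-run `ledger` data.frame, and `status`
#'   (`"ok"`/`"unmodelable"`).
#' @export
build_ensemble <- function(runs, tss_min = 0.6) {
  if (length(runs) == 0) stop("no model runs supplied")
  ledger <- do.call(rbind, lapply(runs, function(r) data.frame(
    algorithm = r$algorithm, pa_set = r$pa_set_id, eval_run = r$eval_run_id,
    status = r$status, tss = r$tss_test, threshold = r$threshold,
    admitted = !is.na(r$tss_test) && r$status == "fitted" && r$tss_test > tss_min,
    weight = NA_real_)))
  adm <- which(ledger$admitted)
  if (length(adm) == 0) {
    warning(sprintf("no run exceeds TSS %.2f: species unmodelable", tss_min))
    return(structure(list(members = list(), weights = numeric(0),
                          threshold = NA_real_, ledger = ledger,
                          tss_min = tss_min, status = "unmodelable"),
                     class = "species_ensemble"))
  }
  w <- ledger$tss[adm] / sum(ledger$tss[adm])
  ledger$weight[adm] <- w
  members <- lapply(runs[adm], `[[`, "learner")

  pooled <- do.call(rbind, lapply(runs[adm], `[[`, "test_data"))
  feats <- pooled[, setdiff(names(pooled), "occ"), drop = FALSE]
  probs <- ensemble_probs(members, w, feats)
  th <- max_tss_threshold(probs, pooled$occ)

  structure(list(members = members, weights = w, threshold = th$threshold,
                 ensemble_tss = th$tss, ledger = ledger, tss_min = tss_min,
                 status = "ok"),
            class = "species_ensemble")
}

ensemble_probs <- function(members, weights, features) {
  p <- numeric(nrow(features))
  for (i in seq_along(members))
    p <- p + weights[i] * predict(members[[i]], features)
  p
}

#' @export
print.species_ensemble <- function(x, ...) {
  cat(sprintf("<species_ensemble> %d/%d runs admitted (TSS > %.2f), status %s\n",
              sum(x$ledger$admitted), nrow(x$ledger), x$tss_min, x$status))
  if (x$status == "ok")
    cat(sprintf("  ensemble threshold %.3f, pooled held-out TSS %.3f\n",
                x$threshold, x$ensemble_tss))
  invisible(x)
}

#' Fit the full per-species ensemble design
#'
#' Runs the complete single-species workflow: for each of `n_pa_sets`
#' pseudo-absence draws and each of `n_eval_runs` stratified 70/30 splits,
#' every algorithm is fitted on the calibration fraction and scored by TSS on
#' the held-out fraction — `7 x 3 x 3 = 63` model runs by default, all of
#' which appear in the ledger with status fitted or failed. Admitted runs
#' (TSS > `tss_min`) form a TSS-weighted ensemble via [build_ensemble()].
#'
#' @param occ_set cleaned `occurrence_set` (presences).
#' @param stack `climate_stack` of predictor layers (the calibration climate).
#' @param n_pa,buffer_km pseudo-absence count and exclusion buffer, see
#'   [sample_pseudo_absences()].
#' @param n_pa_sets,n_eval_runs design repetitions (default 3 and 3).
#' @param algorithms algorithms to run (default all seven).
#' @param tss_min ensemble admission threshold (default 0.6).
#' @param train_frac calibration fraction (default 0.70).
#' @param seed single pipeline seed; per-(pa_set, eval_run, algorithm) seeds
#'   are derived deterministically and recorded in the ledger.
#' @return a `species_ensemble` (see [build_ensemble()]) with the species id
#'   and feature names attached.
#' @export
fit_species_ensemble <- function(occ_set, stack, n_pa = 5000, buffer_km = 10,
                                 n_pa_sets = 3, n_eval_runs = 3,
                                 algorithms = sdm_algorithms, tss_min = 0.6,
                                 train_frac = 0.70, seed = 1) {
  pres <- occ_set$records
  pres_feat <- extract_features(stack, pres$lon, pres$lat)
  ok <- stats::complete.cases(pres_feat)
  if (!all(ok)) {
    warning(sprintf("%s: %d presences on nodata cells dropped",
                    occ_set$species_id, sum(!ok)))
    pres <- pres[ok, , drop = FALSE]
    pres_feat <- pres_feat[ok, , drop = FALSE]
  }
  if (nrow(pres) < 5) stop("too few presences with valid predictor values")

  n_alg <- length(algorithms)
  seeds <- derive_seeds(seed, n_pa_sets * (1 + n_eval_runs * (1 + n_alg)))
  si <- 0L
  next_seed <- function() { si <<- si + 1L; seeds[si] }

  runs <- list()
  for (pa_id in seq_len(n_pa_sets)) {
    pa <- sample_pseudo_absences(pres, stack$layers[[1]], n = n_pa,
                                 buffer_km = buffer_km, seed = next_seed())
    pa_feat <- extract_features(stack, pa$points$lon, pa$points$lat)
    tab <- rbind(cbind(occ = 1L, pres_feat), cbind(occ = 0L, pa_feat))
    tab <- tab[stats::complete.cases(tab), , drop = FALSE]
    for (run_id in seq_len(n_eval_runs)) {
      sp <- split_calibration(tab, train_frac = train_frac, seed = next_seed())
      for (alg in algorithms) {
        fit_seed <- next_seed()
        run <- tryCatch({
          set.seed(fit_seed)
          lrn <- fit_learner(alg, sp$train)
          p <- predict(lrn, sp$test)
          th <- max_tss_threshold(p, sp$test$occ)
          model_run(alg, pa_id, run_id, learner = lrn, tss_test = th$tss,
                    threshold = th$threshold, test_data = sp$test,
                    seed = fit_seed)
        }, error = function(e)
          model_run(alg, pa_id, run_id, status = paste("failed:",
                                                       conditionMessage(e)),
                    seed = fit_seed))
        runs[[length(runs) + 1]] <- run
      }
    }
  }
  ens <- build_ensemble(runs, tss_min = tss_min)
  ens$species_id <- occ_set$species_id
  ens$features <- names(stack$layers)
  ens$seed <- seed
  ens
}

#' Project a species ensemble onto a climate scenario
#'
#' Computes the weighted-mean continuous suitability over every cell valid in
#' all stack layers, and the binary suitable/unsuitable map obtained by
#' cutting the continuous map at the ensemble's max-TSS threshold. The
#' threshold was fixed on held-out current-climate data and is reused
#' unchanged for future projections (a future scenario has no observations to
#' re-threshold on).
#'
#' @param ens a `species_ensemble` with status `"ok"`.
#' @param stack `climate_stack` with exactly the training variables; its
#'   `scenario_tag` labels the output.
#' @return An object of class `ensemble_prediction`: `continuous` and `binary`
#'   `raster_grid`s, `threshold`, `species_id`, `scenario_tag`.
#' @export
predict_suitability <- function(ens, stack) {
  if (ens$status != "ok") stop("species is unmodelable: no map can be emitted")
  if (!setequal(names(stack$layers), ens$features))
    stop("stack variables do not match the ensemble's training variables")
  sv <- stack_values(stack)
  feats <- as.data.frame(sv$values)[, ens$features, drop = FALSE]
  p <- ensemble_probs(ens$members, ens$weights, feats)

  tmpl <- stack$layers[[1]]
  cont <- tmpl
  cont$values <- matrix(NA_real_, nrow(tmpl$values), ncol(tmpl$values))
  cont$values[sv$index] <- p
  bin <- cont
  bin$values[sv$index] <- as.numeric(p >= ens$threshold)

  structure(list(species_id = ens$species_id, continuous = cont, binary = bin,
                 threshold = ens$threshold, scenario_tag = stack$scenario_tag),
            class = "ensemble_prediction")
}

#' @export
print.ensemble_prediction <- function(x, ...) {
  cat(sprintf("<ensemble_prediction> '%s' (%s): threshold %.3f, %d suitable cells\n",
              x$species_id, x$scenario_tag, x$threshold,
              sum(x$binary$values == 1, na.rm = TRUE)))
  invisible(x)
}
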