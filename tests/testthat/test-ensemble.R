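# A few real GLM-backed model runs for ensemble assembly tests.
make_run <- function(tss, pa = 1, run = 1, seed = 1, status = "fitted") {
  train <- separable_table(n = 30, seed = seed)
  test <- separable_table(n = 15, seed = seed + 100)
  lrn <- fit_learner("GLM", train)
  th <- max_tss_threshold(predict(lrn, test), test$occ)
  model_run("GLM", pa, run, learner = lrn, tss_test = tss,
            threshold = th$threshold, test_data = test, status = status)
}

test_that("pseudo-absences respect the buffer, land on valid cells and are unique", {
  tmpl <- test_grid(matrix(0, 40, 40)) # projected-km, 1 km cells
  tmpl$values[1:5, 1:5] <- NA
  pres <- data.frame(lon = c(20.5, 30.5), lat = c(20.5, 10.5))
  pa <- sample_pseudo_absences(pres, tmpl, n = 300, buffer_km = 6, seed = 42)
  expect_equal(nrow(pa$points), 300L)
  expect_equal(anyDuplicated(pa$points), 0L)
  # brute-force distance oracle: planar distance to both presences
  dmin <- sapply(seq_len(300), function(i)
    min(sqrt((pa$points$lon[i] - pres$lon)^2 + (pa$points$lat[i] - pres$lat)^2)))
  expect_true(all(dmin >= 6))
  # all points are centres of valid cells
  cell <- xy_to_cell(tmpl, pa$points$lon, pa$points$lat)
  expect_true(all(!is.na(tmpl$values[cbind(cell$row, cell$col)])))
})

test_that("pseudo-absence sampling is seed-deterministic", {
  tmpl <- test_grid(matrix(0, 30, 30))
  pres <- data.frame(lon = 15.5, lat = 15.5)
  a <- sample_pseudo_absences(pres, tmpl, n = 100, buffer_km = 3, seed = 7)
  b <- sample_pseudo_absences(pres, tmpl, n = 100, buffer_km = 3, seed = 7)
  d <- sample_pseudo_absences(pres, tmpl, n = 100, buffer_km = 3, seed = 8)
  expect_identical(a$points, b$points)
  expect_false(identical(a$points, d$points))
})

test_that("infeasible pseudo-absence requests report the eligible count", {
  tmpl <- test_grid(matrix(0, 10, 10))
  pres <- data.frame(lon = 5.5, lat = 5.5)
  expect_error(sample_pseudo_absences(pres, tmpl, n = 5000, buffer_km = 2,
                                      seed = 1),
               "eligible.*5000")
})

test_that("geographic buffers use great-circle distance", {
  # 0.1 degree cells near 28 N: ~11.1 km N-S, ~9.8 km E-W
  tmpl <- raster_grid(matrix(0, 20, 20), xmin = 84, ymax = 29, xres = 0.1,
                      crs = "geographic")
  pres <- data.frame(lon = 85.05, lat = 28.05)
  pa <- sample_pseudo_absences(pres, tmpl, n = 50, buffer_km = 30, seed = 3)
  d <- geosphere::distHaversine(cbind(pa$points$lon, pa$points$lat),
                                c(85.05, 28.05)) / 1000
  expect_true(all(d >= 30))
})

test_that("calibration split is stratified 70/30 and deterministic", {
  pts <- data.frame(occ = rep(c(1L, 0L), c(100, 100)), f1 = rnorm(200))
  sp <- split_calibration(pts, seed = 5)
  expect_equal(sum(sp$train$occ == 1), 70L)
  expect_equal(sum(sp$train$occ == 0), 70L)
  expect_equal(sum(sp$test$occ == 1), 30L)
  expect_equal(sum(sp$test$occ == 0), 30L)
  # disjoint and exhaustive
  expect_equal(sort(c(rownames(sp$train), rownames(sp$test))),
               sort(rownames(pts)))
  sp2 <- split_calibration(pts, seed = 5)
  expect_identical(sp$train, sp2$train)

  # odd class sizes: per-class train count within rounding of the fraction
  pts2 <- data.frame(occ = rep(c(1L, 0L), c(37, 113)), f1 = rnorm(150))
  sp3 <- split_calibration(pts2, seed = 1)
  expect_equal(sum(sp3$train$occ == 1), round(0.7 * 37))
  expect_equal(sum(sp3$train$occ == 0), round(0.7 * 113))
  expect_error(split_calibration(data.frame(occ = c(1, 1, 0), f = 1:3),
                                 seed = 1), "at least 2")
})

test_that("a single admitted run yields weight 1 and that run's behavior", {
  runs <- list(make_run(0.85, seed = 2), make_run(0.55, seed = 3))
  ens <- build_ensemble(runs, tss_min = 0.6)
  expect_equal(ens$status, "ok")
  expect_equal(ens$weights, 1)
  expect_length(ens$members, 1)
  # ensemble probabilities equal the admitted member's own predictions
  feats <- runs[[1]]$test_data[, c("f1", "f2")]
  expect_equal(unname(ensemble_probs(ens$members, ens$weights, feats)),
               unname(predict(runs[[1]]$learner, feats)))
})

test_that("admission is strict and weights are TSS-proportional", {
  tss <- c(0.9, 0.61, 0.75, 0.4, 0.6) # 0.6 itself is NOT admitted (strict >)
  runs <- Map(function(t, i) make_run(t, pa = i, seed = i), tss, 1:5)
  ens <- build_ensemble(runs, tss_min = 0.6)
  expect_equal(sum(ens$ledger$admitted), 3L)
  expect_false(ens$ledger$admitted[5])
  keep <- c(0.9, 0.61, 0.75)
  expect_equal(ens$weights, keep / sum(keep))
  expect_equal(sum(ens$weights), 1)
  expect_equal(ens$ledger$weight[ens$ledger$admitted], ens$weights)
  expect_true(all(is.na(ens$ledger$weight[!ens$ledger$admitted])))
})

test_that("failed runs stay in the ledger and are never admitted", {
  runs <- list(make_run(0.9, seed = 1),
               model_run("ANN", 1, 2, status = "failed: did not converge"))
  ens <- build_ensemble(runs)
  expect_equal(nrow(ens$ledger), 2L)
  expect_equal(ens$ledger$status[2], "failed: did not converge")
  expect_false(ens$ledger$admitted[2])
})

test_that("a species with no admitted run is flagged unmodelable", {
  runs <- list(make_run(0.3, seed = 1), make_run(0.5, seed = 2))
  expect_warning(ens <- build_ensemble(runs), "unmodelable")
  expect_equal(ens$status, "unmodelable")
  expect_true(is.na(ens$threshold))
  st <- test_stack(n = 2, names_ = c("f1", "f2"))
  ens$features <- c("f1", "f2")
  expect_error(predict_suitability(ens, st), "unmodelable")
})

test_that("the full per-species design produces a complete ledger and maps", {
  sg <- make_landscape(seed = 5, shape = c(30, 30), autocorr_range = 6)
  vsp <- make_species(sg, list(intercept = 3, linear = c(BIO1 = 1.2),
                               quadratic = c(BIO1 = -0.15)))
  occ <- sample_presences(vsp, n = 80, seed = 11)
  algs <- c("GLM", "CTA")
  ens <- fit_species_ensemble(occ, sg, n_pa = 150, buffer_km = 2,
                              algorithms = algs, seed = 9)
  # every (algorithm, pa_set, eval_run) combination appears exactly once
  expect_equal(nrow(ens$ledger), length(algs) * 3 * 3)
  combos <- with(ens$ledger, paste(algorithm, pa_set, eval_run))
  expect_equal(anyDuplicated(combos), 0L)
  expect_true(all(ens$ledger$status == "fitted" |
                    startsWith(ens$ledger$status, "failed")))
  expect_equal(ens$status, "ok")
  expect_equal(sum(ens$weights), 1)

  # determinism of the whole pipeline from one seed
  ens2 <- fit_species_ensemble(occ, sg, n_pa = 150, buffer_km = 2,
                               algorithms = algs, seed = 9)
  expect_identical(ens$ledger, ens2$ledger)
  expect_equal(ens$threshold, ens2$threshold)

  pred <- predict_suitability(ens, sg)
  expect_s3_class(pred, "ensemble_prediction")
  expect_true(all(pred$continuous$values >= 0 & pred$continuous$values <= 1,
                  na.rm = TRUE))
  expect_setequal(unique(stats::na.omit(c(pred$binary$values))), c(0, 1))
  expect_equal(pred$scenario_tag, "current")
  # binary is exactly the continuous map cut at the stored threshold
  expect_equal(pred$binary$values,
               ifelse(is.na(pred$continuous$values), NA_real_,
                      as.numeric(pred$continuous$values >= pred$threshold)))

  # mismatched projection variables are refused
  bad <- stack_subset(sg, c("BIO1", "BIO2"))
  expect_error(predict_suitability(ens, bad), "variables")
})

test_that("binary suitable area is non-increasing in the threshold", {
  sg <- make_landscape(seed = 6, shape = c(25, 25), autocorr_range = 5)
  vsp <- make_species(sg, list(intercept = 2, linear = c(BIO1 = 1),
                               quadratic = c(BIO1 = -0.1)))
  occ <- sample_presences(vsp, n = 60, seed = 2)
  ens <- fit_species_ensemble(occ, sg, n_pa = 120, buffer_km = 2,
                              algorithms = "GLM", seed = 4)
  areas <- cell_area_km2(sg$layers[[1]])
  a <- sapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(th) {
    e <- ens; e$threshold <- th
    species_area(predict_suitability(e, sg), areas)
  })
  expect_true(all(diff(a) <= 0))
})

test_that("derived sub-seeds are deterministic and leave the RNG untouched", {
  s1 <- derive_seeds(99, 10)
  s2 <- derive_seeds(99, 10)
  expect_identical(s1, s2)
  expect_equal(anyDuplicated(s1), 0L)
  set.seed(1); before <- .Random.seed
  invisible(derive_seeds(5, 3))
  expect_identical(.Random.seed, before)
})
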