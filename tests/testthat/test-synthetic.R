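test_that("landscapes are bit-identical per seed and differ across seeds", {
  a <- make_landscape(seed = 3, shape = c(30, 30))
  b <- make_landscape(seed = 3, shape = c(30, 30))
  d <- make_landscape(seed = 4, shape = c(30, 30))
  expect_identical(a, b)
  expect_false(identical(a$layers$BIO1$values, d$layers$BIO1$values))
  expect_setequal(names(a$layers), c(bioclim_retained_default, "elev"))
  expect_equal(dim(a$layers$BIO14$values), c(30, 30))
  expect_identical(a$layers$elev$crs, "projected-km")
  expect_true(all(a$layers$BIO14$values >= 0)) # precipitation non-negative
  expect_error(make_landscape(1, shape = c(10, 30)), "at least 20")
})

test_that("random fields are standardized and autocorrelated at the set range", {
  set.seed(14)
  f <- gaussian_random_field(80, 80, range = 8)
  expect_equal(mean(f), 0, tolerance = 1e-12)
  expect_equal(sd(f), 1, tolerance = 1e-12)
  # lag-1 correlation along rows is high at range 8
  expect_gt(cor(c(f[-80, ]), c(f[-1, ])), 0.9)

  # at range 1, correlation beyond lag 5 is near zero across seeds
  lag5 <- sapply(1:10, function(s) {
    set.seed(200 + s)
    g <- gaussian_random_field(60, 60, range = 1)
    cor(c(g[1:55, ]), c(g[6:60, ]))
  })
  expect_lt(mean(abs(lag5)), 0.1)
  expect_error(gaussian_random_field(10, 10, range = 10), "smaller")
})

test_that("temperature tracks elevation: uphill is cooler", {
  sg <- make_landscape(seed = 8, shape = c(40, 40))
  r <- cor(c(sg$layers$elev$values), c(sg$layers$BIO1$values))
  expect_lt(r, -0.8)
  # lapse slope close to -6.5 degC per km
  fit <- lm(c(sg$layers$BIO1$values) ~ c(sg$layers$elev$values / 1000))
  expect_equal(unname(coef(fit)[2]), -6.5, tolerance = 0.5)
})

test_that("non-temperature variables are generated independently", {
  # with unsmoothed fields the empirical cross-correlations are tiny ...
  sg <- make_landscape(seed = 9, shape = c(60, 60), autocorr_range = 0)
  others <- setdiff(bioclim_retained_default, "BIO1")
  v <- sapply(sg$layers[others], function(g) c(g$values))
  cm <- cor(v)
  expect_true(all(abs(cm[upper.tri(cm)]) < 0.1))
  # ... and at the default (smooth) range they are zero in expectation: a
  # single smooth realization can correlate strongly, but not systematically
  r_pair <- sapply(1:10, function(s) {
    sg <- make_landscape(seed = 300 + s, shape = c(40, 40))
    cor(c(sg$layers$BIO2$values), c(sg$layers$BIO14$values))
  })
  expect_lt(abs(mean(r_pair)), 0.25)
})

test_that("virtual-species suitability follows the stated logistic form", {
  sg <- make_landscape(seed = 10, shape = c(25, 25))
  co <- list(intercept = 0.5, linear = c(BIO1 = 0.3, BIO14 = -0.1),
             quadratic = c(BIO1 = -0.02))
  vsp <- make_species(sg, co, cutoff = 0.5, species_id = "v")
  # oracle at an arbitrary cell
  i <- 7; j <- 13
  x1 <- sg$layers$BIO1$values[i, j]; x14 <- sg$layers$BIO14$values[i, j]
  expect_equal(vsp$suitability$values[i, j],
               plogis(0.5 + 0.3 * x1 - 0.1 * x14 - 0.02 * x1^2))
  expect_equal(vsp$true_binary$values[i, j],
               as.numeric(vsp$suitability$values[i, j] >= 0.5))

  # intercept-only species is uniformly plogis(intercept)
  flat <- make_species(sg, list(intercept = 1), cutoff = 0.5)
  expect_true(all(flat$suitability$values == plogis(1)))

  expect_error(make_species(sg, list(intercept = -50,
                                     linear = c(BIO1 = 0.001))),
               "cutoff")
  expect_error(make_species(sg, list(intercept = 0, linear = c(NOPE = 1))),
               "not in stack")
})

test_that("presence sampling concentrates where suitability is high", {
  sg <- make_landscape(seed = 12, shape = c(40, 40))
  vsp <- make_species(sg, list(intercept = 2, linear = c(BIO1 = 1),
                               quadratic = c(BIO1 = -0.12)))
  occ <- sample_presences(vsp, n = 400, seed = 6)
  expect_lte(nrow(occ$records), 400)     # thinned to unique cells
  expect_equal(attr(occ, "n_drawn"), 400)
  expect_equal(anyDuplicated(occ$records[, c("lon", "lat")]), 0L)
  # suitability at sampled cells beats the landscape average decisively
  s_occ <- extract_features(climate_stack(list(
    s = vsp$suitability)), occ$records$lon, occ$records$lat)$s
  expect_gt(mean(s_occ), mean(vsp$suitability$values) + 0.2)
  # records carry elevations from the elevation layer
  expect_true(all(is.finite(occ$records$elev_m)))

  # determinism and seed sensitivity
  occ2 <- sample_presences(vsp, n = 400, seed = 6)
  expect_identical(occ$records, occ2$records)
  occ3 <- sample_presences(vsp, n = 400, seed = 7)
  expect_false(identical(occ$records, occ3$records))
})

test_that("sampling bias shifts records toward accessible areas", {
  sg <- make_landscape(seed = 13, shape = c(40, 40))
  flat <- make_species(sg, list(intercept = 1)) # uniform suitability
  bias <- sg$layers[[1]]
  bias$values[] <- 0.05
  bias$values[1:20, 1:20] <- 1 # top-left quadrant 20x more accessible
  occ <- sample_presences(flat, n = 300, bias = bias, seed = 3)
  inq <- mean(occ$records$lon < 20 & occ$records$lat > 20)
  expect_gte(inq, 0.7)
  zero <- bias; zero$values[] <- 0
  expect_error(sample_presences(flat, n = 10, bias = zero, seed = 1), "zero")
})

test_that("realistic occurrence counts are supported end to end", {
  sg <- make_landscape(seed = 15, shape = c(40, 40))
  vsp <- make_species(sg, list(intercept = 3, linear = c(BIO1 = 1),
                               quadratic = c(BIO1 = -0.15)))
  for (n in c(21, 103)) { # smallest and largest published per-species counts
    occ <- sample_presences(vsp, n = n, seed = n)
    expect_lte(nrow(occ$records), n)
    expect_gte(nrow(occ$records), 5)
  }
})

test_that("scenario shifts apply exactly and identity leaves the stack alone", {
  sg <- make_landscape(seed = 16, shape = c(25, 25))
  ident <- shift_climate(sg, scenario_shift(), scenario_tag = "future")
  expect_equal(ident$layers, sg$layers)
  expect_equal(ident$scenario_tag, "future")

  warm <- shift_climate(sg, scenario_shift(add = c(BIO1 = 2)))
  expect_equal(warm$layers$BIO1$values, sg$layers$BIO1$values + 2)
  expect_equal(warm$layers$BIO14$values, sg$layers$BIO14$values)

  dry <- shift_climate(sg, scenario_shift(mul = c(BIO14 = 0.8)))
  expect_equal(dry$layers$BIO14$values, sg$layers$BIO14$values * 0.8)

  expect_error(shift_climate(sg, scenario_shift(add = c(BIO99 = 1))),
               "unknown")
})

test_that("warming shrinks the true range of a cool-adapted species", {
  sg <- make_landscape(seed = 17, shape = c(40, 40))
  # optimum at a cold BIO1 value (low quantile)
  opt <- unname(quantile(sg$layers$BIO1$values, 0.1, names = FALSE))
  co <- list(intercept = 4 - 0.5 * opt^2,
             linear = c(BIO1 = 1 * opt), quadratic = c(BIO1 = -0.5))
  cur <- make_species(sg, co)
  fut <- make_species(shift_climate(sg, scenario_shift(add = c(BIO1 = 2))), co)
  a <- cell_area_km2(sg$layers$BIO1)
  expect_lt(species_area(fut$true_binary, a),
            species_area(cur$true_binary, a))
})

test_that("mask Jaccard behaves at the boundary cases", {
  a <- test_grid(matrix(c(1, 1, 0, 0), 2, 2))
  b <- test_grid(matrix(c(1, 0, 1, 0), 2, 2))
  expect_equal(mask_jaccard(a, a), 1)
  expect_equal(mask_jaccard(a, b), 1 / 3)
  z <- test_grid(matrix(0, 2, 2))
  expect_equal(mask_jaccard(z, z), 1) # both empty
  expect_equal(mask_jaccard(a, z), 0)
})
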