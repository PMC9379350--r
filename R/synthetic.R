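#' Gaussian random field on a grid
#'
#' Stationary, zero-mean, unit-variance random field with (approximately)
#' Gaussian autocorrelation, synthesized by circular FFT convolution of white
#' noise with a Gaussian kernel of standard deviation `range` cells. Draws
#' from the current R RNG stream; seed before calling for reproducibility.
#'
#' @param nrow,ncol grid dimensions.
#' @param range autocorrelation range in cells (kernel sd); must be smaller
#'   than the grid.
#' @return numeric matrix `nrow x ncol`.
#' @export
gaussian_random_field <- function(nrow, ncol, range) {
  if (range >= min(nrow, ncol)) stop("autocorr range must be smaller than the grid")
  w <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  if (range <= 0) return(w)
  di <- pmin(seq_len(nrow) - 1L, nrow - (seq_len(nrow) - 1L))
  dj <- pmin(seq_len(ncol) - 1L, ncol - (seq_len(ncol) - 1L))
  d2 <- outer(di^2, dj^2, `+`)
  k <- exp(-d2 / (2 * range^2))
  f <- Re(stats::fft(stats::fft(w) * stats::fft(k), inverse = TRUE)) / (nrow * ncol)
  (f - mean(f)) / stats::sd(f)
}

#' Generate a synthetic climate landscape
#'
#' Builds a stack of spatially autocorrelated bioclimatic layers plus an
#' elevation layer (`elev`) on a projected 1-km grid, so cell areas are exact
#' km². Temperature (BIO1) follows elevation through a 6.5 °C/km lapse rate
#' plus local noise — uphill is cooler — while the remaining variables are
#' independent random fields on field-realistic scales (°C for temperature
#' variables, mm for precipitation). Deterministic per seed.
#'
#' @param seed RNG seed.
#' @param shape `c(rows, cols)`, at least 20 x 20.
#' @param variables bioclimatic variable codes to generate (default: the seven
#'   retained predictors, [bioclim_retained_default]).
#' @param autocorr_range spatial autocorrelation range in cells (default 10).
#' @return a `climate_stack` tagged `"current"` containing `variables` plus
#'   `elev`.
#' @export
make_landscape <- function(seed, shape = c(100, 100),
                           variables = bioclim_retained_default,
                           autocorr_range = 10) {
  if (any(shape < 20)) stop("shape must be at least 20 x 20")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  nr <- shape[1]; nc <- shape[2]
  grf <- function() gaussian_random_field(nr, nc, autocorr_range)
  as_grid <- function(m) raster_grid(m, xmin = 0, ymax = nr, xres = 1,
                                     crs = "projected-km")
  elev <- pmax(3000 + 1500 * grf(), 0)
  scale_var <- function(v) switch(v,
    BIO1 = 30 - 6.5 * elev / 1000 + 1.5 * grf(),
    BIO2 = 12 + 2 * grf(),
    BIO3 = 45 + 5 * grf(),
    BIO7 = 30 + 4 * grf(),
    BIO14 = pmax(8 + 6 * grf(), 0),
    BIO18 = pmax(600 + 200 * grf(), 0),
    BIO19 = pmax(60 + 40 * grf(), 0),
    grf())
  layers <- lapply(variables, function(v) as_grid(scale_var(v)))
  names(layers) <- variables
  layers$elev <- as_grid(elev)
  climate_stack(layers, scenario_tag = "current")
}

#' Subset the layers of a climate stack
#'
#' @param stack a `climate_stack`.
#' @param variables layer names to keep.
#' @return a `climate_stack` with only those layers.
#' @export
stack_subset <- function(stack, variables) {
  miss <- setdiff(variables, names(stack$layers))
  if (length(miss) > 0)
    stop(sprintf("stack lacks variable(s): %s", paste(miss, collapse = ", ")))
  climate_stack(stack$layers[variables], scenario_tag = stack$scenario_tag)
}

#' Create a virtual species with a known logistic niche
#'
#' True suitability at each cell is `plogis(lp)` with
#' `lp = intercept + sum(linear * x) + sum(quadratic * x^2)` over the named
#' predictors; the true range is `suitability >= cutoff`. Knowing truth lets
#' every downstream stage be validated by recovery rather than plausibility.
#'
#' @param stack `climate_stack` holding the named predictors (and usually an
#'   `elev` layer, carried along so sampled presences get elevations).
#' @param coefficients list with `intercept` (scalar), `linear` (named numeric
#'   vector) and optional `quadratic` (named numeric vector).
#' @param cutoff suitability cutoff defining the true binary range
#'   (default 0.5).
#' @param species_id identifier (default `"virtual"`).
#' @return An object of class `virtual_species`: `suitability` and
#'   `true_binary` `raster_grid`s, the coefficients, cutoff and (if present)
#'   the elevation layer.
#' @export
make_species <- function(stack, coefficients, cutoff = 0.5,
                         species_id = "virtual") {
  lin <- coefficients$linear %||% numeric(0)
  quad <- coefficients$quadratic %||% numeric(0)
  vars <- union(names(lin), names(quad))
  miss <- setdiff(vars, names(stack$layers))
  if (length(miss) > 0)
    stop(sprintf("coefficient variable(s) not in stack: %s",
                 paste(miss, collapse = ", ")))
  sv <- stack_values(stack)
  lp <- rep(coefficients$intercept %||% 0, length(sv$index))
  for (v in names(lin)) lp <- lp + lin[[v]] * sv$values[, v]
  for (v in names(quad)) lp <- lp + quad[[v]] * sv$values[, v]^2
  suit <- stats::plogis(lp)

  tmpl <- stack$layers[[1]]
  sg <- tmpl
  sg$values <- matrix(NA_real_, nrow(tmpl$values), ncol(tmpl$values))
  sg$values[sv$index] <- suit
  if (!any(suit >= cutoff))
    stop("no cell reaches the suitability cutoff: strengthen the coefficients or lower the cutoff")
  bg <- sg
  bg$values[sv$index] <- as.numeric(suit >= cutoff)

  structure(list(species_id = species_id, suitability = sg, true_binary = bg,
                 coefficients = coefficients, cutoff = cutoff,
                 elevation = stack$layers[["elev"]]),
            class = "virtual_species")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample biased presence-only records from a virtual species
#'
#' Cells are drawn with replacement with probability proportional to
#' `true suitability x bias` (uniform bias when none is given), emulating the
#' uneven survey effort of real occurrence data; records are placed at cell
#' centres and then collapsed to one per cell, mirroring the spatial thinning
#' applied to real data. Each record carries the elevation-layer value at its
#' cell.
#'
#' @param species a `virtual_species`.
#' @param n number of draws before thinning.
#' @param bias optional accessibility `raster_grid` (non-negative weights, not
#'   all zero).
#' @param seed RNG seed.
#' @return an `occurrence_set` whose reported elevation range is the observed
#'   record range; attribute `"n_drawn"` records `n`.
#' @export
sample_presences <- function(species, n, bias = NULL, seed) {
  sg <- species$suitability
  valid <- which(!is.na(sg$values))
  w <- sg$values[valid]
  if (!is.null(bias)) {
    check_aligned(sg, bias, what = "suitability and bias layers")
    b <- bias$values[valid]
    if (any(b < 0, na.rm = TRUE)) stop("bias weights must be non-negative")
    w <- w * ifelse(is.na(b), 0, b)
  }
  if (all(w <= 0)) stop("all sampling weights are zero (all-zero bias?)")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cells <- sample(valid, n, replace = TRUE, prob = w)
  cells <- unique(cells)
  nr <- nrow(sg$values)
  row <- (cells - 1L) %% nr + 1L
  col <- (cells - 1L) %/% nr + 1L
  x <- sg$xmin + (col - 0.5) * sg$xres
  y <- sg$ymax - (row - 0.5) * sg$yres
  ev <- if (!is.null(species$elevation))
    species$elevation$values[cbind(row, col)] else rep(NA_real_, length(cells))
  rec <- data.frame(species = species$species_id, lon = x, lat = y,
                    elev_m = ev, source = "synthetic")
  out <- occurrence_set(species$species_id, rec,
                        elev_min_m = suppressWarnings(min(ev, na.rm = TRUE)),
                        elev_max_m = suppressWarnings(max(ev, na.rm = TRUE)),
                        crs = sg$crs)
  attr(out, "n_drawn") <- n
  out
}

#' Define a climate scenario shift
#'
#' A per-variable affine change (`new = mul * old + add`) applied uniformly
#' across the grid, turning a current stack into a synthetic future one (e.g.
#' `add = c(BIO1 = 2)` for 2 °C of warming).
#'
#' @param add named numeric vector of additive offsets (default none).
#' @param mul named numeric vector of multiplicative factors (default none).
#' @return An object of class `scenario_shift`.
#' @export
scenario_shift <- function(add = numeric(0), mul = numeric(0)) {
  structure(list(add = add, mul = mul), class = "scenario_shift")
}

#' Apply a scenario shift to a climate stack
#'
#' @param stack a `climate_stack`.
#' @param shift a [scenario_shift()]. All shifted variables must exist in the
#'   stack.
#' @param scenario_tag tag for the result (default `"future"`).
#' @return the shifted `climate_stack`.
#' @export
shift_climate <- function(stack, shift, scenario_tag = "future") {
  vars <- union(names(shift$add), names(shift$mul))
  miss <- setdiff(vars, names(stack$layers))
  if (length(miss) > 0)
    stop(sprintf("shift names unknown variable(s): %s", paste(miss, collapse = ", ")))
  layers <- stack$layers
  for (v in names(shift$mul))
    layers[[v]]$values <- layers[[v]]$values * shift$mul[[v]]
  for (v in names(shift$add))
    layers[[v]]$values <- layers[[v]]$values + shift$add[[v]]
  climate_stack(layers, scenario_tag = scenario_tag)
}

#' Jaccard similarity of two binary masks
#'
#' @param a,b aligned binary `raster_grid`s (or `hotspot_map`s).
#' @return `|a & b| / |a | b|` over valid cells (1 when both are empty).
#' @export
mask_jaccard <- function(a, b) {
  a <- as_mask_grid(a); b <- as_mask_grid(b)
  check_aligned(a, b, what = "masks")
  av <- !is.na(a$values) & a$values == 1
  bv <- !is.na(b$values) & b$values == 1
  un <- sum(av | bv)
  if (un == 0) return(1)
  sum(av & bv) / un
}
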