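# Small grid/stack constructors shared across test files.

test_grid <- function(values, crs = "projected-km", xres = 1,
                      xmin = 0, ymax = nrow(as.matrix(values))) {
  raster_grid(as.matrix(values), xmin = xmin, ymax = ymax, xres = xres,
              crs = crs)
}

# n layers of iid noise on an r x c projected-km grid.
test_stack <- function(n = 3, r = 10, c = 10, seed = 1, tag = "current",
                       names_ = paste0("V", seq_len(n))) {
  set.seed(seed)
  layers <- lapply(seq_len(n), function(i) test_grid(matrix(rnorm(r * c), r, c)))
  names(layers) <- names_
  climate_stack(layers, scenario_tag = tag)
}

# Labeled presence/absence table with two informative features.
separable_table <- function(n = 50, gap = 2, seed = 1) {
  set.seed(seed)
  data.frame(occ = rep(c(1L, 0L), each = n),
             f1 = c(rnorm(n, gap), rnorm(n, -gap)),
             f2 = c(rnorm(n, -gap), rnorm(n, gap)))
}
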