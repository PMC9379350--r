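#' Bioclimatic variables retained after collinearity pruning
#'
#' The default predictor set used throughout: annual mean temperature (BIO1),
#' mean diurnal range (BIO2), isothermality (BIO3), temperature annual range
#' (BIO7), precipitation of driest month (BIO14), precipitation of warmest
#' quarter (BIO18) and precipitation of coldest quarter (BIO19). Shipped as an
#' explicit, overridable list so the downstream pipeline does not depend on
#' re-running the pruning.
#'
#' @export
bioclim_retained_default <- c("BIO1", "BIO2", "BIO3", "BIO7", "BIO14", "BIO18", "BIO19")

#' Prune collinear predictor layers by pairwise Pearson correlation
#'
#' Greedy priority-ordered elimination: variables are visited in `priority`
#' order; a variable is removed when its absolute Pearson correlation with any
#' already-retained variable exceeds `r_threshold`. Correlations are computed
#' over cells valid in every layer (grid-wide, not at presence points).
#' Negative correlation counts: a pair at r = -0.9 is just as collinear as one
#' at +0.9, so the test is on `|r|`.
#'
#' @param stack a `climate_stack` with at least two layers.
#' @param r_threshold removal threshold on `|r|` (default 0.70).
#' @param priority character vector ordering the variables (first = kept
#'   preferentially). Defaults to the stack's layer order.
#' @return An object of class `correlation_report`: list with `pairs` (all
#'   pairwise r), `retained` (variable codes) and `removed` (data.frame of
#'   variable, culprit, r).
#' @export
correlation_filter <- function(stack, r_threshold = 0.70,
                               priority = names(stack$layers)) {
  vars <- names(stack$layers)
  if (length(vars) < 2) stop("correlation_filter: need at least two layers")
  if (!setequal(priority, vars))
    stop("priority must be a permutation of the stack's variable names")
  sv <- stack_values(stack)$values
  sds <- apply(sv, 2, stats::sd)
  if (any(sds == 0 | is.na(sds)))
    stop(sprintf("constant layer(s) with undefined correlation: %s",
                 paste(vars[sds == 0 | is.na(sds)], collapse = ", ")))
  cm <- stats::cor(sv)
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  pairs <- data.frame(var_a = vars[ut[, 1]], var_b = vars[ut[, 2]],
                      pearson_r = cm[ut])

  retained <- character(0)
  removed <- data.frame(variable = character(0), culprit = character(0),
                        r = numeric(0))
  for (v in priority) {
    if (length(retained) > 0) {
      rs <- cm[v, retained]
      hit <- which(abs(rs) > r_threshold)
      if (length(hit) > 0) {
        worst <- hit[which.max(abs(rs[hit]))]
        removed <- rbind(removed, data.frame(
          variable = v, culprit = retained[worst], r = rs[worst]))
        next
      }
    }
    retained <- c(retained, v)
  }
  structure(list(pairs = pairs, retained = retained, removed = removed,
                 r_threshold = r_threshold),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report> |r| > %.2f: retained %d (%s), removed %d\n",
              x$r_threshold, length(x$retained),
              paste(x$retained, collapse = ", "), nrow(x$removed)))
  invisible(x)
}

#' Write a correlation report to CSV
#'
#' @param report a `correlation_report`.
#' @param path output CSV (the pairwise table; retained/removed flags added).
#' @return `path`, invisibly.
#' @export
write_correlation_report <- function(report, path) {
  df <- report$pairs
  df$a_retained <- df$var_a %in% report$retained
  df$b_retained <- df$var_b %in% report$retained
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Average several GCM climate stacks into one ensemble stack
#'
#' Cell-wise arithmetic mean per variable across global-circulation-model
#' variants; a cell is nodata in the result if any member is nodata there.
#' Reduces single-model bias in the future scenario before any species
#' modeling happens.
#'
#' @param stacks list of `climate_stack` objects with identical variable sets
#'   and aligned grids.
#' @param scenario_tag tag for the result (default: tag of the first stack).
#' @return a `climate_stack` of means.
#' @export
gcm_ensemble <- function(stacks, scenario_tag = stacks[[1]]$scenario_tag) {
  if (length(stacks) < 1) stop("gcm_ensemble: need at least one stack")
  vars <- names(stacks[[1]]$layers)
  for (s in stacks[-1])
    if (!setequal(names(s$layers), vars))
      stop("gcm_ensemble: variable sets differ across stacks")
  grids <- unlist(lapply(stacks, function(s) s$layers), recursive = FALSE)
  check_aligned(grids, what = "GCM stack layers")
  layers <- lapply(vars, function(v) {
    acc <- stacks[[1]]$layers[[v]]
    m <- acc$values
    for (s in stacks[-1]) m <- m + s$layers[[v]]$values # NA propagates
    acc$values <- m / length(stacks)
    acc
  })
  names(layers) <- vars
  climate_stack(layers, scenario_tag = scenario_tag)
}
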