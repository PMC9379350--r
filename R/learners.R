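#' Algorithms available for ensemble members
#'
#' Three regression methods (GLM, GAM, MARS), three machine-learning methods
#' (ANN, GBM, RF) and one classification method (CTA).
#'
#' @export
sdm_algorithms <- c("GLM", "GAM", "MARS", "ANN", "GBM", "RF", "CTA")

#' Fit one ensemble-member learner
#'
#' Uniform adapter over seven presence/pseudo-absence classifiers. Every
#' adapter takes a labeled table and returns an object whose [predict()]
#' method maps feature rows to occurrence probabilities in `[0, 1]`:
#'
#' * `GLM` — linear logistic regression, [stats::glm()].
#' * `GAM` — binomial additive model with thin-plate smooths (`k = 5`) per
#'   predictor, [mgcv::gam()]; near-constant predictors enter linearly.
#' * `MARS` — piecewise-linear logistic regression: forward selection of hinge
#'   basis-function pairs at quantile knots (implemented in-package).
#' * `ANN` — single-hidden-layer neural network, [nnet::nnet()], on
#'   standardized features.
#' * `GBM` — gradient-boosted trees, [xgboost::xgboost()].
#' * `RF` — random forest, [randomForest::randomForest()].
#' * `CTA` — classification tree, [rpart::rpart()].
#'
#' RF and ANN draw from the R RNG: seed before calling for reproducibility
#' (the pipeline driver does this per run).
#'
#' @param algorithm one of [sdm_algorithms].
#' @param train data.frame with integer 0/1 column `occ` and numeric feature
#'   columns; no missing values.
#' @return An object of class `sdm_learner`.
#' @export
fit_learner <- function(algorithm, train) {
  algorithm <- match.arg(algorithm, sdm_algorithms)
  if (!"occ" %in% names(train)) stop("train must contain an 'occ' column")
  y <- as.integer(train$occ)
  if (!all(y %in% c(0L, 1L))) stop("occ must be 0/1")
  if (length(unique(y)) < 2)
    stop("degenerate training data: only one class present")
  x <- train[, setdiff(names(train), "occ"), drop = FALSE]
  if (ncol(x) == 0) stop("no feature columns")
  if (anyNA(x)) stop("missing values in features")

  fit <- switch(algorithm,
    GLM = stats::glm(occ ~ ., data = train, family = stats::binomial()),
    GAM = fit_gam(train),
    MARS = fit_mars_hinge(x, y),
    ANN = fit_ann(x, y),
    GBM = xgboost::xgboost(
      data = as.matrix(x), label = y, nrounds = 100, verbose = 0,
      params = list(objective = "binary:logistic", max_depth = 3, eta = 0.1,
                    nthread = 1)),
    RF = randomForest::randomForest(x = x, y = factor(y, levels = c(0, 1)),
                                    ntree = 300),
    CTA = rpart::rpart(occ ~ ., data = transform(train, occ = factor(occ)),
                       method = "class",
                       control = rpart::rpart.control(cp = 0.005, xval = 0,
                                                      minbucket = 5))
  )
  structure(list(algorithm = algorithm, fit = fit, features = names(x)),
            class = "sdm_learner")
}

fit_gam <- function(train) {
  feats <- setdiff(names(train), "occ")
  terms <- vapply(feats, function(f) {
    nu <- length(unique(train[[f]]))
    if (nu >= 10) sprintf("s(%s, k = 5)", f)
    else if (nu >= 2) f
    else "" # constant feature contributes nothing
  }, character(1))
  terms <- terms[nzchar(terms)]
  if (length(terms) == 0) stop("all features constant")
  fml <- stats::as.formula(paste("occ ~", paste(terms, collapse = " + ")))
  # REML occasionally diverges on (near-)separable data; fall back to the
  # default GCV/UBRE criterion before giving up
  tryCatch(
    mgcv::gam(fml, data = train, family = stats::binomial(), method = "REML"),
    error = function(e)
      mgcv::gam(fml, data = train, family = stats::binomial()))
}

fit_ann <- function(x, y) {
  ctr <- vapply(x, mean, numeric(1))
  scl <- vapply(x, stats::sd, numeric(1))
  scl[scl == 0 | is.na(scl)] <- 1
  xs <- scale(as.matrix(x), center = ctr, scale = scl)
  net <- nnet::nnet(xs, y, size = 5, decay = 0.01, maxit = 300,
                    entropy = TRUE, trace = FALSE)
  list(net = net, center = ctr, scale = scl)
}

# Minimal MARS-style learner: forward selection of reflected hinge pairs
# h(x - k), h(k - x) at quantile knots, fit as a binomial GLM on the selected
# basis. No interaction terms; backward pruning replaced by a deviance
# improvement stop, which is enough for the smooth univariate responses the
# pipeline models.
fit_mars_hinge <- function(x, y, max_pairs = 8, min_improve = 1e-3) {
  x <- as.matrix(x)
  cands <- list()
  for (j in seq_len(ncol(x))) {
    ks <- unique(stats::quantile(x[, j], probs = seq(0.1, 0.9, by = 0.2),
                                 names = FALSE))
    if (length(unique(x[, j])) < 3) next
    for (k in ks) cands[[length(cands) + 1]] <- list(feature = j, knot = k)
  }
  n <- length(y)
  design <- matrix(1, n, 1)
  chosen <- list()
  dev0 <- stats::glm.fit(design, y, family = stats::binomial())$deviance
  cur_dev <- dev0
  used <- rep(FALSE, length(cands))
  while (length(chosen) < max_pairs && any(!used)) {
    devs <- rep(Inf, length(cands))
    for (i in which(!used)) {
      cc <- cands[[i]]
      b <- cbind(pmax(x[, cc$feature] - cc$knot, 0),
                 pmax(cc$knot - x[, cc$feature], 0))
      fit <- suppressWarnings(
        try(stats::glm.fit(cbind(design, b), y, family = stats::binomial()),
            silent = TRUE))
      if (!inherits(fit, "try-error")) devs[i] <- fit$deviance
    }
    best <- which.min(devs)
    if (!is.finite(devs[best]) || cur_dev - devs[best] < min_improve * dev0)
      break
    cc <- cands[[best]]
    design <- cbind(design,
                    pmax(x[, cc$feature] - cc$knot, 0),
                    pmax(cc$knot - x[, cc$feature], 0))
    chosen[[length(chosen) + 1]] <- cc
    cur_dev <- devs[best]
    used[best] <- TRUE
  }
  final <- suppressWarnings(
    stats::glm.fit(design, y, family = stats::binomial()))
  list(terms = chosen, coef = final$coefficients)
}

predict_mars_hinge <- function(model, x) {
  x <- as.matrix(x)
  design <- matrix(1, nrow(x), 1)
  for (cc in model$terms)
    design <- cbind(design,
                    pmax(x[, cc$feature] - cc$knot, 0),
                    pmax(cc$knot - x[, cc$feature], 0))
  beta <- model$coef
  beta[is.na(beta)] <- 0
  stats::plogis(drop(design %*% beta))
}

#' Predict occurrence probability from a fitted learner
#'
#' @param object an `sdm_learner`.
#' @param newdata data.frame containing the training feature columns.
#' @param ... unused.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict.sdm_learner <- function(object, newdata, ...) {
  miss <- setdiff(object$features, names(newdata))
  if (length(miss) > 0)
    stop(sprintf("newdata lacks feature(s): %s", paste(miss, collapse = ", ")))
  x <- newdata[, object$features, drop = FALSE]
  p <- switch(object$algorithm,
    GLM = stats::predict(object$fit, newdata = x, type = "response"),
    GAM = as.numeric(stats::predict(object$fit, newdata = x, type = "response")),
    MARS = predict_mars_hinge(object$fit, x),
    ANN = {
      xs <- scale(as.matrix(x), center = object$fit$center,
                  scale = object$fit$scale)
      as.numeric(stats::predict(object$fit$net, xs))
    },
    GBM = stats::predict(object$fit, as.matrix(x)),
    RF = stats::predict(object$fit, newdata = x, type = "prob")[, "1"],
    CTA = stats::predict(object$fit, newdata = x, type = "prob")[, "1"]
  )
  pmin(pmax(as.numeric(p), 0), 1)
}
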