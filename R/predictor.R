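#' Stratified train/test split
#'
#' Samples `fraction` of each stratum (rounded to the nearest count, at
#' least one test observation per stratum) into the training set; the rest
#' is the test set. Deterministic given the seed; per-stratum train
#' proportions are within one observation of the global fraction.
#'
#' @param n total number of observations, or a vector whose length is used.
#' @param strata factor/vector of stratum labels (e.g. growth stage), one
#'   per observation; every stratum needs at least 2 observations.
#' @param fraction training fraction (default 0.8).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
split_train_test <- function(n, strata = NULL, fraction = 0.8, seed = 1L) {
  if (length(n) > 1L) n <- length(n)
  if (is.null(strata)) strata <- rep(1L, n)
  if (length(strata) != n) stop("'strata' must have one label per observation")
  tab <- table(strata)
  if (any(tab < 2L))
    stop("stratum of size 1: ", paste(names(tab)[tab < 2L], collapse = ", "),
         " (every stratum needs at least 2 observations)")
  set.seed(as.integer(seed))
  train <- unlist(lapply(split(seq_len(n), strata), function(idx) {
    k <- round(fraction * length(idx))
    k <- min(max(k, 1L), length(idx) - 1L)   # keep both sets non-empty
    sample(idx, k)
  }), use.names = FALSE)
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Prediction accuracy metrics
#'
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`,
#' `RMSE = sqrt(mean((y - yhat)^2))`, `rRMSE = RMSE / mean(y) * 100` (%).
#'
#' @param observed,predicted numeric vectors of equal length >= 2.
#' @return data.frame with `r2`, `rmse`, `rrmse`, `n`. With zero observed
#'   variance `r2` is `NA` (flagged with a warning); with zero observed
#'   mean `rrmse` is `NA`.
#' @export
evaluate <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("'observed' and 'predicted' must have equal length")
  if (length(observed) < 2L) stop("need at least 2 observations")
  ok <- is.finite(observed) & is.finite(predicted)
  y <- observed[ok]; yhat <- predicted[ok]
  sse <- sum((y - yhat)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) {
    warning("zero observed variance; R2 undefined")
    NA_real_
  } else 1 - sse / sst
  rmse <- sqrt(sse / length(y))
  rrmse <- if (mean(y) == 0) NA_real_ else rmse / mean(y) * 100
  data.frame(r2 = r2, rmse = rmse, rrmse = rrmse, n = length(y))
}

#' Random forest regression with mtry tuning
#'
#' Thin contract over `ranger`: variance split rule, 150 trees, minimum
#' node size 5 (the usual defaults for this kind of trait prediction), with
#' `mtry` chosen by k-fold cross-validated RMSE over a grid.
#'
#' @param X feature matrix; @param y response.
#' @param n_trees,min_node,mtry_grid hyperparameters; `mtry_grid` defaults
#'   to `unique(c(floor(p/3), floor(sqrt(p)), p))`.
#' @param k_folds folds for mtry tuning (default 5).
#' @param seed integer seed (tuning folds and forest are reproducible).
#' @return object of class `rf_model` wrapping the fitted ranger forest.
#' @export
fit_rf <- function(X, y, n_trees = 150L, min_node = 5L, mtry_grid = NULL,
                   k_folds = 5L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L * min_node) stop("need at least 2 * min_node observations")
  if (is.null(mtry_grid))
    mtry_grid <- sort(unique(pmax(1L, c(floor(p / 3), floor(sqrt(p)), p))))
  if (any(mtry_grid > p))
    stop("mtry values exceed the number of features (", p, ")")
  df <- data.frame(y = y, X, check.names = FALSE)
  set.seed(as.integer(seed))
  folds <- sample(rep_len(seq_len(k_folds), n))
  cv_rmse <- vapply(mtry_grid, function(m) {
    errs <- vapply(seq_len(k_folds), function(f) {
      tr <- folds != f
      fit <- ranger::ranger(dependent.variable.name = "y",
                            data = df[tr, , drop = FALSE],
                            num.trees = n_trees, mtry = m,
                            min.node.size = min_node,
                            splitrule = "variance", seed = seed,
                            num.threads = 1L)
      pred <- stats::predict(fit, df[!tr, , drop = FALSE],
                             num.threads = 1L)$predictions
      mean((df$y[!tr] - pred)^2)
    }, 0)
    sqrt(mean(errs))
  }, 0)
  mtry <- mtry_grid[which.min(cv_rmse)]
  forest <- ranger::ranger(dependent.variable.name = "y", data = df,
                           num.trees = n_trees, mtry = mtry,
                           min.node.size = min_node,
                           splitrule = "variance", seed = seed,
                           num.threads = 1L)
  structure(list(forest = forest, mtry = mtry,
                 cv_rmse = stats::setNames(cv_rmse, mtry_grid),
                 feature_names = colnames(X)),
            class = "rf_model")
}

#' @export
predict.rf_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata, check.names = FALSE)
  missing_f <- setdiff(object$feature_names, colnames(newdata))
  if (length(missing_f))
    stop("missing feature column(s): ", paste(missing_f, collapse = ", "))
  stats::predict(object$forest,
                 newdata[, object$feature_names, drop = FALSE],
                 num.threads = 1L)$predictions
}

#' @export
print.rf_model <- function(x, ...) {
  cat("rf_model:", x$forest$num.trees, "trees, mtry", x$mtry, ",",
      length(x$feature_names), "features\n")
  invisible(x)
}

#' Train a trait-prediction model with the full selection workflow
#'
#' Reproduces the four-model workflow: a PLSR on all features with
#' LOOCV-tuned component count (`plsr_allvars`), importance-ranked,
#' correlation-filtered, elbow-stopped variable selection, then a PLSR
#' refit on the selected variables (`plsr_topvars`), and the random-forest
#' counterparts (`rf_allvars`, `rf_topvars`).
#'
#' @param X feature matrix; @param y trait values.
#' @param model which model to return.
#' @param r_threshold,elbow_delta selection parameters (defaults 0.8, 0.01).
#' @param seed integer seed (used by the RF models).
#' @return object of class `trait_model`: the fitted model, the selected
#'   variables (for topvars models), the tuned `ncomp`/`mtry`, and the
#'   importance ranking.
#' @export
train_predictor <- function(X, y,
                            model = c("plsr_topvars", "plsr_allvars",
                                      "rf_topvars", "rf_allvars"),
                            r_threshold = 0.8, elbow_delta = 0.01,
                            seed = 1L) {
  model <- match.arg(model)
  X <- as.matrix(X)
  keep <- apply(X, 2, stats::sd) > 0
  X <- X[, keep, drop = FALSE]
  tuned <- tune_ncomp(X, y)
  base <- fit_plsr(X, y, tuned$ncomp)
  ranking <- variable_importance(base)
  topvars <- NULL
  if (model %in% c("plsr_topvars", "rf_topvars"))
    topvars <- select_top_variables(ranking, X, y, r_threshold, elbow_delta)
  fitted <- switch(model,
    plsr_allvars = base,
    plsr_topvars = {
      Xt <- X[, topvars, drop = FALSE]
      tt <- tune_ncomp(Xt, y)
      fit_plsr(Xt, y, tt$ncomp)
    },
    rf_allvars = fit_rf(X, y, seed = seed),
    rf_topvars = fit_rf(X[, topvars, drop = FALSE], y, seed = seed))
  structure(list(model = model, fit = fitted, topvars = topvars,
                 ncomp = if (inherits(fitted, "plsr_model")) fitted$ncomp,
                 importance = ranking),
            class = "trait_model")
}

#' @export
predict.trait_model <- function(object, newdata, ...) {
  predict(object$fit, newdata, ...)
}

#' @export
print.trait_model <- function(x, ...) {
  cat("trait_model (", x$model, ")\n", sep = "")
  if (!is.null(x$topvars))
    cat("  selected:", paste(x$topvars, collapse = ", "), "\n")
  print(x$fit)
  invisible(x)
}

#' Predict traits for an untested panel
#'
#' @param model a `trait_model` (or any model with a `predict` method and a
#'   `feature_names` contract).
#' @param features data.frame with `plot_id` plus feature columns matching
#'   the training schema (missing columns are an error naming them).
#' @return data.frame: `plot_id`, `predicted`.
#' @export
predict_panel <- function(model, features) {
  stopifnot("plot_id" %in% names(features))
  Xn <- features[, setdiff(names(features), "plot_id"), drop = FALSE]
  data.frame(plot_id = features$plot_id,
             predicted = predict(model, Xn),
             stringsAsFactors = FALSE)
}
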