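#' Fit a partial least squares regression by NIPALS
#'
#' Univariate-response NIPALS: predictors are centered and scaled
#' internally, the response centered. For full-rank `X` with
#' `ncomp = rank(X)` the predictions coincide with ordinary least squares.
#' All model fields needed to reproduce predictions bit-for-bit are stored.
#'
#' @param X numeric matrix (n x p) of predictors.
#' @param y numeric response of length n.
#' @param ncomp number of latent components, `1 <= ncomp <= p`.
#' @return object of class `plsr_model`: predictor means/scales, weight
#'   matrix `W` (p x ncomp), loadings `P`, response loadings `q`, scores
#'   sum-of-squares `ss_scores`, explained response sum-of-squares per
#'   component `ssy_explained`, regression coefficients (standardized and
#'   raw scale), and intercept.
#' @export
fit_plsr <- function(X, y, ncomp) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  if (ncomp < 1L || ncomp > p)
    stop("'ncomp' must lie in 1..ncol(X)")
  if (n < ncomp + 1L)
    stop("need at least ncomp + 1 observations")
  mx <- colMeans(X)
  sx <- apply(X, 2, stats::sd)
  if (any(sx == 0))
    stop("constant predictor column(s): ",
         paste(colnames(X)[sx == 0], collapse = ", "))
  Xs <- scale(X, mx, sx)
  my <- mean(y)
  ys <- y - my
  rk <- qr(Xs)$rank
  if (ncomp > rk)
    stop(sprintf("ncomp = %d exceeds rank(X) = %d", ncomp, rk))

  W <- P <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  ss_scores <- numeric(ncomp)
  ssy <- numeric(ncomp)
  Xd <- Xs; yd <- ys
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- a - 1L; break }
    w <- w / nw
    t_a <- drop(Xd %*% w)
    tt <- sum(t_a^2)
    p_a <- crossprod(Xd, t_a) / tt
    q_a <- sum(yd * t_a) / tt
    Xd <- Xd - tcrossprod(t_a, p_a)
    yd <- yd - q_a * t_a
    W[, a] <- w; P[, a] <- p_a; q[a] <- q_a
    ss_scores[a] <- tt
    ssy[a] <- q_a^2 * tt
  }
  if (ncomp == 0L) stop("response is orthogonal to all predictors")
  W <- W[, seq_len(ncomp), drop = FALSE]
  P <- P[, seq_len(ncomp), drop = FALSE]
  q <- q[seq_len(ncomp)]
  # coefficients on the standardized scale: B = W (P'W)^-1 q
  Bstar <- drop(W %*% solve(crossprod(P, W), q))
  coef_raw <- Bstar / sx
  intercept <- my - sum(coef_raw * mx)
  structure(list(ncomp = ncomp, x_center = mx, x_scale = sx, y_center = my,
                 W = W, P = P, q = q,
                 ss_scores = ss_scores[seq_len(ncomp)],
                 ssy_explained = ssy[seq_len(ncomp)],
                 coef_std = Bstar, coef = coef_raw, intercept = intercept,
                 feature_names = colnames(X)),
            class = "plsr_model")
}

#' @export
predict.plsr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$feature_names)) {
    missing_f <- setdiff(object$feature_names, colnames(newdata))
    if (length(missing_f))
      stop("missing feature column(s): ", paste(missing_f, collapse = ", "))
    newdata <- newdata[, object$feature_names, drop = FALSE]
  }
  drop(newdata %*% object$coef) + object$intercept
}

#' @export
print.plsr_model <- function(x, ...) {
  cat("plsr_model:", length(x$coef), "features,", x$ncomp, "components\n")
  invisible(x)
}

#' Select the number of PLS components by leave-one-out cross-validation
#'
#' Fits the model on each leave-one-out fold once at the largest grid value
#' and reads predictions for every smaller component count from the same
#' fit; returns the grid value minimizing LOOCV RMSE, ties going to the
#' smallest count.
#'
#' @param X,y training data.
#' @param grid candidate component counts (default `1:ncol(X)`, capped at
#'   the rank attainable on the folds).
#' @return list: `ncomp` (selected), `rmse` (per grid value).
#' @export
tune_ncomp <- function(X, y, grid = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 observations for LOOCV")
  max_c <- min(ncol(X), n - 2L)
  if (is.null(grid)) grid <- seq_len(max_c)
  grid <- sort(unique(pmin(grid, max_c)))
  ncomp_max <- max(grid)
  err2 <- matrix(NA_real_, n, length(grid))
  for (i in seq_len(n)) {
    fit <- fit_plsr_safe(X[-i, , drop = FALSE], y[-i], ncomp_max)
    preds <- predict_all_ncomp(fit, X[i, , drop = FALSE], grid)
    err2[i, ] <- (y[i] - preds)^2
  }
  rmse <- sqrt(colMeans(err2))
  list(ncomp = grid[which.min(rmse)],
       rmse = stats::setNames(rmse, grid))
}

# fit, reducing ncomp if a fold's rank is lower
fit_plsr_safe <- function(X, y, ncomp) {
  rk <- qr(scale(X))$rank
  fit_plsr(X, y, min(ncomp, rk))
}

# predictions from a single NIPALS fit truncated at each component count
predict_all_ncomp <- function(fit, newX, grid) {
  newX <- as.matrix(newX)[, fit$feature_names, drop = FALSE]
  Xs <- scale(newX, fit$x_center, fit$x_scale)
  vapply(grid, function(a) {
    a <- min(a, fit$ncomp)
    W <- fit$W[, 1:a, drop = FALSE]
    P <- fit$P[, 1:a, drop = FALSE]
    B <- drop(W %*% solve(crossprod(P, W), fit$q[1:a]))
    drop(Xs %*% B) + fit$y_center
  }, 0)
}

#' PLSR variable importance
#'
#' Importance of feature j is the weighted sum of its absolute NIPALS
#' weights across components, weighted by the response sum-of-squares each
#' component explains: `score_j = sum_a |w_ja| * SSY_a`, normalized so the
#' top feature scores 100.
#'
#' @param model a `plsr_model`.
#' @return data.frame sorted by decreasing `score`: `feature`, `score`.
#' @export
variable_importance <- function(model) {
  stopifnot(inherits(model, "plsr_model"))
  raw <- drop(abs(model$W) %*% model$ssy_explained)
  score <- 100 * raw / max(raw)
  nms <- model$feature_names %||% sprintf("V%d", seq_along(score))
  out <- data.frame(feature = nms, score = score, stringsAsFactors = FALSE)
  out <- out[order(-out$score), ]
  rownames(out) <- NULL
  out
}

#' Greedy decorrelated variable selection with an elbow stop
#'
#' Walks down the importance ranking; a candidate joins the selected set
#' only if its absolute Pearson correlation with every already-selected
#' variable is below `r_threshold` (so the final set is pairwise
#' decorrelated). Selection stops at the elbow: the first set size k after
#' which two consecutive additions each raise the multiple-linear-
#' regression R^2 on `y` by less than `elbow_delta`.
#'
#' @param ranked data.frame from [variable_importance()] (or a character
#'   vector of feature names in rank order).
#' @param X feature matrix containing the ranked columns.
#' @param y response used for the elbow R^2.
#' @param r_threshold correlation filter (default 0.8).
#' @param elbow_delta minimum R^2 gain counted as progress (default 0.01).
#' @return character vector of selected feature names, in rank order.
#' @export
select_top_variables <- function(ranked, X, y, r_threshold = 0.8,
                                 elbow_delta = 0.01) {
  if (is.data.frame(ranked)) ranked <- ranked$feature
  X <- as.matrix(X)
  missing_f <- setdiff(ranked, colnames(X))
  if (length(missing_f))
    stop("ranked features absent from X: ", paste(missing_f, collapse = ", "))
  selected <- character(0)
  r2 <- numeric(0)
  for (f in ranked) {
    if (length(selected)) {
      rmax <- max(abs(stats::cor(X[, f], X[, selected, drop = FALSE])))
      if (rmax >= r_threshold) next
    }
    selected <- c(selected, f)
    fit <- stats::lm(y ~ X[, selected, drop = FALSE])
    r2 <- c(r2, summary(fit)$r.squared)
    k <- length(r2)
    if (k >= 3L) {
      gains <- diff(r2)
      if (gains[k - 1L] < elbow_delta && gains[k - 2L] < elbow_delta)
        return(selected[seq_len(k - 2L)])
    }
  }
  if (!length(selected))
    stop("no selectable variable (correlation filter removed everything)")
  selected
}
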