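#' AR1 x AR1 separable correlation structure
#'
#' Correlation between the plots at grid positions (j, k) and (j', k') is
#' `rho_row^|j - j'| * rho_col^|k - k'|` — the Kronecker product of two
#' first-order autoregressive correlation matrices, restricted to the
#' observed cells.
#'
#' @param rho_row,rho_col AR1 correlations, strictly inside (-1, 1).
#' @param n_rows,n_cols grid dimensions; alternatively pass explicit
#'   `rows`/`cols` coordinates for an incomplete grid.
#' @param rows,cols optional integer coordinates of the observed plots (in
#'   matching order); default the full grid in column-major order.
#' @return correlation matrix (plots x plots), symmetric positive definite.
#' @export
ar1_kron_correlation <- function(rho_row, rho_col, n_rows, n_cols,
                                 rows = NULL, cols = NULL) {
  if (abs(rho_row) >= 1 || abs(rho_col) >= 1)
    stop("AR1 correlations must lie strictly inside (-1, 1)")
  if (is.null(rows)) {
    rows <- rep(seq_len(n_rows), times = n_cols)
    cols <- rep(seq_len(n_cols), each = n_rows)
  }
  d_row <- abs(outer(rows, rows, "-"))
  d_col <- abs(outer(cols, cols, "-"))
  (rho_row^d_row) * (rho_col^d_col)
}

#' Fit the spatial linear mixed model for one trait
#'
#' Fits, by REML, the plot-level model
#' `y = mu + genotype + replicate + row + column + e`, with replicate, row
#' and column as independent random effects and residuals spatially
#' correlated as `N(0, sigma2_spatial * AR1xAR1)` plus (optionally) an
#' independent nugget `sigma2_resid * I`. Genotype enters either as a fixed
#' effect (for BLUEs) or as a further independent random effect (for
#' heritability).
#'
#' The spatial variance is profiled out analytically; the remaining
#' variance ratios and the two autocorrelations are optimized by bounded
#' quasi-Newton (`L-BFGS-B`) from three starting points, keeping the best.
#' The fit is deterministic given the data and optimizer settings.
#'
#' @param obs data.frame with columns `genotype`, `rep`, `row`, `col` and
#'   the trait column.
#' @param trait name of the trait column (default `"y"`).
#' @param genotype_as `"fixed"` or `"random"`.
#' @param include_nugget include the iid residual component (default TRUE).
#' @param reltol convergence tolerance on the REML criterion.
#' @return object of class `spatial_lmm`: variance components
#'   (`sigma2_spatial`, `sigma2_resid`, `sigma2_rep`, `sigma2_row`,
#'   `sigma2_col`, and `sigma2_g` when genotype is random), `rho_row`,
#'   `rho_col`, `mu`/fixed-effect estimates, the minimized `criterion`
#'   (-2 REML log-likelihood up to a constant), and an `objective` function
#'   of named natural-scale parameters for likelihood comparisons.
#' @export
fit_lmm <- function(obs, trait = "y",
                    genotype_as = c("fixed", "random"),
                    include_nugget = TRUE, reltol = 1e-8) {
  genotype_as <- match.arg(genotype_as)
  needed <- c("genotype", "rep", "row", "col", trait)
  missing_c <- setdiff(needed, names(obs))
  if (length(missing_c))
    stop("observations lack column(s): ", paste(missing_c, collapse = ", "))
  if (anyDuplicated(obs[c("row", "col")]))
    stop("(row, col) positions must be unique within the trial")
  y <- obs[[trait]]
  if (any(!is.finite(y))) {
    keep <- is.finite(y)
    obs <- obs[keep, , drop = FALSE]
    y <- y[keep]
  }
  n <- length(y)
  g <- factor(obs$genotype)
  reps <- factor(obs$rep)
  if (nlevels(g) < 2L || nlevels(reps) < 2L)
    stop("need at least 2 genotypes and 2 replicates")

  X <- if (genotype_as == "fixed") stats::model.matrix(~g) else
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("singular fixed-effect design; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }
  p <- ncol(X)

  ind <- function(f) outer(f, f, "==") * 1
  M_rep <- ind(as.integer(reps))
  M_row <- ind(obs$row)
  M_col <- ind(obs$col)
  M_g <- if (genotype_as == "random") ind(as.integer(g)) else NULL
  d_row <- abs(outer(obs$row, obs$row, "-"))
  d_col <- abs(outer(obs$col, obs$col, "-"))
  In <- diag(n)

  build_V <- function(rho_r, rho_c, gam) {
    V <- (rho_r^d_row) * (rho_c^d_col) +
      gam[["rep"]] * M_rep + gam[["row"]] * M_row + gam[["col"]] * M_col
    if (include_nugget) V <- V + gam[["nug"]] * In
    if (!is.null(M_g)) V <- V + gam[["g"]] * M_g
    V
  }

  # -2 REML log-likelihood (up to an additive constant), spatial variance
  # profiled out
  crit_fn <- function(rho_r, rho_c, gam) {
    V <- build_V(rho_r, rho_c, gam)
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(1e10)
    logdetV <- 2 * sum(log(diag(R)))
    Xi <- backsolve(R, forwardsolve(t(R), X))
    yi <- backsolve(R, forwardsolve(t(R), y))
    XtVX <- crossprod(X, Xi)
    cXtVX <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(cXtVX)) return(1e10)
    beta <- chol2inv(cXtVX) %*% crossprod(Xi, y)
    r <- y - X %*% beta
    rss <- sum(r * backsolve(R, forwardsolve(t(R), r)))
    if (rss <= 0) return(1e10)
    s2 <- rss / (n - p)
    (n - p) * log(s2) + logdetV + 2 * sum(log(diag(cXtVX))) + (n - p)
  }

  gam_names <- c("rep", "row", "col",
                 if (include_nugget) "nug", if (!is.null(M_g)) "g")
  unpack <- function(th) {
    list(rho_r = tanh(th[1L]), rho_c = tanh(th[2L]),
         gam = stats::setNames(exp(th[-(1:2)]), gam_names))
  }
  obj <- function(th) {
    pr <- unpack(th)
    crit_fn(pr$rho_r, pr$rho_c, pr$gam)
  }

  rho_starts <- list(c(0, 0), c(0.5, 0.5), c(-0.3, 0.3))
  gam_start <- stats::setNames(rep(0.3, length(gam_names)), gam_names)
  if (!is.null(M_g)) gam_start[["g"]] <- 1
  lower <- c(rep(atanh(-0.98), 2), rep(-10, length(gam_names)))
  upper <- c(rep(atanh(0.98), 2), rep(6, length(gam_names)))
  best <- NULL
  for (st in rho_starts) {
    th0 <- c(atanh(st), log(gam_start))
    fit <- tryCatch(
      stats::optim(th0, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(factr = reltol / .Machine$double.eps,
                                  maxit = 200L)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best))
    stop("REML optimization failed from every starting point")
  pr <- unpack(best$par)
  V <- build_V(pr$rho_r, pr$rho_c, pr$gam)
  R <- chol(V)
  Xi <- backsolve(R, forwardsolve(t(R), X))
  XtVXi <- chol2inv(chol(crossprod(X, Xi)))
  beta <- drop(XtVXi %*% crossprod(Xi, y))
  r <- y - X %*% beta
  s2 <- sum(r * backsolve(R, forwardsolve(t(R), r))) / (n - p)

  vc <- list(sigma2_spatial = s2,
             sigma2_resid = if (include_nugget) s2 * pr$gam[["nug"]] else 0,
             sigma2_rep = s2 * pr$gam[["rep"]],
             sigma2_row = s2 * pr$gam[["row"]],
             sigma2_col = s2 * pr$gam[["col"]],
             rho_row = pr$rho_r, rho_col = pr$rho_c)
  if (!is.null(M_g)) vc$sigma2_g <- s2 * pr$gam[["g"]]

  structure(c(vc, list(
    beta = stats::setNames(beta, colnames(X)),
    mu = beta[1L],
    criterion = best$value,
    convergence = best$convergence,
    genotype_as = genotype_as,
    include_nugget = include_nugget,
    genotype_levels = levels(g),
    n = n, n_fixed = p,
    X = X, y = y, V = V,
    g_index = as.integer(g),
    obs = obs, trait = trait,
    objective = function(params) {
      gam <- stats::setNames(numeric(length(gam_names)), gam_names)
      gam[["rep"]] <- params$sigma2_rep / params$sigma2_spatial
      gam[["row"]] <- (params$sigma2_row %||% 0) / params$sigma2_spatial
      gam[["col"]] <- (params$sigma2_col %||% 0) / params$sigma2_spatial
      if (include_nugget)
        gam[["nug"]] <- params$sigma2_resid / params$sigma2_spatial
      if (!is.null(M_g))
        gam[["g"]] <- params$sigma2_g / params$sigma2_spatial
      crit_fn(params$rho_row, params$rho_col, gam)
    })), class = "spatial_lmm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.spatial_lmm <- function(x, ...) {
  cat("spatial_lmm (genotype", x$genotype_as, "),", x$n, "plots\n")
  cat(sprintf("  rho_row = %.3f  rho_col = %.3f\n", x$rho_row, x$rho_col))
  cat(sprintf(paste0("  sigma2: spatial %.4g, nugget %.4g, rep %.4g,",
                     " row %.4g, col %.4g"),
              x$sigma2_spatial, x$sigma2_resid, x$sigma2_rep,
              x$sigma2_row, x$sigma2_col))
  if (!is.null(x$sigma2_g)) cat(sprintf(", genotype %.4g", x$sigma2_g))
  cat("\n  -2 REML criterion:", format(x$criterion), "\n")
  invisible(x)
}

#' Genotype BLUEs from a fitted spatial model
#'
#' Generalized-least-squares adjusted genotype means (`mu + G_i`) under the
#' estimated covariance, with standard errors.
#'
#' @param fit a [fit_lmm()] result with genotype fitted as fixed.
#' @return data.frame of class `blue_table`: `genotype`, `blue`, `se`.
#' @export
compute_blues <- function(fit) {
  stopifnot(inherits(fit, "spatial_lmm"))
  if (fit$genotype_as != "fixed")
    stop("genotype was fitted as random; BLUEs need a fixed-genotype fit ",
         "(use estimate_heritability() on this fit instead)")
  R <- chol(fit$V)
  Xi <- backsolve(R, forwardsolve(t(R), fit$X))
  cov_beta <- fit$sigma2_spatial * chol2inv(chol(crossprod(fit$X, Xi)))
  ng <- length(fit$genotype_levels)
  # L maps coefficients (intercept + treatment contrasts) to genotype means
  L <- cbind(1, rbind(0, diag(ng - 1L)))
  est <- drop(L %*% fit$beta)
  se <- sqrt(rowSums((L %*% cov_beta) * L))
  out <- data.frame(genotype = fit$genotype_levels, blue = est, se = se,
                    stringsAsFactors = FALSE)
  class(out) <- c("blue_table", "data.frame")
  out
}

#' Spatially detrended plot values
#'
#' Removes the BLUPs of the replicate, row, column and AR1xAR1 spatial
#' components from each observation, leaving the genotype signal plus the
#' independent residual — the stage-1 "adjusted plot value" handed to the
#' root-depth splines. Component BLUPs are `gamma_c * M_c V*^-1 r` with `r`
#' the marginal residual.
#'
#' @param fit a [fit_lmm()] result (genotype fixed).
#' @return data.frame: the fit's observation table plus an `adjusted`
#'   column.
#' @export
adjust_plot_values <- function(fit) {
  stopifnot(inherits(fit, "spatial_lmm"))
  obs <- fit$obs
  y <- fit$y
  r <- y - fit$X %*% fit$beta
  Vinv_r <- solve(fit$V, r)
  s2 <- fit$sigma2_spatial
  ind <- function(f) outer(f, f, "==") * 1
  trend <- (fit$sigma2_rep / s2) * (ind(as.integer(factor(obs$rep))) %*% Vinv_r) +
    (fit$sigma2_row / s2) * (ind(obs$row) %*% Vinv_r) +
    (fit$sigma2_col / s2) * (ind(obs$col) %*% Vinv_r) +
    ar1_kron_correlation(fit$rho_row, fit$rho_col,
                         rows = obs$row, cols = obs$col) %*% Vinv_r
  obs$adjusted <- drop(y - trend)
  obs
}

#' Broad-sense heritability from a random-genotype fit
#'
#' Line-mean heritability
#' `H2 = sigma2_g / (sigma2_g + (sigma2_spatial + sigma2_resid)/n_reps)`,
#' with `n_reps` the harmonic-mean number of replicates per genotype.
#' The Cullis definition `1 - mean PEV of BLUP differences / (2 sigma2_g)`
#' is available for unbalanced/spatial designs.
#'
#' @param fit a [fit_lmm()] result with genotype fitted as random.
#' @param method `"line_mean"` (default) or `"cullis"`.
#' @return heritability in `[0, 1]`.
#' @export
estimate_heritability <- function(fit, method = c("line_mean", "cullis")) {
  stopifnot(inherits(fit, "spatial_lmm"))
  method <- match.arg(method)
  if (fit$genotype_as != "random")
    stop("heritability needs a fit with genotype_as = 'random'")
  s2g <- fit$sigma2_g
  if (s2g < 1e-10 * (fit$sigma2_spatial + fit$sigma2_resid + 1e-12)) {
    warning("genotype variance estimated at the boundary; H2 = 0")
    return(0)
  }
  if (method == "line_mean") {
    reps_per_g <- tabulate(fit$g_index)
    n_eff <- length(reps_per_g) / sum(1 / reps_per_g)
    h2 <- s2g / (s2g + (fit$sigma2_spatial + fit$sigma2_resid) / n_eff)
    return(min(max(h2, 0), 1))
  }
  # Cullis: PEV of genotype BLUPs via P = Vinv - Vinv X (X'Vinv X)^-1 X'Vinv
  ng <- length(fit$genotype_levels)
  Z <- matrix(0, fit$n, ng)
  Z[cbind(seq_len(fit$n), fit$g_index)] <- 1
  Vi <- chol2inv(chol(fit$V)) / fit$sigma2_spatial
  XtViX <- crossprod(fit$X, Vi %*% fit$X)
  P <- Vi - Vi %*% fit$X %*% solve(XtViX, crossprod(fit$X, Vi))
  PEV <- s2g * diag(ng) - s2g^2 * crossprod(Z, P %*% Z)
  pev_d <- outer(diag(PEV), diag(PEV), "+") - 2 * PEV
  vbar <- mean(pev_d[upper.tri(pev_d)])
  min(max(1 - vbar / (2 * s2g), 0), 1)
}
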