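#' Fit a penalized B-spline to a root-count depth profile
#'
#' Cubic B-spline basis with knots on the 10-cm core-break grid and a
#' difference penalty on adjacent coefficients (a P-spline). The smoothing
#' parameter is selected by generalized cross-validation over a log-spaced
#' grid, so the fit is deterministic. Polynomials in the nullspace of the
#' penalty (degree `penalty_order - 1`) are unpenalized; noiseless
#' polynomial data drive GCV to the smallest smoothing and are reproduced
#' essentially exactly.
#'
#' @param profile data.frame with columns `depth` (cm, strictly increasing)
#'   and `count` (adjusted root counts, may be non-integer), or two numeric
#'   vectors via `depth`/`count`.
#' @param penalty_order order of the difference penalty (default 2).
#' @param lambda fixed smoothing parameter; `NULL` (default) selects by GCV.
#' @param lambda_grid grid searched by GCV.
#' @return object of class `depth_curve`: knots, degree, coefficients,
#'   chosen `lambda`, `gcv` table, fitted values at the data depths, and a
#'   `predict` method usable at any depth within the domain.
#' @export
fit_depth_spline <- function(profile, penalty_order = 2L, lambda = NULL,
                             lambda_grid = 10^seq(-6, 6, by = 0.25)) {
  if (is.data.frame(profile)) {
    depth <- profile$depth
    count <- profile$count
  } else stop("'profile' must be a data.frame with depth and count")
  if (length(depth) < 5L)
    stop("need at least 5 depth observations to fit the spline")
  if (any(diff(depth) <= 0)) stop("depths must be strictly increasing")
  if (any(count < 0)) stop("counts must be non-negative")
  zero_profile <- all(count == 0)
  if (zero_profile)
    warning("all-zero profile; returning the zero curve")

  step <- min(diff(depth))
  lo <- min(depth) - step          # domain padded one interval each side
  hi <- max(depth) + step
  degree <- 3L
  knots <- seq(lo - degree * step, hi + degree * step, by = step)
  B <- splines::splineDesign(knots, depth, ord = degree + 1L)
  nb <- ncol(B)
  D <- diff(diag(nb), differences = penalty_order)
  P <- crossprod(D)
  BtB <- crossprod(B)
  Bty <- crossprod(B, count)
  n <- length(count)

  fit_at <- function(lam) {
    M <- BtB + lam * P
    cM <- chol(M + 1e-10 * diag(nb))
    theta <- backsolve(cM, forwardsolve(t(cM), Bty))
    H_tr <- sum(diag(backsolve(cM, forwardsolve(t(cM), BtB))))
    fitted <- drop(B %*% theta)
    rss <- sum((count - fitted)^2)
    list(theta = theta, edf = H_tr,
         gcv = n * rss / (n - H_tr)^2, fitted = fitted)
  }

  if (is.null(lambda)) {
    gcv_tab <- data.frame(lambda = lambda_grid,
                          gcv = vapply(lambda_grid,
                                       function(l) fit_at(l)$gcv, 0))
    lambda <- gcv_tab$lambda[which.min(gcv_tab$gcv)]
  } else gcv_tab <- NULL
  f <- fit_at(lambda)

  structure(list(knots = knots, degree = degree, coef = drop(f$theta),
                 lambda = lambda, penalty_order = penalty_order,
                 edf = f$edf, gcv = gcv_tab,
                 depth = depth, count = count, fitted = f$fitted,
                 domain = c(lo, hi)),
            class = "depth_curve")
}

#' Evaluate a fitted depth curve
#'
#' @param object a `depth_curve`.
#' @param depth depths (cm) at which to evaluate; clamped to the fitted
#'   domain.
#' @param ... unused.
#' @return fitted root counts (not clipped; clipping at zero happens only
#'   in AUC computation).
#' @export
predict.depth_curve <- function(object, depth, ...) {
  depth <- pmin(pmax(depth, object$domain[1]), object$domain[2])
  B <- splines::splineDesign(object$knots, depth, ord = object$degree + 1L)
  drop(B %*% object$coef)
}

#' @export
print.depth_curve <- function(x, ...) {
  cat("depth_curve: domain", x$domain[1], "-", x$domain[2], "cm, lambda",
      format(x$lambda), ", edf", sprintf("%.1f", x$edf), "\n")
  invisible(x)
}

#' Area under the (non-negative part of the) root-count curve
#'
#' Composite trapezoid rule on a 0.5-cm grid of `max(curve, 0)` between two
#' depths.
#'
#' @param curve a `depth_curve`.
#' @param a_cm,b_cm integration bounds in cm, `0 <= a < b`.
#' @param step_cm quadrature step (default 0.5 cm).
#' @return the AUC (count x cm units).
#' @export
compute_auc <- function(curve, a_cm, b_cm, step_cm = 0.5) {
  stopifnot(inherits(curve, "depth_curve"))
  if (a_cm >= b_cm)
    stop(sprintf("integration bounds reversed or empty: [%g, %g]",
                 a_cm, b_cm))
  grid <- seq(a_cm, b_cm, by = step_cm)
  if (grid[length(grid)] < b_cm) grid <- c(grid, b_cm)
  v <- pmax(predict(curve, grid), 0)
  sum(diff(grid) * (v[-1] + v[-length(v)]) / 2)
}

#' Derive the five AUC root-proxy traits
#'
#' Total AUC over the full profile plus the four soil-stratum AUCs
#' (0-20, 20-60, 60-100, 100-170 cm), the strata tiling the full depth
#' range so their sum equals the total.
#'
#' @param curve a `depth_curve`.
#' @param strata numeric vector of stratum boundaries (default
#'   `c(0, 20, 60, 100, 170)`).
#' @return named numeric vector: `auc_total`, `auc_0_20`, `auc_20_60`,
#'   `auc_60_100`, `auc_100_170`.
#' @export
derive_root_proxies <- function(curve, strata = c(0, 20, 60, 100, 170)) {
  stopifnot(inherits(curve, "depth_curve"), length(strata) >= 2L)
  parts <- vapply(seq_len(length(strata) - 1L), function(i) {
    compute_auc(curve, strata[i], strata[i + 1L])
  }, 0)
  names(parts) <- sprintf("auc_%g_%g", strata[-length(strata)], strata[-1L])
  c(auc_total = sum(parts), parts)
}

#' Per-plot root proxies for a whole trial
#'
#' Fits a per-plot P-spline to each plot's depth profile and derives the
#' five AUC proxies; genotype-level values are the genotype means of the
#' plot proxies (the hierarchical variant collapsed, since the proxies are
#' the only downstream consumers).
#'
#' @param rootcounts data.frame with columns `plot_id`, `depth`, `count`.
#' @param ... passed to [fit_depth_spline()].
#' @return data.frame: `plot_id` plus the five proxy columns.
#' @export
root_proxies_by_plot <- function(rootcounts, ...) {
  stopifnot(all(c("plot_id", "depth", "count") %in% names(rootcounts)))
  ids <- unique(rootcounts$plot_id)
  rows <- lapply(ids, function(id) {
    pr <- rootcounts[rootcounts$plot_id == id, c("depth", "count")]
    pr <- pr[order(pr$depth), ]
    curve <- fit_depth_spline(pr, ...)
    as.data.frame(as.list(derive_root_proxies(curve)))
  })
  out <- cbind(data.frame(plot_id = ids, stringsAsFactors = FALSE),
               do.call(rbind, rows))
  rownames(out) <- NULL
  out
}
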