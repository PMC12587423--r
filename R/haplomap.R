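#' Marker quality control
#'
#' Removes markers with minor allele frequency at or below `maf_cut`
#' (inclusive) or with a heterozygote fraction above `het_cut`, and reports
#' the removals by reason.
#'
#' @param panel a `marker_panel` (complete dosage matrix).
#' @param maf_cut MAF threshold, removal if `MAF <= maf_cut` (default 0.05).
#' @param het_cut heterozygosity threshold, removal if het `> het_cut`
#'   (default 0.10).
#' @return the filtered `marker_panel`, with a `qc_report` element
#'   (data.frame: marker, maf, het, reason).
#' @export
qc_markers <- function(panel, maf_cut = 0.05, het_cut = 0.10) {
  stopifnot(inherits(panel, "marker_panel"))
  if (anyNA(panel$dosage))
    stop("dosage matrix contains missing genotypes; impute before QC ",
         "(the scan requires a complete matrix)")
  p <- colMeans(panel$dosage) / 2
  maf <- pmin(p, 1 - p)
  het <- colMeans(panel$dosage == 1L)
  bad_maf <- maf <= maf_cut
  bad_het <- het > het_cut
  drop_idx <- bad_maf | bad_het
  if (all(drop_idx))
    stop("QC removed every marker (maf_cut = ", maf_cut,
         ", het_cut = ", het_cut, ")")
  reason <- ifelse(bad_maf & bad_het, "maf+het",
                   ifelse(bad_maf, "maf", "het"))
  report <- data.frame(marker = colnames(panel$dosage)[drop_idx],
                       maf = maf[drop_idx], het = het[drop_idx],
                       reason = reason[drop_idx], stringsAsFactors = FALSE)
  rownames(report) <- NULL
  keep <- !drop_idx
  out <- panel
  out$dosage <- panel$dosage[, keep, drop = FALSE]
  out$map <- panel$map[keep, , drop = FALSE]
  rownames(out$map) <- NULL
  out$maf <- maf[keep]
  out$het <- het[keep]
  if (!is.null(panel$true_blocks))
    out$true_blocks <- panel$true_blocks[keep, , drop = FALSE]
  out$qc_report <- report
  out
}

#' Pairwise linkage disequilibrium r^2
#'
#' Squared Pearson correlation of two dosage vectors.
#'
#' @param panel a `marker_panel`.
#' @param j1,j2 marker indices or names.
#' @return r^2 in `[0, 1]`.
#' @export
compute_ld_r2 <- function(panel, j1, j2) {
  x1 <- panel$dosage[, j1]
  x2 <- panel$dosage[, j2]
  if (stats::sd(x1) == 0 || stats::sd(x2) == 0)
    stop("monomorphic marker; LD undefined")
  stats::cor(x1, x2)^2
}

#' Assign markers to LD blocks
#'
#' Greedy left-to-right chaining within each chromosome: the current block
#' is anchored at its first marker; the next marker joins the block if its
#' r^2 with the anchor reaches `ld_threshold`. Up to `tolerance`
#' consecutive sub-threshold markers may be bridged — they join the block
#' retroactively if a later marker re-qualifies. When the bridge budget is
#' exhausted the block closes before the first sub-threshold marker, which
#' anchors the next block. Blocks never span chromosomes; singletons are
#' allowed, and every marker lands in exactly one block.
#'
#' @param panel a QC'd `marker_panel` with a position-sorted map.
#' @param ld_threshold r^2 threshold (default 0.7).
#' @param tolerance maximum consecutive bridgeable markers (default 3).
#' @return object of class `ld_blocks`: data.frames `blocks` (block,
#'   chrom, start, end, n_markers) and `assignment` (marker, block), plus
#'   the parameters used.
#' @export
assign_ld_blocks <- function(panel, ld_threshold = 0.7, tolerance = 3L) {
  stopifnot(inherits(panel, "marker_panel"))
  map <- panel$map
  ord_ok <- all(unlist(lapply(split(map$pos, map$chrom),
                              function(p) !is.unsorted(p, strictly = TRUE))))
  if (!ord_ok)
    stop("marker map is not position-sorted within chromosomes")
  block_of <- integer(nrow(map))
  b <- 0L
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    i <- 1L
    while (i <= length(idx)) {
      b <- b + 1L
      anchor <- idx[i]
      members <- anchor
      pending <- integer(0)
      j <- i + 1L
      while (j <= length(idx)) {
        cand <- idx[j]
        if (compute_ld_r2(panel, anchor, cand) >= ld_threshold) {
          members <- c(members, pending, cand)   # bridge pending markers
          pending <- integer(0)
        } else {
          pending <- c(pending, cand)
          if (length(pending) > tolerance) break
        }
        j <- j + 1L
      }
      block_of[members] <- b
      if (length(pending)) {
        # block closed before the first sub-threshold marker
        i <- match(pending[1L], idx)
      } else {
        i <- length(idx) + 1L
      }
    }
  }
  blocks <- do.call(rbind, lapply(sort(unique(block_of)), function(bb) {
    m <- which(block_of == bb)
    data.frame(block = bb, chrom = map$chrom[m[1L]],
               start = min(map$pos[m]), end = max(map$pos[m]),
               n_markers = length(m))
  }))
  structure(list(blocks = blocks,
                 assignment = data.frame(marker = map$marker,
                                         block = block_of,
                                         stringsAsFactors = FALSE),
                 ld_threshold = ld_threshold, tolerance = tolerance),
            class = "ld_blocks")
}

#' @export
print.ld_blocks <- function(x, ...) {
  cat("ld_blocks:", nrow(x$blocks), "blocks over",
      nrow(x$assignment), "markers (mean",
      sprintf("%.2f", mean(x$blocks$n_markers)), "markers/block;",
      "r^2 >=", x$ld_threshold, ", tolerance", x$tolerance, ")\n")
  invisible(x)
}

#' Ridge-regression BLUP marker effects
#'
#' Solves `y = 1 mu + Z u + e` with `u ~ N(0, sigma2_u I)` and
#' `e ~ N(0, sigma2_e I)`, `Z` the column-centered dosage matrix. The
#' variance ratio `lambda = sigma2_e / sigma2_u` is estimated by REML via
#' the spectral decomposition of `Z Z'` (one-dimensional profile
#' optimization), and marker effects are the BLUP
#' `u_hat = Z' (Z Z' + lambda I)^-1 (y - mu_hat)`, which equals the
#' closed-form ridge solution `(Z'Z + lambda I)^-1 Z' (y - mu_hat)` by the
#' Woodbury identity.
#'
#' @param panel a QC'd `marker_panel`.
#' @param blues data.frame with columns `genotype` and `blue` (one
#'   phenotype record per line), or a named numeric vector.
#' @param lambda fixed variance ratio; `NULL` (default) estimates by REML.
#' @return object of class `rrblup_fit`: `effects` (named per-marker),
#'   `mu`, `lambda`, `sigma2_u`, `sigma2_e`.
#' @export
fit_rrblup <- function(panel, blues, lambda = NULL) {
  stopifnot(inherits(panel, "marker_panel"))
  if (is.data.frame(blues)) {
    y <- stats::setNames(blues$blue, blues$genotype)
  } else y <- blues
  common <- intersect(rownames(panel$dosage), names(y))
  if (length(common) < 30L)
    stop("phenotypes available for only ", length(common),
         " genotyped lines; need at least 30")
  y <- y[common]
  Z <- scale(panel$dosage[common, , drop = FALSE], center = TRUE,
             scale = FALSE)
  n <- length(y)
  K <- tcrossprod(Z)
  eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  ys <- drop(crossprod(U, y))
  xs <- drop(crossprod(U, rep(1, n)))

  profile <- function(lam) {
    w <- 1 / (d + lam)
    xwx <- sum(xs^2 * w)
    mu <- sum(xs * ys * w) / xwx
    r <- ys - xs * mu
    s2 <- sum(r^2 * w) / (n - 1)
    crit <- (n - 1) * log(s2) - sum(log(w)) + log(xwx)
    list(crit = crit, mu = mu, s2 = s2)
  }
  if (is.null(lambda)) {
    opt <- stats::optimize(function(ll) profile(exp(ll))$crit,
                           interval = c(-12, 12), tol = 1e-8)
    lambda <- exp(opt$minimum)
  }
  pr <- profile(lambda)
  sigma2_u <- pr$s2
  if (sigma2_u * sum(d) / (n - 1) < 1e-10 * stats::var(y))
    warning("genetic variance at the boundary; effects are ~0")
  r <- y - pr$mu
  Vinv_r <- U %*% ((1 / (d + lambda)) * crossprod(U, r))
  effects <- drop(crossprod(Z, Vinv_r))
  structure(list(effects = stats::setNames(effects, colnames(Z)),
                 mu = pr$mu, lambda = lambda,
                 sigma2_u = sigma2_u, sigma2_e = sigma2_u * lambda,
                 lines = common),
            class = "rrblup_fit")
}

#' @export
print.rrblup_fit <- function(x, ...) {
  cat("rrblup_fit:", length(x$effects), "marker effects,",
      length(x$lines), "lines; lambda =", format(x$lambda), "\n")
  invisible(x)
}

#' Local genomic estimated breeding values per LD block
#'
#' For every block and line, sums the estimated SNP effects weighted by the
#' line's (centered) dosages: `LGEBV(block, line) = sum_{j in block}
#' dosage_c(line, j) * u_hat_j`. Per-block variance across lines and the
#' scaled variance (variance / max block variance) are attached.
#'
#' @param effects an `rrblup_fit` (or named effect vector).
#' @param panel the `marker_panel` the effects refer to.
#' @param blocks an `ld_blocks` assignment.
#' @return object of class `lgebv_result`: `lgebv` (blocks x lines
#'   matrix), `block_stats` (block, chrom, start, end, n_markers,
#'   variance, scaled_variance).
#' @export
compute_lgebv <- function(effects, panel, blocks) {
  u <- if (inherits(effects, "rrblup_fit")) effects$effects else effects
  stopifnot(inherits(panel, "marker_panel"), inherits(blocks, "ld_blocks"))
  if (!identical(names(u), colnames(panel$dosage)))
    stop("effects are not aligned with the panel's markers")
  Zc <- scale(panel$dosage, center = TRUE, scale = FALSE)
  assign <- blocks$assignment
  ids <- blocks$blocks$block
  lg <- t(sapply(ids, function(b) {
    idx <- which(assign$block == b)
    if (!length(idx)) stop("block ", b, " is empty")
    drop(Zc[, idx, drop = FALSE] %*% u[idx])
  }))
  rownames(lg) <- paste0("b", sprintf("%06d", ids))
  colnames(lg) <- rownames(panel$dosage)
  v <- apply(lg, 1, stats::var)
  stats_df <- cbind(blocks$blocks,
                    data.frame(variance = v,
                               scaled_variance = if (max(v) > 0)
                                 v / max(v) else v * 0))
  rownames(stats_df) <- NULL
  structure(list(lgebv = lg, block_stats = stats_df),
            class = "lgebv_result")
}

#' @export
print.lgebv_result <- function(x, ...) {
  cat("lgebv_result:", nrow(x$lgebv), "blocks x", ncol(x$lgebv), "lines\n")
  invisible(x)
}

#' Select high-variance haploblocks
#'
#' Flags blocks whose scaled LGEBV variance reaches `scaled_threshold` and
#' returns them sorted by scaled variance (descending), with the selection
#' fraction reported.
#'
#' @param result an `lgebv_result`.
#' @param scaled_threshold scaled-variance cutoff (default 0.2).
#' @return data.frame of the selected blocks (block stats plus `selected`
#'   flag), with attribute `selection_fraction`.
#' @export
select_blocks <- function(result, scaled_threshold = 0.2) {
  stopifnot(inherits(result, "lgebv_result"))
  st <- result$block_stats
  st$selected <- st$scaled_variance >= scaled_threshold
  sel <- st[st$selected, , drop = FALSE]
  sel <- sel[order(-sel$scaled_variance), ]
  rownames(sel) <- NULL
  attr(sel, "selection_fraction") <- nrow(sel) / nrow(st)
  sel
}

#' Modified Rogers distance between lines
#'
#' `MRD(a, b) = sqrt( sum_loci sum_alleles (p_a - p_b)^2 / (2 m) )` with
#' within-line allele frequencies `p = dosage/2`; for biallelic loci this
#' reduces to `sqrt(mean_j (p_aj - p_bj)^2)`. Symmetric, zero diagonal,
#' range `[0, 1]` (1 for opposite homozygotes at every marker).
#'
#' @param panel a QC'd `marker_panel`.
#' @return a `dist`-convertible symmetric matrix (lines x lines).
#' @export
modified_rogers_distance <- function(panel) {
  stopifnot(inherits(panel, "marker_panel"))
  P <- panel$dosage / 2
  G <- tcrossprod(P)
  sq <- diag(G)
  d2 <- outer(sq, sq, "+") - 2 * G
  D <- sqrt(pmax(d2, 0) / ncol(P))
  diag(D) <- 0
  D
}

#' Population structure by MDS + k-means and Ward clustering
#'
#' Classical (metric) multidimensional scaling of the distance matrix,
#' k-means on the leading coordinates, and Ward ("ward.D2") hierarchical
#' clustering cut at the same k; both labelings are returned with the MDS
#' coordinates and the variance explained per axis.
#'
#' @param distances symmetric distance matrix (e.g.
#'   [modified_rogers_distance()]).
#' @param k number of clusters (default 3).
#' @param n_axes MDS axes kept (default `min(10, n - 1)`).
#' @param seed seed for the k-means starts.
#' @return object of class `pop_structure`: `mds` (coordinates),
#'   `kmeans_cluster`, `ward_cluster`, `eig_fraction`.
#' @export
cluster_population <- function(distances, k = 3L, n_axes = NULL, seed = 1L) {
  D <- as.matrix(distances)
  n <- nrow(D)
  if (k > n) stop("k = ", k, " exceeds the number of lines (", n, ")")
  if (is.null(n_axes)) n_axes <- min(10L, n - 1L)
  mds <- stats::cmdscale(D, k = n_axes, eig = TRUE)
  pos <- mds$eig[mds$eig > 0]
  eig_fraction <- mds$eig[seq_len(n_axes)] / sum(pos)
  set.seed(as.integer(seed))
  km <- if (k == 1L) list(cluster = rep(1L, n)) else
    stats::kmeans(mds$points, centers = k, nstart = 25L)
  hc <- stats::hclust(stats::as.dist(D), method = "ward.D2")
  ward <- stats::cutree(hc, k = k)
  structure(list(mds = mds$points,
                 kmeans_cluster = stats::setNames(km$cluster, rownames(D)),
                 ward_cluster = stats::setNames(ward, rownames(D)),
                 eig_fraction = eig_fraction, k = k),
            class = "pop_structure")
}

#' @export
print.pop_structure <- function(x, ...) {
  cat("pop_structure: k =", x$k, "; kmeans sizes:",
      paste(table(x$kmeans_cluster), collapse = "/"),
      "; ward sizes:", paste(table(x$ward_cluster), collapse = "/"), "\n")
  invisible(x)
}
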