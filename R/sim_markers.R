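#' Simulate a biallelic SNP panel with block-structured LD
#'
#' Markers are generated block by block with a Gaussian copula: within a
#' block the latent normals are equicorrelated at a level solved numerically
#' so that the correlation of the thresholded allele indicators matches the
#' requested within-block linkage disequilibrium (`cfg$ld_within`, an r^2).
#' Blocks are mutually independent, so between-block r^2 is ~0. Lines are
#' near-inbred, as in a breeding panel: most carry a doubled haplotype, and
#' a fraction `cfg$het_rate` carries two independent haplotypes in a block
#' (residual heterozygosity). Dosages are coded 0/1/2 counting the minor
#' allele; consumers are expected to center them.
#'
#' Each block uses a single target minor allele frequency drawn from
#' `cfg$maf_range` (equal latent thresholds keep every `ld_within` in
#' `[0, 1]` attainable; `ld_within = 1` therefore yields identical columns).
#' A positive `cfg$maf_jitter` perturbs per-marker frequencies; if the
#' requested LD then exceeds the maximum correlation attainable between
#' binary variables with those margins, generation fails loudly rather than
#' silently clipping. Blocks whose realized MAF falls outside `maf_range`
#' are redrawn (bounded retries).
#'
#' @param cfg a [sim_config()].
#' @return an object of class `marker_panel`: list with `dosage` (lines x
#'   markers integer matrix), `map` (data.frame: marker, chrom, pos),
#'   `maf`, `het` (per-marker stats), and `true_blocks` (data.frame:
#'   marker, block — the planted block labels, simulation ground truth).
#' @export
simulate_marker_panel <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(child_seed(cfg$seed, "markers"))
  n <- cfg$n_lines
  mpb <- cfg$markers_per_block
  n_blocks <- cfg$n_chrom * cfg$blocks_per_chrom
  rho_lat <- solve_latent_rho(cfg$ld_within)

  dosage <- matrix(0L, n, n_blocks * mpb)
  block_id <- integer(n_blocks * mpb)
  chrom <- integer(n_blocks * mpb)
  b <- 0L
  for (ch in seq_len(cfg$n_chrom)) {
    for (bl in seq_len(cfg$blocks_per_chrom)) {
      b <- b + 1L
      idx <- ((b - 1L) * mpb + 1L):(b * mpb)
      dosage[, idx] <- draw_ld_block(n, mpb, rho_lat, cfg)
      block_id[idx] <- b
      chrom[idx] <- ch
    }
  }
  marker <- sprintf("m%04d", seq_len(ncol(dosage)))
  colnames(dosage) <- marker
  rownames(dosage) <- sprintf("L%03d", seq_len(n))
  # positions: cumulative random spacings, strictly increasing per chromosome
  pos <- unlist(lapply(split(seq_along(marker), chrom), function(i) {
    cumsum(round(stats::runif(length(i), 2e5, 1.5e6)))
  }), use.names = FALSE)
  map <- data.frame(marker = marker, chrom = chrom, pos = pos,
                    stringsAsFactors = FALSE)
  p <- colMeans(dosage) / 2
  structure(list(dosage = dosage, map = map,
                 maf = pmin(p, 1 - p),
                 het = colMeans(dosage == 1L),
                 true_blocks = data.frame(marker = marker, block = block_id,
                                          stringsAsFactors = FALSE)),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("marker_panel:", nrow(x$dosage), "lines x", ncol(x$dosage),
      "markers on", length(unique(x$map$chrom)), "chromosomes\n")
  cat("  MAF range:", sprintf("%.3f-%.3f", min(x$maf), max(x$maf)),
      " mean het:", sprintf("%.3f", mean(x$het)), "\n")
  invisible(x)
}

# P(Z1 < a, Z2 < b) for standard bivariate normal with correlation rho,
# by one-dimensional quadrature (no external bivariate-normal dependency).
bvn_lower <- function(a, b, rho) {
  if (abs(rho) >= 1 - 1e-12) {
    if (rho > 0) return(stats::pnorm(min(a, b)))
    return(max(0, stats::pnorm(a) + stats::pnorm(b) - 1))
  }
  f <- function(z) stats::dnorm(z) *
    stats::pnorm((b - rho * z) / sqrt(1 - rho^2))
  stats::integrate(f, -Inf, a, rel.tol = 1e-10)$value
}

# Correlation between allele indicators 1{Z1 < a}, 1{Z2 < b} under a
# Gaussian copula with latent correlation rho.
binary_cor <- function(rho, a, b) {
  p1 <- stats::pnorm(a); p2 <- stats::pnorm(b)
  (bvn_lower(a, b, rho) - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
}

# Solve the latent equicorrelation giving allele-level r^2 = ld_within for
# equal thresholds (threshold level drops out to first order; solved at the
# representative MAF 0.3).
solve_latent_rho <- function(ld_within) {
  if (ld_within <= 0) return(0)
  if (ld_within >= 1) return(1)
  target_r <- sqrt(ld_within)
  a <- stats::qnorm(0.3)
  stats::uniroot(function(r) binary_cor(r, a, a) - target_r,
                 c(1e-6, 1 - 1e-6), tol = 1e-8)$root
}

# Draw one LD block of dosages (n lines x m markers), redrawing until every
# realized MAF lies inside cfg$maf_range.
draw_ld_block <- function(n, m, rho_lat, cfg) {
  for (attempt in seq_len(100L)) {
    p_block <- stats::runif(1, cfg$maf_range[1], cfg$maf_range[2])
    p <- rep(p_block, m)
    if (cfg$maf_jitter > 0) {
      p <- pmin(pmax(p + stats::rnorm(m, 0, cfg$maf_jitter), 0.01), 0.5)
      check_ld_feasible(p, cfg$ld_within)
    }
    thr <- stats::qnorm(p)
    draw_hap <- function() {
      shared <- stats::rnorm(n)
      z <- sqrt(rho_lat) * matrix(shared, n, m) +
        sqrt(1 - rho_lat) * matrix(stats::rnorm(n * m), n, m)
      t(t(z) < thr) * 1L
    }
    h1 <- draw_hap()
    h2 <- draw_hap()
    # near-inbred lines: most lines carry a doubled haplotype; a small
    # fraction (het_rate) keeps a second, independent one (residual
    # heterozygosity from recent outcrossing)
    inbred <- stats::runif(n) >= cfg$het_rate
    h2[inbred, ] <- h1[inbred, ]
    d <- h1 + h2
    freq <- colMeans(d) / 2
    flip <- freq > 0.5              # recode so the minor allele is counted
    d[, flip] <- 2L - d[, flip]
    maf <- pmin(freq, 1 - freq)
    if (all(maf >= cfg$maf_range[1] & maf <= cfg$maf_range[2]))
      return(d)
  }
  stop("could not generate an LD block with every realized MAF inside ",
       sprintf("[%.3f, %.3f] after 100 attempts; ", cfg$maf_range[1],
               cfg$maf_range[2]),
       "widen 'maf_range', enlarge 'n_lines', or lower 'ld_within'")
}

# With unequal margins the correlation of thresholded binaries is bounded
# above by its value at latent correlation 1; requesting more is infeasible.
check_ld_feasible <- function(p, ld_within) {
  if (ld_within <= 0) return(invisible(TRUE))
  thr <- stats::qnorm(p)
  for (j in seq_len(length(p) - 1L)) {
    rmax <- binary_cor(1 - 1e-9, thr[j], thr[j + 1L])
    if (rmax^2 < ld_within)
      stop(sprintf(paste0("requested within-block r^2 = %.3f is unattainable",
                          " for marker MAFs %.3f and %.3f (max attainable ",
                          "r^2 = %.3f); reduce 'maf_jitter' or 'ld_within'"),
                   ld_within, stats::pnorm(thr[j]), stats::pnorm(thr[j + 1L]),
                   rmax^2))
  }
  invisible(TRUE)
}

#' Plant QTL effects and build latent trait values
#'
#' Chooses `cfg$n_qtl_blocks` LD blocks per latent trait, plants one causal
#' marker with a standard-normal effect inside each (a causal variant
#' tagged by its haplotype block — iid effects across near-collinear
#' markers would concentrate signal in within-block difference directions
#' that carry almost no dosage variance, which no real variant does), and
#' builds per-line latent trait values as the genic score plus independent
#' non-genetic noise,
#' scaled so that the genic fraction of the (in-sample) latent variance is
#' exactly `cfg$qtl_h2`. Each planted block contributes an equal share of
#' the genic variance. Latent traits are the four depth-stratum root
#' intensities plus one biomass scale; they are the single source of truth
#' used by the root-count, biomass and vegetation-index generators.
#'
#' @param panel a [simulate_marker_panel()] result.
#' @param cfg the [sim_config()] used to generate `panel`.
#' @return object of class `true_genetics`: list with `latents` (lines x
#'   traits matrix), `effects` (markers x traits, zero outside QTL blocks),
#'   `qtl_blocks` (list of planted block ids per trait), `qtl_h2`.
#' @export
simulate_genetic_effects <- function(panel, cfg) {
  stopifnot(inherits(panel, "marker_panel"))
  n_blocks <- max(panel$true_blocks$block)
  if (cfg$n_qtl_blocks > n_blocks)
    stop("'n_qtl_blocks' exceeds the number of simulated blocks")
  set.seed(child_seed(cfg$seed, "effects"))
  traits <- c("root_0_20", "root_20_60", "root_60_100", "root_100_170",
              "biomass")
  Zc <- scale(panel$dosage, center = TRUE, scale = FALSE)
  n <- nrow(Zc)
  latents <- matrix(0, n, length(traits),
                    dimnames = list(rownames(panel$dosage), traits))
  effects <- matrix(0, ncol(Zc), length(traits),
                    dimnames = list(colnames(panel$dosage), traits))
  qtl_blocks <- vector("list", length(traits))
  names(qtl_blocks) <- traits
  for (tr in seq_along(traits)) {
    noise <- stats::rnorm(n)
    if (cfg$n_qtl_blocks == 0L) {
      latents[, tr] <- as.vector(scale(noise))
      next
    }
    picked <- sort(sample.int(n_blocks, cfg$n_qtl_blocks))
    qtl_blocks[[tr]] <- picked
    g <- numeric(n)
    for (b in picked) {
      idx <- which(panel$true_blocks$block == b)
      causal <- idx[sample.int(length(idx), 1L)]
      gb <- Zc[, causal]
      s <- stats::sd(gb)
      if (s < 1e-12) stop("planted QTL block ", b, " is monomorphic")
      # unit-variance block contribution, equal genic share per block
      effects[causal, tr] <- 1 / (s * sqrt(cfg$n_qtl_blocks))
      g <- g + gb / (s * sqrt(cfg$n_qtl_blocks))
    }
    g_sd <- stats::sd(g)
    effects[, tr] <- effects[, tr] * sqrt(cfg$qtl_h2) / g_sd
    g <- g * sqrt(cfg$qtl_h2) / g_sd
    if (cfg$qtl_h2 >= 1) {
      latents[, tr] <- g - mean(g)
    } else {
      # orthogonalize noise against the genic score so the in-sample genetic
      # variance fraction is exactly qtl_h2
      e <- stats::resid(stats::lm(noise ~ g))
      e <- e / stats::sd(e) * sqrt(1 - cfg$qtl_h2)
      latents[, tr] <- (g - mean(g)) + e
    }
  }
  structure(list(latents = latents, effects = effects,
                 qtl_blocks = qtl_blocks, qtl_h2 = cfg$qtl_h2),
            class = "true_genetics")
}

#' @export
print.true_genetics <- function(x, ...) {
  cat("true_genetics:", ncol(x$latents), "latent traits,",
      nrow(x$latents), "lines; qtl_h2 =", x$qtl_h2, "\n")
  for (tr in colnames(x$latents))
    cat("  ", tr, ": QTL blocks",
        if (is.null(x$qtl_blocks[[tr]])) "(none)" else
          paste(x$qtl_blocks[[tr]], collapse = ", "), "\n")
  invisible(x)
}
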