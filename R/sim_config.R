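#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator: the SNP panel
#' (block-structured linkage disequilibrium, planted QTL), the field layout
#' (replicated grid with separable AR1xAR1 spatial noise), the root-count-
#' over-depth curves, the stage-wise biomass trajectory, the vegetation-index
#' feature generator, and the per-plot image generator. One `sim_config`
#' plus one seed fixes every downstream draw.
#'
#' Defaults mirror the study conditions the pipeline is meant to emulate:
#' a barley breeding panel of a few hundred lines genotyped at ~500 SNPs on
#' 7 chromosomes (about 3 markers per LD block, strong within-block LD), a
#' replicated coring trial of a 20-line core set with six complete blocks,
#' soil cores broken at 10 cm intervals from 0 to 170 cm, biomass cuts at
#' tillering / stem elongation / flowering, and multispectral flights over
#' the season.
#'
#' @param n_lines number of lines in the panel.
#' @param n_chrom number of chromosomes.
#' @param blocks_per_chrom number of LD blocks per chromosome.
#' @param markers_per_block markers per LD block.
#' @param ld_within target average adjacent-marker r^2 within a block, in
#'   `[0, 1]`. `1` forces identical marker columns within a block.
#' @param maf_range length-2 numeric, (min, max) minor allele frequency in
#'   `(0, 0.5]`; realized per-marker MAF is kept inside this range.
#' @param maf_jitter sd of per-marker jitter around the block MAF (default 0;
#'   jitter can make a high `ld_within` unattainable, which is an error).
#' @param het_rate fraction of line x block segments that are heterozygous
#'   (carry two independent haplotypes instead of a doubled one). Breeding
#'   lines are near-inbred, so the default is small.
#' @param n_qtl_blocks number of LD blocks carrying true QTL effects (per
#'   latent trait).
#' @param qtl_h2 fraction of each latent trait's variance that is genetic,
#'   in `(0, 1]`.
#' @param n_rows,n_cols field grid dimensions.
#' @param n_reps complete replicates in the trial.
#' @param rho_row,rho_col AR1 correlations along rows / columns, in (-1, 1).
#' @param sigma2_spatial variance of the AR1xAR1-correlated residual.
#' @param sigma2_resid variance of the independent (nugget) residual.
#' @param sigma2_rep,sigma2_rowef,sigma2_colef variances of the replicate,
#'   row and column random effects.
#' @param genetic_var variance of the genotype contribution to a plot
#'   observation (trait units^2).
#' @param depth_grid soil-core break depths in cm, strictly increasing.
#' @param stages named numeric vector of growth-stage sampling times in days
#'   after sowing.
#' @param flight_days days after sowing of the simulated flights.
#' @param vi_loading_matrix latent-trait x feature loading matrix for the
#'   vegetation-index feature generator, or `NULL` to build a default with
#'   unit-norm columns (one feature per index x flight day).
#' @param vi_noise_sd sd of the iid noise added to each feature. The default
#'   0.316 gives signal-to-noise ratio ~10 on unit-variance latents.
#' @param vi_phenology_sd scale of the deterministic canopy-development
#'   offset each feature carries at its flight day (constant across plots
#'   within a column; emulates indices tracking canopy growth through the
#'   season). Set to 0 for pure latent mixtures.
#' @param image_size side length (pixels) of the square synthetic plot images.
#' @param canopy_temp_offset degrees C by which vegetation pixels are cooler
#'   than soil pixels.
#' @param root_overdispersion negative-binomial size parameter for core-break
#'   counts (larger = closer to Poisson).
#' @param seed integer seed fixing all randomness of the generator.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_lines = 200,
                       n_chrom = 7,
                       blocks_per_chrom = 24,
                       markers_per_block = 3,
                       ld_within = 0.95,
                       maf_range = c(0.1, 0.5),
                       maf_jitter = 0,
                       het_rate = 0.03,
                       n_qtl_blocks = 3,
                       qtl_h2 = 0.6,
                       n_rows = 10,
                       n_cols = 12,
                       n_reps = 6,
                       rho_row = 0.5,
                       rho_col = 0.3,
                       sigma2_spatial = 1,
                       sigma2_resid = 0.25,
                       sigma2_rep = 0.1,
                       sigma2_rowef = 0,
                       sigma2_colef = 0,
                       genetic_var = 1,
                       depth_grid = seq(10, 170, by = 10),
                       stages = c(tillering = 25, stem_elongation = 55,
                                  flowering = 88),
                       flight_days = c(25, 55, 88, 118),
                       vi_loading_matrix = NULL,
                       vi_noise_sd = 0.316,
                       vi_phenology_sd = 2,
                       image_size = 16,
                       canopy_temp_offset = 6,
                       root_overdispersion = 20,
                       seed = 1L) {
  cfg <- list(n_lines = n_lines, n_chrom = n_chrom,
              blocks_per_chrom = blocks_per_chrom,
              markers_per_block = markers_per_block,
              ld_within = ld_within, maf_range = maf_range,
              maf_jitter = maf_jitter, het_rate = het_rate,
              n_qtl_blocks = n_qtl_blocks, qtl_h2 = qtl_h2,
              n_rows = n_rows, n_cols = n_cols, n_reps = n_reps,
              rho_row = rho_row, rho_col = rho_col,
              sigma2_spatial = sigma2_spatial, sigma2_resid = sigma2_resid,
              sigma2_rep = sigma2_rep, sigma2_rowef = sigma2_rowef,
              sigma2_colef = sigma2_colef,
              genetic_var = genetic_var,
              depth_grid = depth_grid, stages = stages,
              flight_days = flight_days,
              vi_loading_matrix = vi_loading_matrix,
              vi_noise_sd = vi_noise_sd,
              vi_phenology_sd = vi_phenology_sd,
              image_size = image_size,
              canopy_temp_offset = canopy_temp_offset,
              root_overdispersion = root_overdispersion,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  counts <- c("n_lines", "n_chrom", "blocks_per_chrom", "markers_per_block",
              "n_rows", "n_cols", "n_reps", "image_size")
  for (nm in counts) {
    v <- cfg[[nm]]
    if (length(v) != 1L || !is.finite(v) || v < 1 || v != round(v))
      stop(sprintf("'%s' must be a single integer >= 1 (got %s)", nm,
                   paste(v, collapse = ",")))
  }
  if (cfg$ld_within < 0 || cfg$ld_within > 1)
    stop("'ld_within' must lie in [0, 1]")
  mr <- cfg$maf_range
  if (length(mr) != 2L || mr[1] <= 0 || mr[2] > 0.5 || mr[1] > mr[2])
    stop("'maf_range' must be (min, max) with 0 < min <= max <= 0.5")
  if (cfg$maf_jitter < 0) stop("'maf_jitter' must be >= 0")
  if (cfg$het_rate < 0 || cfg$het_rate > 1)
    stop("'het_rate' must lie in [0, 1]")
  if (cfg$qtl_h2 <= 0 || cfg$qtl_h2 > 1)
    stop("'qtl_h2' must lie in (0, 1]")
  if (cfg$n_qtl_blocks < 0)
    stop("'n_qtl_blocks' must be >= 0")
  if (cfg$n_qtl_blocks > cfg$n_chrom * cfg$blocks_per_chrom)
    stop("'n_qtl_blocks' exceeds the number of simulated blocks")
  for (nm in c("rho_row", "rho_col"))
    if (abs(cfg[[nm]]) >= 1)
      stop(sprintf("'%s' must lie in the open interval (-1, 1)", nm))
  for (nm in c("sigma2_spatial", "sigma2_resid", "sigma2_rep",
               "sigma2_rowef", "sigma2_colef", "genetic_var",
               "vi_noise_sd", "vi_phenology_sd"))
    if (cfg[[nm]] < 0) stop(sprintf("'%s' must be >= 0", nm))
  if (cfg$root_overdispersion <= 0)
    stop("'root_overdispersion' must be > 0")
  if (any(diff(cfg$depth_grid) <= 0))
    stop("'depth_grid' must be strictly increasing")
  if (is.null(names(cfg$stages)) || any(!nzchar(names(cfg$stages))))
    stop("'stages' must be a named vector of days after sowing")
  if (cfg$image_size < 8)
    stop("'image_size' must be at least 8 pixels")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  m <- x$n_chrom * x$blocks_per_chrom * x$markers_per_block
  cat("sim_config:", x$n_lines, "lines,", m, "markers (",
      x$n_chrom, "chrom x", x$blocks_per_chrom, "blocks x",
      x$markers_per_block, "markers ), grid",
      x$n_rows, "x", x$n_cols, ",", x$n_reps, "reps, seed", x$seed, "\n")
  invisible(x)
}

# Internal: derive a child RNG seed from the config seed and a stream label,
# so that each generator stage has its own reproducible stream. Kept below
# 2^31 - 1.
child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 10007 + h %% 99991) %% 2147483562)
}
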