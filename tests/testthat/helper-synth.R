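# Small reusable fixtures, all generated in code.

small_cfg <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_lines = 100L, n_chrom = 2L, blocks_per_chrom = 5L,
         markers_per_block = 3L, seed = seed),
    list(...))
  do.call(sim_config, args)
}

# A coring-trial-sized config: 20 lines x 6 reps on a 10 x 12 grid.
trial_cfg <- function(seed = 1L, ...) {
  small_cfg(seed = seed, n_lines = 20L, ...)
}

flowering_obs <- function(trial) {
  d <- merge(trial$biomass[trial$biomass$stage == "flowering", ],
             trial$plots, by = "plot_id")
  data.frame(genotype = d$genotype, rep = d$rep, row = d$row, col = d$col,
             y = d$biomass)
}

# Hand-built multiband image with two exact pixel populations.
two_pop_image <- function(n_side = 10, cover = 0.5,
                          veg = c(blue = 0.05, green = 0.10, red = 0.05,
                                  rededge = 0.30, nir = 0.45, thermal = 24),
                          soil = c(blue = 0.30, green = 0.30, red = 0.30,
                                   rededge = 0.30, nir = 0.30, thermal = 30)) {
  npix <- n_side^2
  n_veg <- round(cover * npix)
  bands <- names(veg)
  arr <- array(0, dim = c(n_side, n_side, 6),
               dimnames = list(NULL, NULL, bands))
  is_veg <- c(rep(TRUE, n_veg), rep(FALSE, npix - n_veg))
  for (b in bands) arr[, , b] <- ifelse(is_veg, veg[[b]], soil[[b]])
  structure(list(plot_id = "T1", data = arr, bands = bands, cover = cover),
            class = "plot_image")
}

# Panel with three allele-frequency-diverged subpopulations (for structure
# tests): inbred dosages drawn at subpopulation-specific frequencies.
subpop_panel <- function(n_per_pop = 30, m = 120, fst_shift = 0.4,
                         seed = 1L) {
  set.seed(seed)
  base_p <- runif(m, 0.2, 0.8)
  pops <- lapply(1:3, function(k) {
    p <- pmin(pmax(base_p + runif(m, -fst_shift, fst_shift), 0.02), 0.98)
    d <- sapply(p, function(pp) 2L * rbinom(n_per_pop, 1, pp))
    d
  })
  dosage <- do.call(rbind, pops)
  rownames(dosage) <- sprintf("S%d_%02d", rep(1:3, each = n_per_pop),
                              rep(seq_len(n_per_pop), 3))
  colnames(dosage) <- sprintf("m%03d", seq_len(m))
  panel <- structure(list(
    dosage = dosage,
    map = data.frame(marker = colnames(dosage), chrom = 1L,
                     pos = seq_len(m) * 1e5),
    maf = pmin(colMeans(dosage) / 2, 1 - colMeans(dosage) / 2),
    het = colMeans(dosage == 1L)), class = "marker_panel")
  list(panel = panel, labels = rep(1:3, each = n_per_pop))
}

adjusted_rand_index <- function(a, b) mclust::adjustedRandIndex(a, b)

# Tiny hand-specifiable marker panel from an explicit dosage matrix.
toy_panel <- function(dosage, chrom = NULL) {
  m <- ncol(dosage)
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("t%02d", seq_len(m))
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("L%02d", seq_len(nrow(dosage)))
  if (is.null(chrom)) chrom <- rep(1L, m)
  p <- colMeans(dosage) / 2
  structure(list(dosage = dosage,
                 map = data.frame(marker = colnames(dosage), chrom = chrom,
                                  pos = stats::ave(seq_len(m), chrom,
                                                   FUN = seq_along) * 1e5),
                 maf = pmin(p, 1 - p), het = colMeans(dosage == 1L)),
            class = "marker_panel")
}
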