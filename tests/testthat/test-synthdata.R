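test_that("config validation rejects out-of-range parameters", {
  expect_error(small_cfg(ld_within = 1.2), "ld_within")
  expect_error(small_cfg(maf_range = c(0, 0.5)), "maf_range")
  expect_error(small_cfg(rho_row = 1), "rho_row")
  expect_error(small_cfg(qtl_h2 = 0), "qtl_h2")
  expect_error(small_cfg(depth_grid = c(10, 10, 30)), "increasing")
  expect_error(small_cfg(image_size = 4), "image_size")
  expect_error(small_cfg(n_qtl_blocks = 1000), "exceeds")
})

test_that("perfect within-block LD forces identical marker columns", {
  cfg <- small_cfg(seed = 3, ld_within = 1, n_qtl_blocks = 1)
  panel <- simulate_marker_panel(cfg)
  for (b in unique(panel$true_blocks$block)) {
    idx <- which(panel$true_blocks$block == b)
    for (j in idx[-1])
      expect_identical(panel$dosage[, j], panel$dosage[, idx[1]],
                       ignore_attr = TRUE)
  }
})

test_that("zero LD gives near-zero between-adjacent-marker r2 (many seeds)", {
  r2s <- vapply(1:50, function(s) {
    cfg <- small_cfg(seed = s, n_lines = 80, n_chrom = 1,
                     blocks_per_chrom = 8, markers_per_block = 2,
                     ld_within = 0, n_qtl_blocks = 1)
    panel <- simulate_marker_panel(cfg)
    m <- ncol(panel$dosage)
    mean(vapply(seq_len(m - 1),
                function(j) compute_ld_r2(panel, j, j + 1), 0))
  }, 0)
  expect_lt(mean(r2s), 0.05)
})

test_that("generated markers respect the MAF bounds and the map is sorted", {
  cfg <- small_cfg(seed = 11, maf_range = c(0.05, 0.5))
  panel <- simulate_marker_panel(cfg)
  expect_true(all(panel$maf >= 0.05 & panel$maf <= 0.5))
  for (ch in unique(panel$map$chrom))
    expect_false(is.unsorted(panel$map$pos[panel$map$chrom == ch],
                             strictly = TRUE))
})

test_that("high LD with jittered MAFs fails loudly when unattainable", {
  cfg <- small_cfg(seed = 2, ld_within = 0.99, maf_jitter = 0.2,
                   maf_range = c(0.05, 0.5))
  expect_error(simulate_marker_panel(cfg), "unattainable")
})

test_that("panel generation is reproducible from config + seed", {
  p1 <- simulate_marker_panel(small_cfg(seed = 9))
  p2 <- simulate_marker_panel(small_cfg(seed = 9))
  expect_identical(p1$dosage, p2$dosage)
  expect_identical(p1$map, p2$map)
  p3 <- simulate_marker_panel(small_cfg(seed = 10))
  expect_false(identical(p1$dosage, p3$dosage))
})

test_that("qtl_h2 = 1 makes the latent exactly the genic score", {
  cfg <- small_cfg(seed = 5, qtl_h2 = 1)
  panel <- simulate_marker_panel(cfg)
  g <- simulate_genetic_effects(panel, cfg)
  Zc <- scale(panel$dosage, scale = FALSE)
  for (tr in colnames(g$latents))
    expect_equal(g$latents[, tr], drop(Zc %*% g$effects[, tr]),
                 tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("equal-effect QTL blocks share genic variance equally", {
  shares <- t(vapply(1:60, function(s) {
    cfg <- small_cfg(seed = s, qtl_h2 = 1)
    panel <- simulate_marker_panel(cfg)
    g <- simulate_genetic_effects(panel, cfg)
    Zc <- scale(panel$dosage, scale = FALSE)
    tb <- panel$true_blocks$block
    picked <- g$qtl_blocks$biomass
    v <- vapply(picked, function(b) {
      idx <- which(tb == b)
      stats::var(drop(Zc[, idx, drop = FALSE] %*% g$effects[idx, "biomass"]))
    }, 0)
    v / sum(v)
  }, numeric(3)))
  expect_equal(colMeans(shares), rep(1 / 3, 3), tolerance = 0.02)
})

test_that("zero planted QTL yield a purely environmental trait", {
  cfg <- small_cfg(seed = 4, n_qtl_blocks = 0)
  panel <- simulate_marker_panel(cfg)
  g <- simulate_genetic_effects(panel, cfg)
  expect_true(all(g$effects == 0))
  expect_equal(unname(apply(g$latents, 2, stats::var)), rep(1, 5),
               tolerance = 1e-12)
})

test_that("trial layout errors when the grid cannot hold the plots", {
  cfg <- trial_cfg(seed = 1, n_rows = 5, n_cols = 5)
  panel <- simulate_marker_panel(cfg)
  g <- simulate_genetic_effects(panel, cfg)
  expect_error(simulate_field_trial(panel, g, cfg), "cannot hold 120 plots")
})

test_that("without spatial structure plot residuals are uncorrelated", {
  cfg <- trial_cfg(seed = 8, rho_row = 0, rho_col = 0, sigma2_spatial = 0,
                   sigma2_rep = 0)
  panel <- simulate_marker_panel(cfg)
  g <- simulate_genetic_effects(panel, cfg)
  tr <- simulate_field_trial(panel, g, cfg)
  obs <- flowering_obs(tr)
  res <- stats::resid(stats::lm(y ~ genotype, data = obs))
  grid <- matrix(NA_real_, max(obs$row), max(obs$col))
  grid[cbind(obs$row, obs$col)] <- res
  lag1 <- stats::cor(as.vector(grid[-1, ]), as.vector(grid[-nrow(grid), ]),
                     use = "complete.obs")
  expect_lt(abs(lag1), 0.15)
})

test_that("the spatial field generator reproduces its AR1 correlations", {
  lags <- vapply(1:50, function(s) {
    set.seed(s)
    E <- phenoroot:::ar1_field(20, 12, 0.5, 0.3)
    stats::cor(as.vector(E[-1, ]), as.vector(E[-20, ]))
  }, 0)
  expect_equal(mean(lags), 0.5, tolerance = 0.05)
})

test_that("root counts decline with depth and biomass grows across stages", {
  cfg <- trial_cfg(seed = 2)
  panel <- simulate_marker_panel(cfg)
  g <- simulate_genetic_effects(panel, cfg)
  tr <- simulate_field_trial(panel, g, cfg)
  m <- tapply(tr$rootcounts$count, tr$rootcounts$depth, mean)
  expect_gt(m[["10"]], m[["170"]])
  expect_true(all(tr$rootcounts$count >= 0))
  bm <- tapply(tr$biomass$biomass, tr$biomass$das, mean)
  expect_true(all(diff(bm[order(as.numeric(names(bm)))]) > 0))
})

test_that("one set of line latents feeds trial, roots and features", {
  cfg <- trial_cfg(seed = 6)
  panel <- simulate_marker_panel(cfg)
  g <- simulate_genetic_effects(panel, cfg)
  tr <- simulate_field_trial(panel, g, cfg)
  expect_equal(tr$truth$latents,
               g$latents[tr$plots$genotype, ], ignore_attr = TRUE)
})

test_that("noise-free invertible loadings make latents recoverable", {
  L <- diag(5) + 0.1
  colnames(L) <- sprintf("f%d", 1:5)
  cfg <- trial_cfg(seed = 3, vi_loading_matrix = L, vi_noise_sd = 0,
                   vi_phenology_sd = 0)
  panel <- simulate_marker_panel(cfg)
  g <- simulate_genetic_effects(panel, cfg)
  tr <- simulate_field_trial(panel, g, cfg)
  feat <- simulate_vi_features(tr, g, cfg)
  rec <- as.matrix(feat[, -1]) %*% solve(L)
  expect_equal(rec, unname(g$latents[tr$plots$genotype, ]),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("duplicated loading columns create near-duplicate features", {
  L <- matrix(rnorm(5 * 4), 5, 4)
  L <- cbind(L, L[, 4])
  colnames(L) <- c("fa", "fb", "fc", "fd", "fd_copy")
  cfg <- trial_cfg(seed = 3, vi_loading_matrix = L, vi_noise_sd = 0.01,
                   vi_phenology_sd = 0)
  panel <- simulate_marker_panel(cfg)
  g <- simulate_genetic_effects(panel, cfg)
  tr <- simulate_field_trial(panel, g, cfg)
  feat <- simulate_vi_features(tr, g, cfg)
  expect_gt(stats::cor(feat$fd, feat$fd_copy), 0.99)
})

test_that("plot images have exact cover, cooler canopy, and bounded bands", {
  cfg <- trial_cfg(seed = 4)
  panel <- simulate_marker_panel(cfg)
  g <- simulate_genetic_effects(panel, cfg)
  tr <- simulate_field_trial(panel, g, cfg)
  expect_error(simulate_plot_images(tr, cfg, cover = 1.4), "\\[0, 1\\]")
  imgs <- simulate_plot_images(tr, cfg, cover = 0.5)
  im <- imgs[[1]]
  expect_identical(dimnames(im$data)[[3]],
                   c("blue", "green", "red", "rededge", "nir", "thermal"))
  refl <- im$data[, , 1:5]
  expect_true(all(refl >= 0 & refl <= 1.5))
  nir <- im$data[, , "nir"]
  veg <- nir > 0.4
  expect_equal(mean(veg), 0.5, tolerance = 0.01)
  expect_lt(mean(im$data[, , "thermal"][veg]),
            mean(im$data[, , "thermal"][!veg]) - 4)
})
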