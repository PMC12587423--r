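test_that("marker QC applies the inclusive MAF cut and the het cut", {
  n <- 50
  d_maf04 <- c(rep(2L, 2), rep(0L, n - 2))            # MAF 0.04 -> out
  d_maf05 <- c(rep(2L, 2), 1L, rep(0L, n - 3))        # MAF 0.05 -> out
  d_maf06 <- c(rep(2L, 3), rep(0L, n - 3))            # MAF 0.06 -> kept
  d_het12 <- c(rep(1L, 6), rep(2L, 20), rep(0L, n - 26))  # 12% het -> out
  d_ok <- c(rep(2L, 20), rep(0L, n - 20))
  panel <- toy_panel(cbind(a = d_maf04, b = d_maf05, c = d_maf06,
                           d = d_het12, e = d_ok))
  qc <- qc_markers(panel)
  expect_identical(colnames(qc$dosage), c("c", "e"))
  expect_setequal(qc$qc_report$marker, c("a", "b", "d"))
  expect_identical(qc$qc_report$reason[qc$qc_report$marker == "d"], "het")
  expect_error(qc_markers(toy_panel(cbind(x = d_maf04))), "every marker")
  panel_na <- panel
  panel_na$dosage[1, 1] <- NA
  expect_error(qc_markers(panel_na), "missing")
})

test_that("LD r2 matches hand arithmetic and is sign free", {
  x1 <- c(0, 2, 2, 0, 1, 2)
  x2 <- c(0, 2, 0, 0, 1, 2)
  panel <- toy_panel(cbind(m1 = x1, m2 = x2, m3 = 2 - x1))
  expect_equal(compute_ld_r2(panel, "m1", "m3"), 1)   # mirrored coding
  # arithmetic oracle: correlation from explicit sums
  n <- 6
  sxy <- sum(x1 * x2) - sum(x1) * sum(x2) / n
  sxx <- sum(x1^2) - sum(x1)^2 / n
  syy <- sum(x2^2) - sum(x2)^2 / n
  expect_equal(compute_ld_r2(panel, "m1", "m2"), sxy^2 / (sxx * syy))
  mono <- toy_panel(cbind(m1 = x1, m2 = rep(2, 6)))
  expect_error(compute_ld_r2(mono, "m1", "m2"), "monomorphic")
})

test_that("block chaining handles perfect LD, independence and tolerance", {
  set.seed(1)
  base <- rbinom(100, 1, 0.4) * 2L
  perfect <- toy_panel(matrix(rep(base, 6), ncol = 6))
  bl <- assign_ld_blocks(perfect)
  expect_equal(nrow(bl$blocks), 1L)
  expect_equal(bl$blocks$n_markers, 6L)
  indep <- toy_panel(sapply(1:8, function(i) rbinom(100, 1, 0.5) * 2L))
  bli <- assign_ld_blocks(indep)
  expect_equal(nrow(bli$blocks), 8L)
  expect_true(all(bli$blocks$n_markers == 1L))
  # one sub-threshold marker bridged when a later marker re-qualifies
  noisy <- base
  flip <- sample(100, 45)
  noisy[flip] <- 2L - noisy[flip]
  bridge <- toy_panel(cbind(m1 = base, m2 = noisy, m3 = base))
  blb <- assign_ld_blocks(bridge, tolerance = 1)
  expect_equal(blb$assignment$block, c(1L, 1L, 1L))
  # tolerance 0 closes the block instead
  bl0 <- assign_ld_blocks(bridge, tolerance = 0)
  expect_equal(bl0$assignment$block[1], 1L)
  expect_gt(max(bl0$assignment$block), 1L)
  unsorted <- bridge
  unsorted$map$pos <- rev(unsorted$map$pos)
  expect_error(assign_ld_blocks(unsorted), "sorted")
})

test_that("blocks partition the markers of random panels", {
  for (s in 1:5) {
    cfg <- small_cfg(seed = s)
    panel <- simulate_marker_panel(cfg)
    qc <- qc_markers(panel)
    bl <- assign_ld_blocks(qc)
    expect_identical(bl$assignment$marker, qc$map$marker)
    expect_true(all(bl$assignment$block > 0))
    expect_equal(sum(bl$blocks$n_markers), ncol(qc$dosage))
    # blocks are contiguous runs within a chromosome
    expect_true(all(diff(bl$assignment$block) %in% c(0L, 1L)))
    by_block <- split(qc$map$chrom, bl$assignment$block)
    expect_true(all(vapply(by_block,
                           function(ch) length(unique(ch)) == 1L, TRUE)))
  }
})

test_that("planted LD blocks are recovered from the simulated panel", {
  hits <- vapply(1:3, function(s) {
    cfg <- small_cfg(seed = s)
    panel <- simulate_marker_panel(cfg)
    qc <- qc_markers(panel)
    bl <- assign_ld_blocks(qc)
    tb <- qc$true_blocks$block
    mean(vapply(unique(tb), function(b) {
      idx <- which(tb == b)
      a <- bl$assignment$block[idx]
      length(unique(a)) == 1L && sum(bl$assignment$block == a[1]) ==
        length(idx)
    }, TRUE))
  }, 0)
  expect_gte(mean(hits), 0.95)
})

test_that("ridge-regression BLUP shrinks and recovers planted effects", {
  cfg <- small_cfg(seed = 3, n_lines = 120)
  panel <- simulate_marker_panel(cfg)
  g <- simulate_genetic_effects(panel, cfg)
  qc <- qc_markers(panel)
  blues <- data.frame(genotype = rownames(g$latents),
                      blue = g$latents[, "biomass"])
  huge <- fit_rrblup(qc, blues, lambda = 1e8)
  expect_lt(max(abs(huge$effects)), 1e-3)
  rr <- fit_rrblup(qc, blues)
  inside <- qc$true_blocks$block %in% g$qtl_blocks$biomass
  expect_gt(mean(abs(rr$effects[inside])), 2 * mean(abs(rr$effects[!inside])))
  expect_error(fit_rrblup(qc, blues[1:10, ]), "at least 30")
})

test_that("LGEBVs sum hand-worked toys and conserve the total GEBV", {
  dosage <- rbind(c(0, 2, 2, 0, 1),
                  c(2, 2, 0, 0, 1),
                  c(0, 0, 2, 2, 2),
                  c(2, 0, 0, 2, 0))
  panel <- toy_panel(dosage)
  dosage <- panel$dosage            # named copy
  # force a known block structure: {1,2}, {3}, {4,5}
  blocks <- structure(list(
    blocks = data.frame(block = 1:3, chrom = 1L,
                        start = c(1e5, 3e5, 4e5), end = c(2e5, 3e5, 5e5),
                        n_markers = c(2L, 1L, 2L)),
    assignment = data.frame(marker = colnames(dosage),
                            block = c(1L, 1L, 2L, 3L, 3L)),
    ld_threshold = 0.7, tolerance = 3L), class = "ld_blocks")
  u <- c(0.5, -1, 2, 0.25, -0.5)
  names(u) <- colnames(dosage)
  lg <- compute_lgebv(u, panel, blocks)
  Zc <- scale(dosage, scale = FALSE)
  expected_b1 <- drop(Zc[, 1:2] %*% u[1:2])
  expect_equal(lg$lgebv[1, ], expected_b1, ignore_attr = TRUE)
  expect_equal(lg$lgebv[2, ], drop(Zc[, 3] * u[3]), ignore_attr = TRUE)
  # single-marker block: variance = effect^2 * var(dosage)
  expect_equal(lg$block_stats$variance[2],
               unname(u[3]^2 * stats::var(dosage[, 3])))
  # conservation: block LGEBVs sum to the line's total GEBV
  expect_equal(colSums(lg$lgebv), drop(Zc %*% u), ignore_attr = TRUE,
               tolerance = 1e-12)
  # all-zero effects give all-zero LGEBVs
  lg0 <- compute_lgebv(setNames(rep(0, 5), names(u)), panel, blocks)
  expect_true(all(lg0$lgebv == 0) && all(lg0$block_stats$variance == 0))
})

test_that("block selection flags by scaled variance with the max on top", {
  dosage <- sapply(1:6, function(i) rbinom(80, 1, 0.5) * 2L)
  panel <- toy_panel(dosage)
  bl <- assign_ld_blocks(panel)
  u <- setNames(c(2, 0.1, 0.1, 0.5, 0.1, 0.1), colnames(panel$dosage))
  lg <- compute_lgebv(u, panel, bl)
  sel <- select_blocks(lg)
  expect_equal(sel$scaled_variance[1], 1)
  expect_true(all(diff(sel$scaled_variance) <= 0))
  only_max <- select_blocks(lg, scaled_threshold = 1)
  expect_equal(nrow(only_max), 1L)
  expect_equal(attr(sel, "selection_fraction"),
               nrow(sel) / nrow(lg$block_stats))
})

test_that("modified Rogers distance matches hand values and its range", {
  dosage <- rbind(A = c(0, 2, 2), B = c(2, 0, 2), C = c(1, 1, 0))
  D <- modified_rogers_distance(toy_panel(dosage))
  expect_equal(unname(diag(D)), rep(0, 3))
  expect_equal(D["A", "B"], sqrt(2 / 3))
  expect_equal(D["A", "C"], sqrt(0.5))
  expect_equal(D, t(D))
  opposite <- toy_panel(rbind(A = c(0, 0, 0, 0), B = c(2, 2, 2, 2)))
  expect_equal(modified_rogers_distance(opposite)["A", "B"], 1)
  dup <- toy_panel(rbind(A = c(0, 2, 1), B = c(0, 2, 1)))
  expect_equal(modified_rogers_distance(dup)["A", "B"], 0)
})

test_that("population clustering separates planted subpopulations", {
  skip_if_not_installed("mclust")
  sp <- subpop_panel(seed = 2)
  D <- modified_rogers_distance(sp$panel)
  res <- cluster_population(D, k = 3, seed = 1)
  expect_gte(adjusted_rand_index(res$kmeans_cluster, sp$labels), 0.9)
  expect_gte(adjusted_rand_index(res$ward_cluster, sp$labels), 0.9)
  res1 <- cluster_population(D, k = 1)
  expect_true(all(res1$kmeans_cluster == 1))
  expect_error(cluster_population(D, k = 1000), "exceeds")
  # duplicated lines land in the same cluster
  pan2 <- sp$panel
  pan2$dosage <- rbind(pan2$dosage, dupline = pan2$dosage[1, ])
  D2 <- modified_rogers_distance(pan2)
  res2 <- cluster_population(D2, k = 3, seed = 1)
  expect_equal(unname(res2$kmeans_cluster["dupline"]),
               unname(res2$kmeans_cluster[1]))
})
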