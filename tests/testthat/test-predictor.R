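test_that("stratified splits honor proportions, determinism and contracts", {
  sp <- split_train_test(100, strata = rep(c("a", "b"), each = 50),
                         fraction = 0.8, seed = 1)
  expect_length(sp$train, 80)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), 1:100)
  expect_equal(sum(sp$train <= 50), 40)
  expect_identical(sp, split_train_test(100, rep(c("a", "b"), each = 50),
                                        0.8, seed = 1))
  sp2 <- split_train_test(100, rep(c("a", "b"), each = 50), 0.8, seed = 2)
  expect_false(identical(sp$train, sp2$train))
  # uneven strata: per-stratum train counts within one of the fraction
  spu <- split_train_test(20, strata = rep(c("a", "b"), c(7, 13)),
                          fraction = 0.8, seed = 3)
  expect_true(sum(spu$train <= 7) %in% 5:6)
  expect_true(sum(spu$train > 7) %in% 10:11)
  expect_error(split_train_test(3, strata = c("a", "a", "b")), "size 1")
})

test_that("full-rank PLSR equals ordinary least squares", {
  set.seed(1)
  X <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(NULL, paste0("x", 1:3)))
  y <- drop(X %*% c(1, -2, 0.5)) + rnorm(20, 0, 0.1)
  fit <- fit_plsr(X, y, 3)
  ols <- stats::lm(y ~ X)
  expect_equal(unname(fit$coef), unname(coef(ols)[-1]), tolerance = 1e-8)
  expect_equal(predict(fit, X), unname(fitted(ols)), tolerance = 1e-8)
  expect_error(fit_plsr(X, y, 4), "1..ncol")
  expect_error(fit_plsr(cbind(X, x4 = X[, 1]), y, 4), "exceeds rank")
})

test_that("with orthonormal predictors the first weight follows X'y", {
  set.seed(2)
  Q <- qr.Q(qr(matrix(rnorm(30 * 4), 30, 4)))
  colnames(Q) <- paste0("q", 1:4)
  y <- rnorm(30)
  fit <- fit_plsr(Q, y, 1)
  Xs <- scale(Q)
  w_ref <- crossprod(Xs, y - mean(y))
  w_ref <- w_ref / sqrt(sum(w_ref^2))
  expect_equal(abs(fit$W[, 1]), abs(drop(w_ref)), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("LOOCV picks the intrinsic dimension and handles tiny data", {
  set.seed(3)
  T2 <- matrix(rnorm(40 * 2), 40, 2)
  W <- matrix(rnorm(2 * 6), 2, 6)
  X <- T2 %*% W                    # predictors of exact intrinsic rank 2
  colnames(X) <- paste0("v", 1:6)
  y <- drop(T2 %*% c(1, -1))
  expect_equal(tune_ncomp(X, y)$ncomp, 2)
  # n = 5, p = 3: every fold has 4 training rows and it completes
  Xs <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, paste0("s", 1:3)))
  expect_no_error(tune_ncomp(Xs, rnorm(5)))
})

test_that("pure-noise responses keep the selected component count small", {
  small <- vapply(1:50, function(s) {
    set.seed(s)
    X <- matrix(rnorm(30 * 8), 30, 8, dimnames = list(NULL, paste0("n", 1:8)))
    tune_ncomp(X, rnorm(30))$ncomp <= 2
  }, TRUE)
  expect_gte(mean(small), 0.9)
})

test_that("importance ranks the informative feature first", {
  top <- vapply(1:50, function(s) {
    set.seed(s)
    X <- matrix(rnorm(60 * 10), 60, 10,
                dimnames = list(NULL, paste0("f", 1:10)))
    y <- 3 * X[, 5] + rnorm(60, 0, 0.3)
    fit <- fit_plsr(X, y, 2)
    variable_importance(fit)$feature[1] == "f5"
  }, TRUE)
  expect_gte(mean(top), 0.95)
})

test_that("importance is symmetric for duplicates and reduces at ncomp 1", {
  set.seed(4)
  X <- matrix(rnorm(60 * 6), 60, 6, dimnames = list(NULL, paste0("f", 1:6)))
  X <- cbind(X, f3b = X[, 3])
  y <- X[, 3] + rnorm(60, 0, 0.5)
  vi <- variable_importance(fit_plsr(X, y, 2))
  expect_lt(abs(vi$score[vi$feature == "f3"] -
                  vi$score[vi$feature == "f3b"]), 1e-10)
  fit1 <- fit_plsr(X[, 1:6], y, 1)
  vi1 <- variable_importance(fit1)
  expect_identical(vi1$feature,
                   colnames(X[, 1:6])[order(-abs(fit1$W[, 1]))])
})

test_that("greedy selection decorrelates and stops at the elbow", {
  set.seed(5)
  X <- matrix(rnorm(80 * 6), 80, 6, dimnames = list(NULL, paste0("f", 1:6)))
  X <- cbind(X, f1copy = X[, 1] + rnorm(80, 0, 0.01))
  y <- 2 * X[, 1] + rnorm(80, 0, 0.3)
  vi <- variable_importance(fit_plsr(X, y, 2))
  sel <- select_top_variables(vi, X, y)
  expect_false(all(c("f1", "f1copy") %in% sel))
  # known structure: 3 informative + many noise features
  sizes <- vapply(1:10, function(s) {
    set.seed(s)
    Xs <- matrix(rnorm(100 * 33), 100, 33,
                 dimnames = list(NULL, paste0("v", 1:33)))
    ys <- drop(Xs[, 1:3] %*% c(3, 2.5, 2)) + rnorm(100, 0, 0.3)
    f <- fit_plsr(Xs, ys, tune_ncomp(Xs, ys)$ncomp)
    ss <- select_top_variables(variable_importance(f), Xs, ys)
    cm <- abs(stats::cor(Xs[, ss, drop = FALSE]))
    diag(cm) <- 0
    expect_lt(max(cm), 0.8)
    length(ss)
  }, 0)
  expect_true(all(abs(sizes - 3) <= 1))
})

test_that("random forests satisfy their basic contracts", {
  set.seed(6)
  X <- matrix(rnorm(120 * 5), 120, 5, dimnames = list(NULL, paste0("x", 1:5)))
  expect_error(fit_rf(X, rnorm(120), mtry_grid = 10), "exceed")
  rf_const <- fit_rf(X, rep(2, 120), seed = 1)
  expect_equal(stats::sd(predict(rf_const, X)), 0, tolerance = 1e-12)
  y_step <- ifelse(X[, 2] > 0, 5, 0) + rnorm(120, 0, 0.3)
  rf <- fit_rf(X, y_step, seed = 1)
  expect_gt(evaluate(y_step, predict(rf, X))$r2, 0.8)
})

test_that("the tree ensemble beats a single tree out of sample", {
  wins <- vapply(1:20, function(s) {
    set.seed(s)
    X <- matrix(rnorm(150 * 4), 150, 4,
                dimnames = list(NULL, paste0("x", 1:4)))
    y <- X[, 1]^2 + X[, 2] + rnorm(150, 0, 0.5)
    tr <- 1:100; te <- 101:150
    big <- fit_rf(X[tr, ], y[tr], n_trees = 150, mtry_grid = 2, seed = s)
    one <- fit_rf(X[tr, ], y[tr], n_trees = 1, mtry_grid = 2, seed = s)
    rmse <- function(m) sqrt(mean((y[te] - predict(m, X[te, ]))^2))
    rmse(big) <= rmse(one)
  }, TRUE)
  expect_gte(mean(wins), 0.9)
})

test_that("metrics match their definitions and identities", {
  m <- evaluate(c(1, 2, 3), c(1, 2, 4))
  expect_equal(m$rmse, sqrt(1 / 3))
  expect_equal(m$rrmse, sqrt(1 / 3) / 2 * 100)
  expect_equal(m$r2, 0.5)
  perfect <- evaluate(1:10, 1:10)
  expect_equal(c(perfect$r2, perfect$rmse, perfect$rrmse), c(1, 0, 0))
  # predicting the mean gives exactly zero R2
  y <- rnorm(20, 5)
  expect_equal(evaluate(y, rep(mean(y), 20))$r2, 0, tolerance = 1e-12)
  # rRMSE * mean / 100 recovers RMSE exactly
  yhat <- y + rnorm(20, 0, 0.5)
  mm <- evaluate(y, yhat)
  expect_equal(mm$rrmse * mean(y) / 100, mm$rmse, tolerance = 1e-12)
  # R2 is invariant under a shared affine rescaling
  m2 <- evaluate(3 * y + 7, 3 * yhat + 7)
  expect_equal(m2$r2, mm$r2, tolerance = 1e-12)
  expect_warning(evaluate(rep(1, 5), rnorm(5)), "zero observed variance")
})

test_that("panel prediction reproduces fitted values and names gaps", {
  set.seed(7)
  X <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- X[, 1] - X[, 2] + rnorm(50, 0, 0.2)
  model <- train_predictor(X, y, model = "plsr_allvars")
  feats <- data.frame(plot_id = sprintf("P%02d", 1:50), X,
                      check.names = FALSE)
  preds <- predict_panel(model, feats)
  expect_equal(preds$predicted, predict(model, X))
  expect_error(predict_panel(model, feats[, 1:3]), "f3")
})

test_that("permuted features carry no predictive signal", {
  cors <- vapply(1:10, function(s) {
    set.seed(s)
    X <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("f", 1:5)))
    y <- X[, 1] + rnorm(60, 0.1)
    model <- train_predictor(X, y, model = "plsr_allvars")
    Xperm <- apply(X, 2, sample)
    colnames(Xperm) <- colnames(X)
    abs(cor(predict(model, Xperm), y))
  }, 0)
  expect_lt(mean(cors), 0.15)
})

test_that("end-to-end trait recovery holds at the generator's SNR", {
  # Pooled-stage biomass: the plot observations carry ~14% field noise, so
  # the attainable held-out R2 has a ceiling near 0.95; the workflow must
  # land close to it, averaged over splits.
  r2s <- vapply(1:6, function(s) {
    cfg <- small_cfg(seed = 800 + s, n_lines = 50, n_rows = 10,
                     n_cols = 20, n_reps = 4)
    panel <- simulate_marker_panel(cfg)
    g <- simulate_genetic_effects(panel, cfg)
    core <- simulate_field_trial(panel, g, cfg)
    feat <- simulate_vi_features(core, g, cfg)
    bmerged <- merge(core$biomass, feat, by = "plot_id")
    bX <- NULL; by <- NULL; bs <- NULL
    for (das in unique(bmerged$das)) {
      sub <- bmerged[bmerged$das == das, ]
      cols <- grep(paste0("_", das, "$"), names(sub), value = TRUE)
      Xs <- as.matrix(sub[, cols])
      colnames(Xs) <- sub(paste0("_", das, "$"), "", cols)
      bX <- rbind(bX, Xs); by <- c(by, sub$biomass)
      bs <- c(bs, as.character(sub$stage))
    }
    sp <- split_train_test(length(by), strata = bs, seed = s)
    m <- train_predictor(bX[sp$train, ], by[sp$train],
                         model = "plsr_topvars")
    evaluate(by[sp$test], predict(m, bX[sp$test, ]))$r2
  }, 0)
  expect_gte(mean(r2s), 0.85)
  # Root proxies: predictions for unseen plots must track the true latents
  cfg <- trial_cfg(seed = 77)
  panel <- simulate_marker_panel(cfg)
  g <- simulate_genetic_effects(panel, cfg)
  core <- simulate_field_trial(panel, g, cfg)
  feat <- simulate_vi_features(core, g, cfg)
  X <- as.matrix(feat[, -1])
  prox <- root_proxies_by_plot(core$rootcounts)
  prox <- prox[match(core$plots$plot_id, prox$plot_id), ]
  for (tr in c("auc_0_20", "auc_20_60")) {
    sp <- split_train_test(nrow(X), seed = 11)
    mt <- train_predictor(X[sp$train, ], prox[[tr]][sp$train],
                          model = "plsr_topvars")
    pred <- predict(mt, X)
    latent <- g$latents[core$plots$genotype, sub("auc", "root", tr)]
    expect_gt(cor(pred, latent), 0.9)
    # plot-level proxies carry count + spatial noise; on 24 held-out plots
    # the R2 estimate is coarse — require only clear predictive signal
    expect_gt(evaluate(prox[[tr]][sp$test],
                       predict(mt, X[sp$test, ]))$r2, 0)
  }
})
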