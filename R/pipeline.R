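#' Pipeline configuration
#'
#' Resolves every stage parameter of the end-to-end synthetic workflow into
#' one object that round-trips losslessly through YAML. Defaults follow the
#' workflow's canonical settings: 80/20 stratified split, importance
#' correlation filter r = 0.8, LD threshold 0.7 with marker tolerance 3,
#' scaled-variance selection at 0.2, 150 trees with minimum node size 5.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param outdir output directory for artifacts (created if needed).
#' @param sim a [sim_config()] or a named list of overrides for it. The
#'   simulated panel is the line pool; its grid fields describe the
#'   intensively phenotyped coring trial.
#' @param n_core_lines lines in the coring (training) trial.
#' @param yield_n_lines,yield_n_reps,yield_n_rows,yield_n_cols the broader
#'   yield-trial panel actually grown and predicted.
#' @param model prediction model for the panel (`"plsr_topvars"` is the
#'   workflow default; see [train_predictor()]).
#' @param image_flight_day day-after-sowing label for the image-derived
#'   features.
#' @param maf_cut,het_cut marker QC thresholds.
#' @param ld_threshold,ld_tolerance LD-block parameters.
#' @param select_threshold scaled-variance cutoff for the haplotype scan.
#' @param r_threshold,elbow_delta variable-selection parameters.
#' @param split_fraction training fraction.
#' @param k_clusters clusters for population structure.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, outdir = NULL, sim = list(),
                            n_core_lines = 20L,
                            yield_n_lines = 120L, yield_n_reps = 2L,
                            yield_n_rows = 16L, yield_n_cols = 15L,
                            model = "plsr_topvars",
                            image_flight_day = 88L,
                            maf_cut = 0.05, het_cut = 0.10,
                            ld_threshold = 0.7, ld_tolerance = 3L,
                            select_threshold = 0.2,
                            r_threshold = 0.8, elbow_delta = 0.01,
                            split_fraction = 0.8, k_clusters = 3L) {
  if (inherits(sim, "sim_config")) {
    sim_cfg <- sim
  } else {
    args <- utils::modifyList(list(seed = child_seed(seed, "sim")), sim)
    sim_cfg <- do.call(sim_config, args)
  }
  cfg <- list(seed = as.integer(seed), outdir = outdir, sim = sim_cfg,
              n_core_lines = n_core_lines,
              yield_n_lines = yield_n_lines, yield_n_reps = yield_n_reps,
              yield_n_rows = yield_n_rows, yield_n_cols = yield_n_cols,
              model = model, image_flight_day = image_flight_day,
              maf_cut = maf_cut, het_cut = het_cut,
              ld_threshold = ld_threshold, ld_tolerance = ld_tolerance,
              select_threshold = select_threshold,
              r_threshold = r_threshold, elbow_delta = elbow_delta,
              split_fraction = split_fraction, k_clusters = k_clusters)
  if (cfg$n_core_lines > sim_cfg$n_lines ||
      cfg$yield_n_lines > sim_cfg$n_lines)
    stop("trial line counts exceed the simulated panel size")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration as YAML
#'
#' @param cfg a `pipeline_config`.
#' @param path YAML file path.
#' @return `read_pipeline_config` returns the reconstructed
#'   `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  lst <- unclass(cfg)
  lst$sim <- unclass(lst$sim)
  # write_yaml drops names of named atomic vectors; keep the stage names
  lst$sim$stages <- as.list(lst$sim$stages)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lst <- yaml::yaml.load_file(path)
  sim <- lst$sim
  sim$stages <- unlist(sim$stages)
  lst$sim <- do.call(sim_config, sim)
  do.call(pipeline_config, lst[setdiff(names(lst), character(0))])
}

#' Run the end-to-end synthetic workflow
#'
#' Executes, in order: simulate (panel, genetics, coring + yield trials,
#' vegetation-index features, plot images) -> extract-vi (image features)
#' -> adjust (per-depth spatial detrending of core-break counts) ->
#' root-curves (per-plot P-splines and AUC proxies) -> train (trait models
#' with variable selection on the coring trial) -> predict (traits for the
#' yield panel) -> adjust-predicted (BLUEs and heritability of predicted
#' traits) -> map-haplotypes (marker QC, LD blocks, rrBLUP, LGEBV scan,
#' population structure). If `cfg$outdir` is set, every table is written
#' as CSV beside the resolved configuration and a markdown report.
#'
#' @param cfg a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with all intermediate and final results:
#'   `panel`, `genetics`, `core_trial`, `yield_trial`, `features`,
#'   `proxies`, `models`, `metrics`, `predictions`, `blues`,
#'   `heritability`, `scan`, `structure`, `artifact_paths`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (!quiet) message("[phenoroot] ", ...)
  t0 <- Sys.time()

  ## --- simulate -------------------------------------------------------
  say("simulate: panel + trials")
  sim <- cfg$sim
  panel <- simulate_marker_panel(sim)
  genetics <- simulate_genetic_effects(panel, sim)
  core_lines <- rownames(panel$dosage)[seq_len(cfg$n_core_lines)]
  core_trial <- simulate_field_trial(panel, genetics, sim,
                                     lines = core_lines)
  ycfg <- sim
  ycfg$n_rows <- cfg$yield_n_rows
  ycfg$n_cols <- cfg$yield_n_cols
  ycfg$n_reps <- cfg$yield_n_reps
  ycfg$seed <- child_seed(cfg$seed, "yield")
  validate_sim_config(ycfg)
  yield_lines <- rownames(panel$dosage)[seq_len(cfg$yield_n_lines)]
  yield_trial <- simulate_field_trial(panel, genetics, ycfg,
                                      lines = yield_lines)
  core_feat <- simulate_vi_features(core_trial, genetics, sim)
  yield_feat <- simulate_vi_features(yield_trial, genetics, ycfg)

  ## --- extract-vi -----------------------------------------------------
  say("extract-vi: image features")
  img_feat <- function(trial, tcfg) {
    imgs <- simulate_plot_images(trial, tcfg)
    long <- extract_plot_features(imgs, indices = c("ndvi", "ndre"),
                                  flight_day = cfg$image_flight_day)
    long <- long[grepl("^(osavimasked_|coverage)", long$feature), ]
    wide <- stats::reshape(long, idvar = "plot_id", timevar = "feature",
                           direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    wide
  }
  core_feat <- merge(core_feat, img_feat(core_trial, sim), by = "plot_id",
                     sort = FALSE)
  yield_feat <- merge(yield_feat, img_feat(yield_trial, ycfg),
                      by = "plot_id", sort = FALSE)

  ## --- adjust: spatial detrending of core-break counts ----------------
  say("adjust: per-depth spatial model for root counts")
  rc <- merge(core_trial$rootcounts, core_trial$plots, by = "plot_id",
              sort = FALSE)
  adj_counts <- do.call(rbind, lapply(unique(rc$depth), function(d) {
    sub <- rc[rc$depth == d, ]
    fit <- fit_lmm(data.frame(genotype = sub$genotype, rep = sub$rep,
                              row = sub$row, col = sub$col,
                              plot_id = sub$plot_id, y = sub$count),
                   genotype_as = "fixed")
    adj <- adjust_plot_values(fit)
    data.frame(plot_id = adj$plot_id, depth = d,
               count = pmax(adj$adjusted, 0), stringsAsFactors = FALSE)
  }))

  ## --- root-curves ----------------------------------------------------
  say("root-curves: P-splines and AUC proxies")
  proxies <- root_proxies_by_plot(adj_counts)
  trait_names <- c("auc_total", "auc_0_20", "auc_20_60", "auc_60_100",
                   "auc_100_170")

  ## --- train ----------------------------------------------------------
  say("train: ", cfg$model, " models")
  feat_cols <- setdiff(names(core_feat), "plot_id")
  strip_day <- function(cols, day) {
    hit <- grepl(paste0("_", day, "$"), cols)
    list(cols = cols[hit], renamed = sub(paste0("_", day, "$"), "", cols[hit]))
  }
  bm <- merge(core_trial$biomass, core_feat, by = "plot_id", sort = FALSE)
  stage_days <- unique(bm$das)
  stage_sels <- lapply(stage_days, function(d) strip_day(feat_cols, d))
  empty <- lengths(lapply(stage_sels, `[[`, "cols")) == 0
  if (any(empty))
    stop("no flight-matched features for stage day(s) ",
         paste(stage_days[empty], collapse = ", "))
  common <- Reduce(intersect, lapply(stage_sels, `[[`, "renamed"))
  bm_rows <- do.call(rbind, lapply(split(bm, bm$stage), function(sub) {
    sel <- strip_day(feat_cols, sub$das[1])
    X <- sub[, sel$cols[match(common, sel$renamed)], drop = FALSE]
    names(X) <- common
    cbind(sub[, c("plot_id", "stage", "biomass")], X)
  }))
  bm_X <- as.matrix(bm_rows[, setdiff(names(bm_rows),
                                      c("plot_id", "stage", "biomass"))])
  split_b <- split_train_test(nrow(bm_rows), strata = bm_rows$stage,
                              fraction = cfg$split_fraction,
                              seed = child_seed(cfg$seed, "split_biomass"))
  bm_model <- train_predictor(bm_X[split_b$train, , drop = FALSE],
                              bm_rows$biomass[split_b$train],
                              model = cfg$model,
                              r_threshold = cfg$r_threshold,
                              elbow_delta = cfg$elbow_delta,
                              seed = child_seed(cfg$seed, "rf_biomass"))
  metrics <- rbind(
    cbind(trait = "biomass", split = "train",
          evaluate(bm_rows$biomass[split_b$train],
                   predict(bm_model, bm_X[split_b$train, , drop = FALSE]))),
    cbind(trait = "biomass", split = "test",
          evaluate(bm_rows$biomass[split_b$test],
                   predict(bm_model, bm_X[split_b$test, , drop = FALSE]))))

  rt <- merge(proxies, core_feat, by = "plot_id", sort = FALSE)
  rt_X <- as.matrix(rt[, feat_cols])
  root_models <- list()
  for (tr in trait_names) {
    split_r <- split_train_test(nrow(rt), fraction = cfg$split_fraction,
                                seed = child_seed(cfg$seed,
                                                  paste0("split_", tr)))
    m <- train_predictor(rt_X[split_r$train, , drop = FALSE],
                         rt[[tr]][split_r$train],
                         model = cfg$model,
                         r_threshold = cfg$r_threshold,
                         elbow_delta = cfg$elbow_delta,
                         seed = child_seed(cfg$seed, paste0("rf_", tr)))
    root_models[[tr]] <- m
    metrics <- rbind(metrics,
      cbind(trait = tr, split = "train",
            evaluate(rt[[tr]][split_r$train],
                     predict(m, rt_X[split_r$train, , drop = FALSE]))),
      cbind(trait = tr, split = "test",
            evaluate(rt[[tr]][split_r$test],
                     predict(m, rt_X[split_r$test, , drop = FALSE]))))
  }

  ## --- predict the yield panel ---------------------------------------
  say("predict: yield panel traits")
  ycols <- setdiff(names(yield_feat), "plot_id")
  predictions <- data.frame(plot_id = yield_feat$plot_id,
                            stringsAsFactors = FALSE)
  for (st in names(sim$stages)) {
    sel <- strip_day(ycols, sim$stages[[st]])
    Xn <- yield_feat[, sel$cols, drop = FALSE]
    names(Xn) <- sel$renamed
    predictions[[paste0("biomass_", st)]] <- predict(bm_model, Xn)
  }
  for (tr in trait_names)
    predictions[[tr]] <- predict(root_models[[tr]],
                                 yield_feat[, ycols, drop = FALSE])

  ## --- adjust predicted traits: BLUEs + heritability ------------------
  say("adjust-predicted: BLUEs and H2 on the yield trial")
  ydat <- merge(yield_trial$plots, predictions, by = "plot_id", sort = FALSE)
  pred_traits <- setdiff(names(predictions), "plot_id")
  blues <- list(); herit <- numeric(0)
  for (tr in pred_traits) {
    d <- data.frame(genotype = ydat$genotype, rep = ydat$rep,
                    row = ydat$row, col = ydat$col, y = ydat[[tr]])
    fit_f <- fit_lmm(d, genotype_as = "fixed")
    bt <- compute_blues(fit_f)
    names(bt)[names(bt) == "blue"] <- "blue"
    bt$trait <- tr
    blues[[tr]] <- bt
    fit_r <- fit_lmm(d, genotype_as = "random")
    herit[tr] <- estimate_heritability(fit_r)
  }
  blue_table <- do.call(rbind, blues)
  rownames(blue_table) <- NULL

  ## --- map-haplotypes --------------------------------------------------
  say("map-haplotypes: QC, LD blocks, LGEBV scan")
  qc_panel <- qc_markers(panel, maf_cut = cfg$maf_cut,
                         het_cut = cfg$het_cut)
  sub_panel <- qc_panel
  sub_panel$dosage <- qc_panel$dosage[yield_lines, , drop = FALSE]
  poly <- apply(sub_panel$dosage, 2, stats::sd) > 0
  sub_panel$dosage <- sub_panel$dosage[, poly, drop = FALSE]
  sub_panel$map <- sub_panel$map[poly, , drop = FALSE]
  if (!is.null(sub_panel$true_blocks))
    sub_panel$true_blocks <- sub_panel$true_blocks[poly, , drop = FALSE]
  blocks <- assign_ld_blocks(sub_panel, ld_threshold = cfg$ld_threshold,
                             tolerance = cfg$ld_tolerance)
  scan <- list()
  for (tr in pred_traits) {
    bt <- blues[[tr]]
    rr <- fit_rrblup(sub_panel, bt)
    lg <- compute_lgebv(rr, sub_panel, blocks)
    sel <- select_blocks(lg, scaled_threshold = cfg$select_threshold)
    scan[[tr]] <- list(rrblup = rr, lgebv = lg, selected = sel)
  }
  selected_union <- unique(unlist(lapply(scan, function(s) s$selected$block)))
  mrd <- modified_rogers_distance(sub_panel)
  structure_res <- cluster_population(mrd, k = cfg$k_clusters,
                                      seed = child_seed(cfg$seed, "kmeans"))

  res <- list(panel = panel, genetics = genetics,
              core_trial = core_trial, yield_trial = yield_trial,
              features = list(core = core_feat, yield = yield_feat),
              adjusted_counts = adj_counts, proxies = proxies,
              models = c(list(biomass = bm_model), root_models),
              metrics = metrics, predictions = predictions,
              blues = blue_table, heritability = herit,
              blocks = blocks, scan = scan,
              selected_blocks = selected_union,
              structure = structure_res,
              elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs")),
              config = cfg)
  if (!is.null(cfg$outdir)) res$artifact_paths <- write_artifacts(res, cfg)
  say(sprintf("done in %.1f s; %d haploblocks selected across %d traits",
              res$elapsed, length(selected_union), length(pred_traits)))
  invisible(res)
}

# Persist every pipeline table as plain text under cfg$outdir.
write_artifacts <- function(res, cfg) {
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(cfg$outdir, f)
  wcsv <- function(x, f) {
    utils::write.csv(format(as.data.frame(x), digits = 10, trim = TRUE),
                     p(f), row.names = FALSE, quote = FALSE)
    p(f)
  }
  paths <- c(
    wcsv(res$core_trial$plots, "plots.csv"),
    wcsv(res$core_trial$rootcounts, "rootcounts.csv"),
    wcsv(res$core_trial$biomass, "biomass.csv"),
    wcsv(res$features$core, "features.csv"),
    wcsv(cbind(line = rownames(res$panel$dosage), res$panel$dosage),
         "genotypes.csv"),
    wcsv(res$panel$map, "map.csv"),
    wcsv(res$proxies, "proxies.csv"),
    wcsv(res$metrics, "metrics.csv"),
    wcsv(res$predictions, "predictions.csv"),
    wcsv(res$blues, "blues.csv"),
    wcsv(data.frame(trait = names(res$heritability),
                    h2 = unname(res$heritability)), "heritability.csv"),
    wcsv(res$blocks$blocks, "blocks.csv"),
    wcsv(do.call(rbind, lapply(names(res$scan), function(tr)
      cbind(trait = tr, res$scan[[tr]]$selected))), "selected_blocks.csv"),
    wcsv(data.frame(line = names(res$structure$kmeans_cluster),
                    kmeans = unname(res$structure$kmeans_cluster),
                    ward = unname(res$structure$ward_cluster)),
         "structure.csv"))
  truth <- list(qtl_blocks = res$genetics$qtl_blocks,
                qtl_h2 = res$genetics$qtl_h2,
                seed = cfg$seed)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  write_pipeline_config(cfg, p("config.yaml"))
  rep_lines <- c(
    "# phenoroot pipeline report", "",
    sprintf("Seed: %d; panel %d lines x %d markers.", cfg$seed,
            nrow(res$panel$dosage), ncol(res$panel$dosage)),
    sprintf("Coring trial: %d plots; yield trial: %d plots.",
            nrow(res$core_trial$plots), nrow(res$yield_trial$plots)),
    "", "## Prediction metrics", "",
    utils::capture.output(print(res$metrics, row.names = FALSE)),
    "", "## Heritability of predicted traits", "",
    sprintf("- %s: %.3f", names(res$heritability), res$heritability),
    "", "## Haplotype scan", "",
    sprintf("%d LD blocks (mean %.2f markers/block); %d blocks selected.",
            nrow(res$blocks$blocks), mean(res$blocks$blocks$n_markers),
            length(res$selected_blocks)))
  writeLines(rep_lines, p("report.md"))
  c(paths, p("truth.json"), p("config.yaml"), p("report.md"))
}
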