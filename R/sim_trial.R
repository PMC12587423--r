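#' Simulate a replicated field trial with AR1xAR1 spatial noise
#'
#' Lays out `n_reps` complete replicates of the chosen lines on an
#' `n_rows x n_cols` grid (replicates occupy consecutive runs of plots in
#' column-major order; genotypes are randomized within replicate) and
#' generates, for every plot:
#'
#' * stage-wise shoot dry biomass following a logistic growth curve, with
#'   an additive decomposition `mean + genotype + replicate + row + column +
#'   AR1xAR1 spatial + iid residual` on a stage-scaled unit,
#' * depth-resolved core-break root counts: a declining exponential template
#'   scaled per soil stratum by the line's latent root traits, drawn as
#'   negative-binomial (overdispersed Poisson) counts.
#'
#' The per-line latent traits come from `genetics` and are the same values
#' the vegetation-index generator uses, so every downstream stage sees one
#' source of truth.
#'
#' @param panel a [simulate_marker_panel()] result.
#' @param genetics a [simulate_genetic_effects()] result.
#' @param cfg the [sim_config()].
#' @param lines character vector of line ids to grow (default: all panel
#'   lines). The grid must hold `length(lines) * n_reps` plots.
#' @param n_reps number of complete replicates (default `cfg$n_reps`).
#' @return object of class `field_trial`: list with data.frames `plots`
#'   (plot_id, row, col, rep, genotype), `rootcounts` (plot_id, depth,
#'   count), `biomass` (plot_id, stage, das, biomass), and a `truth` list
#'   (per-plot spatial/residual draws and per-line genotype values) kept
#'   for recovery testing.
#' @export
simulate_field_trial <- function(panel, genetics, cfg,
                                 lines = rownames(panel$dosage),
                                 n_reps = cfg$n_reps) {
  stopifnot(inherits(panel, "marker_panel"),
            inherits(genetics, "true_genetics"))
  n_lines <- length(lines)
  n_plots <- n_lines * n_reps
  n_cells <- cfg$n_rows * cfg$n_cols
  if (n_cells < n_plots)
    stop(sprintf(paste0("field grid %d x %d = %d cells cannot hold %d plots",
                        " (%d lines x %d reps); enlarge the grid"),
                 cfg$n_rows, cfg$n_cols, n_cells, n_plots, n_lines, n_reps))
  missing_lines <- setdiff(lines, rownames(genetics$latents))
  if (length(missing_lines))
    stop("lines absent from the genetics object: ",
         paste(missing_lines, collapse = ", "))
  set.seed(child_seed(cfg$seed, "trial"))

  # column-major plot enumeration; replicates are consecutive runs
  cells <- data.frame(row = rep(seq_len(cfg$n_rows), times = cfg$n_cols),
                      col = rep(seq_len(cfg$n_cols), each = cfg$n_rows))
  cells <- cells[seq_len(n_plots), , drop = FALSE]
  genotype <- unlist(lapply(seq_len(n_reps), function(m) sample(lines)))
  plots <- data.frame(plot_id = sprintf("P%04d", seq_len(n_plots)),
                      row = cells$row, col = cells$col,
                      rep = rep(seq_len(n_reps), each = n_lines),
                      genotype = genotype, stringsAsFactors = FALSE)

  lat <- genetics$latents[plots$genotype, , drop = FALSE]
  stages <- cfg$stages

  spatial_draw <- function() {
    E <- ar1_field(cfg$n_rows, cfg$n_cols, cfg$rho_row, cfg$rho_col)
    sqrt(cfg$sigma2_spatial) * E[cbind(plots$row, plots$col)] +
      sqrt(cfg$sigma2_resid) * stats::rnorm(n_plots)
  }
  unit_effects <- function() {
    rep_ef <- stats::rnorm(n_reps, 0, sqrt(cfg$sigma2_rep))
    row_ef <- stats::rnorm(cfg$n_rows, 0, sqrt(cfg$sigma2_rowef))
    col_ef <- stats::rnorm(cfg$n_cols, 0, sqrt(cfg$sigma2_colef))
    rep_ef[plots$rep] + row_ef[plots$row] + col_ef[plots$col] + spatial_draw()
  }

  g_bio <- sqrt(cfg$genetic_var) * lat[, "biomass"]
  biomass <- do.call(rbind, lapply(names(stages), function(st) {
    das <- stages[[st]]
    mu <- logistic_biomass(das)
    scale_t <- 0.12 * mu   # stage-proportional unit for all random terms
    data.frame(plot_id = plots$plot_id, stage = st, das = das,
               biomass = pmax(0, mu + scale_t * (g_bio + unit_effects())),
               stringsAsFactors = FALSE)
  }))
  rownames(biomass) <- NULL

  # root counts: exponential decline template scaled per stratum by latents
  depths <- cfg$depth_grid
  template <- 23.2 * exp(-(depths - depths[1]) / 39.4)
  strata <- depth_stratum(depths)
  root_dev <- spatial_draw()   # one plot-level environmental deviation
  root_traits <- c("root_0_20", "root_20_60", "root_60_100", "root_100_170")
  mu_mat <- sapply(seq_along(depths), function(d) {
    m <- exp(0.45 * sqrt(cfg$genetic_var) * lat[, root_traits[strata[d]]] +
               0.1 * root_dev)
    template[d] * m
  })
  counts <- matrix(stats::rnbinom(length(mu_mat),
                                  size = cfg$root_overdispersion,
                                  mu = as.vector(mu_mat)),
                   nrow = n_plots)
  rootcounts <- data.frame(plot_id = rep(plots$plot_id, times = length(depths)),
                           depth = rep(depths, each = n_plots),
                           count = as.vector(counts),
                           stringsAsFactors = FALSE)

  structure(list(plots = plots, rootcounts = rootcounts, biomass = biomass,
                 lines = lines, n_reps = n_reps,
                 truth = list(latents = lat, genotype_biomass = g_bio,
                              root_dev = root_dev),
                 cfg = cfg),
            class = "field_trial")
}

#' @export
print.field_trial <- function(x, ...) {
  cat("field_trial:", nrow(x$plots), "plots (", length(x$lines), "lines x",
      x$n_reps, "reps ) on a", x$cfg$n_rows, "x", x$cfg$n_cols, "grid\n")
  cat("  biomass stages:", paste(unique(x$biomass$stage), collapse = ", "),
      "; depths:", min(x$rootcounts$depth), "-", max(x$rootcounts$depth),
      "cm\n")
  invisible(x)
}

# Mean shoot dry biomass trajectory (g m^-2) over days after sowing:
# logistic growth toward ~600 g m^-2 at maturity, mid-point near heading.
logistic_biomass <- function(das) 600 / (1 + exp(-(das - 72) / 16))

# Which of the four canonical soil strata a core-break depth belongs to.
depth_stratum <- function(depths) {
  findInterval(depths, c(0, 20, 60, 100), left.open = TRUE)
}

# One draw of a unit-variance AR1xAR1 random field on an r x c grid,
# via the Cholesky factors of the two AR1 correlation matrices.
ar1_field <- function(n_rows, n_cols, rho_row, rho_col) {
  Lr <- chol_ar1(n_rows, rho_row)
  Lc <- chol_ar1(n_cols, rho_col)
  Z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  Lr %*% Z %*% t(Lc)
}

chol_ar1 <- function(n, rho) {
  if (n == 1L) return(matrix(1, 1, 1))
  t(chol(ar1_matrix(n, rho)))
}

ar1_matrix <- function(n, rho) {
  rho^abs(outer(seq_len(n), seq_len(n), "-"))
}
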