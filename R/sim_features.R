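#' Simulate plot-level vegetation-index features
#'
#' Generates the feature table a drone campaign plus index extraction would
#' produce, as noisy linear mixtures of the latent shoot/root traits:
#' `feature = latents %*% loadings + N(0, vi_noise_sd^2)`, plus a
#' deterministic canopy-development offset per feature column — a fixed
#' per-index weight times the logistic canopy trajectory evaluated at the
#' column's flight day. The offset is constant across plots within a
#' column (it cancels under centering) but separates flight days the way
#' real indices track canopy growth, which is what makes stage-pooled
#' biomass models learnable. Feature names carry a flight day-after-sowing
#' suffix (e.g. `mean_msavi_118`) so that stage-matched subsets can be
#' selected downstream.
#'
#' @param trial a [simulate_field_trial()] result.
#' @param genetics the matching [simulate_genetic_effects()] result.
#' @param cfg the [sim_config()]. If `cfg$vi_loading_matrix` is `NULL`, a
#'   default latent x feature matrix with unit-norm columns is built, with
#'   six index features per flight day.
#' @return data.frame: `plot_id` plus one numeric column per feature.
#' @export
simulate_vi_features <- function(trial, genetics, cfg) {
  stopifnot(inherits(trial, "field_trial"), inherits(genetics, "true_genetics"))
  lat <- genetics$latents[trial$plots$genotype, , drop = FALSE]
  L <- cfg$vi_loading_matrix
  if (is.null(L)) L <- default_vi_loadings(ncol(lat), cfg$flight_days)
  set.seed(child_seed(cfg$seed, "features"))
  if (nrow(L) != ncol(lat))
    stop(sprintf("vi_loading_matrix has %d rows but there are %d latent traits",
                 nrow(L), ncol(lat)))
  if (is.null(colnames(L)))
    colnames(L) <- sprintf("f%03d", seq_len(ncol(L)))
  feat <- lat %*% L +
    matrix(stats::rnorm(nrow(lat) * ncol(L), 0, cfg$vi_noise_sd),
           nrow(lat), ncol(L))
  phen <- cfg$vi_phenology_sd %||% 0
  if (phen > 0)
    feat <- sweep(feat, 2, phenology_offset(colnames(L), phen), "+")
  out <- data.frame(plot_id = trial$plots$plot_id, feat,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}

# Deterministic per-column canopy-development offset: a fixed weight per
# index base name (stable across flight days) times the normalized logistic
# canopy trajectory at the column's day suffix. Columns without a day
# suffix get no offset.
phenology_offset <- function(feature_names, scale) {
  day <- suppressWarnings(as.numeric(sub("^.*_(\\d+)$", "\\1",
                                         feature_names)))
  base <- sub("_(\\d+)$", "", feature_names)
  ub <- unique(base)
  w <- scale * (0.5 + (seq_along(ub) * 0.6180339887) %% 1)  # fixed weights
  names(w) <- ub
  phase <- 2 * logistic_biomass(ifelse(is.na(day), 72, day)) / 600 - 1
  ifelse(is.na(day), 0, w[base] * phase)
}

# Default loading matrix: one base latent-loading vector per index, reused
# at every flight day with a small day-specific perturbation — an index
# measures the same canopy property whenever it is flown, so its relation
# to the latent traits is stable through the season (which also makes
# same-index features at different days strongly correlated, as real
# multi-flight VI tables are). Columns are unit-norm so each feature has
# unit signal variance on unit-variance latents.
default_vi_loadings <- function(n_latent, flight_days) {
  idx <- c("ndvi", "osavi", "msavi", "ndre", "clre", "temperature")
  set.seed(920341L)   # fixed: the default loading pattern is part of the design
  base <- matrix(stats::rnorm(n_latent * length(idx)), n_latent, length(idx))
  L <- do.call(cbind, lapply(flight_days, function(d) {
    base + 0.2 * matrix(stats::rnorm(n_latent * length(idx)),
                        n_latent, length(idx))
  }))
  L <- sweep(L, 2, sqrt(colSums(L^2)), "/")
  colnames(L) <- as.vector(outer(idx, flight_days,
                                 function(i, d) sprintf("mean_%s_%d", i, d)))
  L
}

#' Simulate multiband plot images
#'
#' Composes, for each plot, a square image mixing a vegetation pixel
#' population (high NIR, low red, cooler) and a soil population (flat
#' spectrum, warmer), with an exact known canopy-cover fraction. Band order
#' is blue, green, red, rededge, nir, thermal; reflectances in `[0, 1.5]`,
#' thermal in degrees C.
#'
#' @param trial a [simulate_field_trial()] result.
#' @param cfg the [sim_config()].
#' @param cover canopy-cover fraction(s) in `[0, 1]`: a scalar, a vector of
#'   length `n_plots`, or `NULL` to derive cover from each line's latent
#'   biomass trait through a logistic link.
#' @return list of `plot_image` objects (one per plot), each a list with
#'   `plot_id`, `data` (H x W x 6 array with band dimnames), `bands`, and
#'   the true `cover` used.
#' @export
simulate_plot_images <- function(trial, cfg, cover = NULL) {
  stopifnot(inherits(trial, "field_trial"))
  n_plots <- nrow(trial$plots)
  if (is.null(cover)) {
    cover <- stats::plogis(0.4 + 0.8 * trial$truth$latents[, "biomass"])
  }
  cover <- rep_len(cover, n_plots)
  if (any(cover < 0 | cover > 1))
    stop("'cover' fractions must lie in [0, 1]")
  set.seed(child_seed(cfg$seed, "images"))
  s <- cfg$image_size
  npix <- s * s
  bands <- c("blue", "green", "red", "rededge", "nir", "thermal")
  veg_mean <- c(blue = 0.06, green = 0.12, red = 0.08, rededge = 0.30,
                nir = 0.50)
  soil_mean <- c(blue = 0.25, green = 0.25, red = 0.25, rededge = 0.25,
                 nir = 0.25)
  lapply(seq_len(n_plots), function(i) {
    n_veg <- round(cover[i] * npix)
    veg_pix <- sample.int(npix, n_veg)
    is_veg <- logical(npix); is_veg[veg_pix] <- TRUE
    arr <- array(0, dim = c(s, s, 6), dimnames = list(NULL, NULL, bands))
    for (b in names(veg_mean)) {
      v <- numeric(npix)
      v[is_veg] <- stats::rnorm(n_veg, veg_mean[[b]], 0.02)
      v[!is_veg] <- stats::rnorm(npix - n_veg, soil_mean[[b]], 0.02)
      arr[, , b] <- pmin(pmax(v, 0), 1.5)
    }
    soil_temp <- 30
    tv <- numeric(npix)
    tv[is_veg] <- stats::rnorm(n_veg, soil_temp - cfg$canopy_temp_offset, 0.5)
    tv[!is_veg] <- stats::rnorm(npix - n_veg, soil_temp, 0.5)
    arr[, , "thermal"] <- tv
    structure(list(plot_id = trial$plots$plot_id[i], data = arr,
                   bands = bands, cover = cover[i]),
              class = "plot_image")
  })
}

#' @export
print.plot_image <- function(x, ...) {
  d <- dim(x$data)
  cat("plot_image", x$plot_id, ":", d[1], "x", d[2], "pixels,",
      d[3], "bands ( true cover", sprintf("%.2f", x$cover), ")\n")
  invisible(x)
}
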