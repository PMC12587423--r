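#' Vegetation-index registry
#'
#' Named list of the implemented per-pixel indices. Each entry holds the
#' bands it needs and the closed-form formula (documented as a string).
#' Normalized-difference indices are bounded in `[-1, 1]`; the raw band
#' "indices" (`r_blue` ... `r_nir`, `temperature`) return the band itself.
#'
#' @format list; see `names(vi_registry())` for the available indices.
#' @return the registry list.
#' @export
vi_registry <- function() {
  nd <- function(a, b) (a - b) / (a + b)
  list(
    ndvi = list(bands = c("nir", "red"),
                formula = "(nir - red) / (nir + red)",
                fn = function(b) nd(b$nir, b$red)),
    osavi = list(bands = c("nir", "red"),
                 formula = "1.16 * (nir - red) / (nir + red + 0.16)",
                 fn = function(b) 1.16 * (b$nir - b$red) /
                   (b$nir + b$red + 0.16)),
    msavi = list(bands = c("nir", "red"),
                 formula = paste0("(2*nir + 1 - sqrt((2*nir + 1)^2",
                                  " - 8*(nir - red))) / 2"),
                 fn = function(b) (2 * b$nir + 1 -
                   sqrt((2 * b$nir + 1)^2 - 8 * (b$nir - b$red))) / 2),
    savi = list(bands = c("nir", "red"),
                formula = "1.5 * (nir - red) / (nir + red + 0.5)",
                fn = function(b) 1.5 * (b$nir - b$red) /
                  (b$nir + b$red + 0.5)),
    mtvi = list(bands = c("nir", "green", "red"),
                formula = "1.2 * (1.2*(nir - green) - 2.5*(red - green))",
                fn = function(b) 1.2 * (1.2 * (b$nir - b$green) -
                                          2.5 * (b$red - b$green))),
    ndre = list(bands = c("nir", "rededge"),
                formula = "(nir - rededge) / (nir + rededge)",
                fn = function(b) nd(b$nir, b$rededge)),
    clre = list(bands = c("nir", "rededge"),
                formula = "nir / rededge - 1",
                fn = function(b) b$nir / b$rededge - 1),
    exg = list(bands = c("green", "red", "blue"),
               formula = "2*green - red - blue",
               fn = function(b) 2 * b$green - b$red - b$blue),
    varigreen = list(bands = c("green", "red", "blue"),
                     formula = "(green - red) / (green + red - blue)",
                     fn = function(b) (b$green - b$red) /
                       (b$green + b$red - b$blue)),
    r_blue = list(bands = "blue", formula = "blue",
                  fn = function(b) b$blue),
    r_green = list(bands = "green", formula = "green",
                   fn = function(b) b$green),
    r_red = list(bands = "red", formula = "red",
                 fn = function(b) b$red),
    r_rededge = list(bands = "rededge", formula = "rededge",
                     fn = function(b) b$rededge),
    r_nir = list(bands = "nir", formula = "nir",
                 fn = function(b) b$nir),
    temperature = list(bands = "thermal", formula = "thermal",
                       fn = function(b) b$thermal)
  )
}

#' Compute a vegetation index per pixel
#'
#' @param image a `plot_image` (see [simulate_plot_images()]) or any list
#'   with a `data` H x W x band array whose third dimnames name the bands.
#' @param name index name; one of `names(vi_registry())`.
#' @return numeric matrix of the image's height x width.
#' @export
compute_index <- function(image, name) {
  reg <- vi_registry()
  if (!name %in% names(reg))
    stop("unknown index '", name, "'; available: ",
         paste(names(reg), collapse = ", "))
  entry <- reg[[name]]
  have <- dimnames(image$data)[[3]]
  missing_b <- setdiff(entry$bands, have)
  if (length(missing_b))
    stop("index '", name, "' needs band(s) ",
         paste(missing_b, collapse = ", "), " absent from the image")
  b <- lapply(have, function(nm) image$data[, , nm])
  names(b) <- have
  entry$fn(b)
}

#' Otsu threshold of a set of values
#'
#' Builds a 256 equal-width-bin histogram over the finite value range and
#' returns the bin boundary maximizing the between-class variance
#' (equivalently minimizing the pooled intra-class variance). Ties are
#' broken toward the lower threshold.
#'
#' @param values numeric vector (NAs dropped); needs at least two distinct
#'   finite values.
#' @param n_bins number of histogram bins (default 256).
#' @return the threshold value (a bin boundary).
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  v <- values[is.finite(values)]
  if (length(v) < 2L || diff(range(v)) == 0)
    stop("Otsu thresholding needs at least two distinct finite values")
  edges <- seq(min(v), max(v), length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, edges, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins = n_bins)
  mids <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  w <- cumsum(h)                       # class-0 counts at each boundary
  m <- cumsum(h * mids)                # class-0 mass
  n <- w[n_bins]; mt <- m[n_bins]
  w0 <- w[-n_bins]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, n_bins - 1L)
  bcv[valid] <- (mt * w0[valid] - n * m[-n_bins][valid])^2 /
    (as.numeric(w0[valid]) * w1[valid])
  k <- which.max(bcv)                  # which.max takes the first (lower) tie
  edges[k + 1L]
}

#' Segment vegetation from soil pixels
#'
#' Computes per-pixel OSAVI, thresholds it with [otsu_threshold()], and
#' labels the upper class as vegetation (regardless of which population is
#' physically vegetation — the mask always selects the high-OSAVI class).
#'
#' Degenerate single-population images (OSAVI range below `min_range`, so
#' Otsu has no separable classes) are classified wholesale by the absolute
#' OSAVI level against `soil_cutoff`: a bare-soil image gets an empty mask
#' (coverage 0, masked statistics undefined downstream), a closed-canopy
#' image a full one.
#'
#' @param image a `plot_image`.
#' @param min_range minimum OSAVI range for two-class thresholding. The
#'   default 0.45 sits well above single-population pixel noise (a few
#'   times the per-pixel reflectance jitter) and well below the
#'   vegetation-soil contrast (~0.7).
#' @param soil_cutoff OSAVI level separating bare soil from canopy in the
#'   single-class fallback.
#' @return list with `mask` (logical matrix, TRUE = vegetation), `coverage`
#'   (vegetation fraction of valid pixels) and `threshold` (NA in the
#'   single-class fallback).
#' @export
mask_vegetation <- function(image, min_range = 0.45, soil_cutoff = 0.25) {
  osavi <- compute_index(image, "osavi")
  if (!any(is.finite(osavi)))
    stop("image has no finite OSAVI pixels; cannot segment")
  rng <- range(osavi[is.finite(osavi)])
  if (diff(rng) < min_range) {
    veg <- stats::median(osavi, na.rm = TRUE) > soil_cutoff
    mask <- array(veg, dim = dim(osavi))
    mask[!is.finite(osavi)] <- NA
    return(list(mask = mask, coverage = mean(mask, na.rm = TRUE),
                threshold = NA_real_))
  }
  thr <- otsu_threshold(osavi)
  mask <- osavi > thr
  mask[!is.finite(osavi)] <- NA
  list(mask = mask, coverage = mean(mask, na.rm = TRUE), threshold = thr)
}

#' Extract plot-level vegetation-index features
#'
#' For every image and requested index, computes the unmasked mean (over
#' all valid pixels) and the OSAVI/Otsu-masked mean (vegetation pixels
#' only), plus the canopy coverage fraction per plot. Feature names follow
#' the `mean_<index>_<day>` / `osavimasked_mean_<index>_<day>` /
#' `coverage_<day>` convention, where `<day>` is the flight day after
#' sowing.
#'
#' @param images list of `plot_image` objects sharing a band set.
#' @param indices character vector of registry index names.
#' @param flight_day integer day-after-sowing suffix for feature names.
#' @param per_index_coverage also emit `coverage_<index>_<day>` features
#'   from index-specific Otsu masks (default FALSE).
#' @return data.frame in long format: `plot_id`, `feature`, `value`.
#'   An empty vegetation mask yields `NA` masked means with a warning,
#'   never zero.
#' @export
extract_plot_features <- function(images, indices = c("ndvi", "osavi",
                                                      "msavi", "ndre"),
                                  flight_day = 0L,
                                  per_index_coverage = FALSE) {
  stopifnot(length(images) >= 1L)
  band_sets <- unique(lapply(images, function(im) dimnames(im$data)[[3]]))
  if (length(band_sets) != 1L)
    stop("images do not share a common band set")
  rows <- lapply(images, function(im) {
    seg <- mask_vegetation(im)
    veg <- which(seg$mask)
    if (length(veg) == 0L)
      warning("plot ", im$plot_id,
              ": empty vegetation mask; masked features set to NA")
    out <- list()
    for (ix in indices) {
      vals <- compute_index(im, ix)
      out[[sprintf("mean_%s_%d", ix, flight_day)]] <-
        mean(vals[is.finite(vals)])
      out[[sprintf("osavimasked_mean_%s_%d", ix, flight_day)]] <-
        if (length(veg)) mean(vals[veg], na.rm = TRUE) else NA_real_
      if (per_index_coverage) {
        thr_ix <- otsu_threshold(vals)
        out[[sprintf("coverage_%s_%d", ix, flight_day)]] <-
          mean(vals > thr_ix, na.rm = TRUE)
      }
    }
    out[[sprintf("coverage_%d", flight_day)]] <- seg$coverage
    data.frame(plot_id = im$plot_id, feature = names(out),
               value = unlist(out, use.names = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
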