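#' Augmentation policy for paired image/mask augmentation
#'
#' Spatial transforms (rotation, scale, translation, flips, elastic
#' deformation) are mirrored on the mask with nearest-neighbor interpolation;
#' intensity jitter and additive noise touch the image only.
#'
#' @param max_rotation_deg maximum absolute rotation, degrees.
#' @param scale_range length-2 multiplicative scale range.
#' @param max_translate_frac maximum translation as a fraction of image side.
#' @param hflip_prob,vflip_prob flip probabilities.
#' @param intensity_jitter_frac maximum relative multiplicative intensity jitter.
#' @param noise_sigma additive Gaussian noise sigma.
#' @param elastic_on enable mild elastic deformation.
#' @param elastic_grid control-point grid side for the elastic field.
#' @param elastic_sigma control-point displacement sigma in pixels.
#' @param seed optional seed for a deterministic draw.
#' @return object of class `augment_policy`.
#' @export
augment_policy <- function(max_rotation_deg = 10, scale_range = c(0.9, 1.1),
                           max_translate_frac = 0.05,
                           hflip_prob = 0.5, vflip_prob = 0.5,
                           intensity_jitter_frac = 0.10, noise_sigma = 0.01,
                           elastic_on = TRUE, elastic_grid = 4L,
                           elastic_sigma = 2, seed = NULL) {
  for (p in c(hflip_prob, vflip_prob)) stopifnot_scalar(p, "flip prob", 0, 1)
  if (length(scale_range) != 2L || scale_range[1] > scale_range[2]) {
    stop("'scale_range' must be an ordered length-2 range", call. = FALSE)
  }
  structure(list(max_rotation_deg = max_rotation_deg, scale_range = scale_range,
                 max_translate_frac = max_translate_frac,
                 hflip_prob = hflip_prob, vflip_prob = vflip_prob,
                 intensity_jitter_frac = intensity_jitter_frac,
                 noise_sigma = noise_sigma, elastic_on = elastic_on,
                 elastic_grid = as.integer(elastic_grid),
                 elastic_sigma = elastic_sigma, seed = seed),
            class = "augment_policy")
}

#' A no-op augmentation policy
#' @return an [augment_policy()] whose draw is always the identity.
#' @export
no_augment <- function() {
  augment_policy(max_rotation_deg = 0, scale_range = c(1, 1),
                 max_translate_frac = 0, hflip_prob = 0, vflip_prob = 0,
                 intensity_jitter_frac = 0, noise_sigma = 0, elastic_on = FALSE)
}

#' Preprocessing configuration
#'
#' @param window_percentiles `(p_low, p_high)` percentile window in `[0,100]`.
#' @param bias_correction logical; remove low-frequency multiplicative shading.
#' @param normalization `"zscore"` or `"minmax"`.
#' @param target_size output side in pixels.
#' @param gamma optional monotonic contrast exponent in `[0.8, 1.2]`;
#'   `NULL` (default) disables it.
#' @param augmentation an [augment_policy()].
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(window_percentiles = c(1, 99),
                              bias_correction = TRUE,
                              normalization = c("zscore", "minmax"),
                              target_size = 256L, gamma = NULL,
                              augmentation = augment_policy()) {
  if (window_percentiles[1] >= window_percentiles[2]) {
    stop("window percentiles must satisfy p_low < p_high", call. = FALSE)
  }
  stopifnot_scalar(target_size, "target_size", lower = 1)
  if (!is.null(gamma)) stopifnot_scalar(gamma, "gamma", 0.8, 1.2)
  structure(list(window_percentiles = window_percentiles,
                 bias_correction = isTRUE(bias_correction),
                 normalization = match.arg(normalization),
                 target_size = as.integer(target_size), gamma = gamma,
                 augmentation = augmentation),
            class = "preprocess_config")
}

#' Percentile windowing
#'
#' Clips at the `p_low`/`p_high` percentiles (inverse-ECDF quantiles, so the
#' operation is exactly idempotent) and rescales linearly to `[0,1]`.
#' Constant images map to all zeros with a warning.
#'
#' @param image numeric matrix, all finite.
#' @param p_low,p_high percentiles in `[0,100]`.
#' @return matrix in `[0,1]`.
#' @export
percentile_window <- function(image, p_low = 1, p_high = 99) {
  nbad <- sum(!is.finite(image))
  if (nbad > 0) {
    stop(sprintf("image contains %d non-finite pixel(s)", nbad), call. = FALSE)
  }
  lo <- quantile(image, p_low / 100, type = 1, names = FALSE)
  hi <- quantile(image, p_high / 100, type = 1, names = FALSE)
  if (hi - lo < 1e-12) {
    warning("constant image in percentile_window; returning zeros")
    return(array(0, dim(image)))
  }
  (pmin(pmax(image, lo), hi) - lo) / (hi - lo)
}

.fourier_basis <- function(n, order = 2L) {
  x <- (seq_len(n) - 0.5) / n
  cols <- list(rep(1, n))
  for (k in seq_len(order)) {
    cols <- c(cols, list(cos(2 * pi * k * x), sin(2 * pi * k * x)))
  }
  do.call(cbind, cols)
}

#' Estimate and remove a low-frequency multiplicative bias field
#'
#' Homomorphic estimator for 2-D radiographs: bright compact anatomy is
#' excluded (Otsu threshold, dilated margin), then the log image is fitted on
#' the remaining background/soft-tissue pixels with a low-order 2-D Fourier
#' surface using iteratively reweighted least squares (Huber weights). The
#' estimated field is strictly positive with mean one;
#' `corrected = image / field`. A parametric low-frequency fit is used rather
#' than plain log-domain smoothing because smoothing attenuates each spatial
#' frequency differently and distorts the recovered field shape.
#'
#' @param image non-negative matrix.
#' @param order Fourier order per axis (order 2 spans fields with up to two
#'   cycles across the image).
#' @param iterations IRLS iterations.
#' @param eps_img positive offset added before the log transform.
#' @return list with `corrected` and `field` matrices.
#' @export
bias_correct <- function(image, order = 2L, iterations = 4L, eps_img = 1e-3) {
  if (all(image == 0)) {
    warning("all-zero image in bias_correct; identity pass-through")
    return(list(corrected = image, field = array(1, dim(image))))
  }
  n1 <- nrow(image); n2 <- ncol(image)
  lx <- log(pmax(image, 0) + eps_img)
  B1 <- .fourier_basis(n1, order); B2 <- .fourier_basis(n2, order)
  # design matrix of the tensor basis, pixels in column-major order
  X <- matrix(0, n1 * n2, ncol(B1) * ncol(B2))
  k <- 0L
  for (j in seq_len(ncol(B2))) for (i in seq_len(ncol(B1))) {
    k <- k + 1L
    X[, k] <- as.vector(outer(B1[, i], B2[, j]))
  }
  y <- as.vector(lx)
  # exclude bright anatomy (plus a dilated margin) from the fit
  w <- rep(1, length(y))
  if (diff(range(image)) > 1e-12) {
    norm <- normalize_image(image, "minmax")
    fg <- (norm > otsu_threshold(norm)) * 1L
    margin <- max(3L, round(min(n1, n2) / 16))
    fg <- EBImage::dilate(fg, .disk_brush(margin))
    if (mean(fg) < 0.9) w[as.vector(fg) > 0] <- 0
  }
  beta <- NULL
  for (it in seq_len(iterations)) {
    fit <- stats::lm.wfit(X, y, w)
    beta <- fit$coefficients
    r <- as.vector(y - X %*% beta)
    s <- median(abs(r[w > 0])) / 0.6745 + 1e-9
    u <- abs(r) / (1.345 * s)
    w <- ifelse(w > 0, pmin(1, 1 / u), 0)
  }
  surf <- matrix(X %*% beta, n1, n2)
  field <- exp(surf - mean(surf))
  field <- field / mean(field)
  list(corrected = image / field, field = field)
}

#' Per-image intensity standardization
#'
#' @param image numeric matrix.
#' @param mode `"zscore"` (mean 0, sd 1, sd floored at 1e-8) or `"minmax"`
#'   (rescale to `[0,1]`).
#' @return standardized matrix.
#' @export
normalize_image <- function(image, mode = c("zscore", "minmax")) {
  mode <- match.arg(mode)
  if (mode == "zscore") {
    s <- max(sd(as.vector(image)), 1e-8)
    (image - mean(image)) / s
  } else {
    rng <- range(image)
    if (diff(rng) < 1e-12) return(array(0, dim(image)))
    (image - rng[1]) / diff(rng)
  }
}

#' Resample an image (and optionally its mask) to a target size
#'
#' The image is resampled with bilinear interpolation; the mask with
#' nearest-neighbor interpolation so labels stay binary.
#'
#' @param image 2-D matrix.
#' @param mask optional binary matrix of the same shape.
#' @param target_size output side in pixels.
#' @return list with `image` and (if supplied) `mask`.
#' @export
standardize_geometry <- function(image, mask = NULL, target_size = 256L) {
  if (!is.null(mask)) check_same_shape(image, mask, "image and mask")
  if (nrow(image) == target_size && ncol(image) == target_size) {
    return(list(image = image, mask = mask))
  }
  img <- .resize_bilinear(image, target_size, target_size)
  out <- list(image = img)
  if (!is.null(mask)) {
    out$mask <- .resize_nearest(mask, target_size, target_size)
  }
  out
}

# Interpolation weight matrix mapping a length-n axis to length-m
# (half-pixel-centre convention); rows sum to one.
.interp_matrix <- function(n_out, n_in) {
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  lo <- floor(src)
  frac <- src - lo
  lo <- pmin(pmax(lo, 0), n_in - 1)
  hi <- pmin(lo + 1, n_in - 1)
  A <- matrix(0, n_out, n_in)
  idx <- seq_len(n_out)
  A[cbind(idx, lo + 1)] <- A[cbind(idx, lo + 1)] + (1 - frac)
  A[cbind(idx, hi + 1)] <- A[cbind(idx, hi + 1)] + frac
  A
}

.resize_bilinear <- function(x, n1, n2) {
  A <- .interp_matrix(n1, nrow(x))
  B <- .interp_matrix(n2, ncol(x))
  A %*% x %*% t(B)
}

.resize_nearest <- function(x, n1, n2) {
  r <- pmin(pmax(ceiling((seq_len(n1) - 0.5) * nrow(x) / n1), 1), nrow(x))
  c <- pmin(pmax(ceiling((seq_len(n2) - 0.5) * ncol(x) / n2), 1), ncol(x))
  x[r, c, drop = FALSE]
}

# Sample x at fractional (row, col) source maps. interp = "bilinear"|"nearest";
# coordinates outside the image read as `fill`.
.warp <- function(x, map_r, map_c, interp = "bilinear", fill = 0) {
  n1 <- nrow(x); n2 <- ncol(x)
  if (interp == "nearest") {
    r <- round(map_r); c <- round(map_c)
    ok <- r >= 1 & r <= n1 & c >= 1 & c <= n2
    out <- array(fill, dim(map_r))
    out[ok] <- x[cbind(r[ok], c[ok])]
    return(out)
  }
  r0 <- floor(map_r); c0 <- floor(map_c)
  fr <- map_r - r0; fc <- map_c - c0
  val <- function(r, c) {
    ok <- r >= 1 & r <= n1 & c >= 1 & c <= n2
    v <- array(fill, dim(r))
    v[ok] <- x[cbind(r[ok], c[ok])]
    v
  }
  val(r0, c0) * (1 - fr) * (1 - fc) + val(r0 + 1, c0) * fr * (1 - fc) +
    val(r0, c0 + 1) * (1 - fr) * fc + val(r0 + 1, c0 + 1) * fr * fc
}

#' Apply one random augmentation draw to an image/mask pair
#'
#' Draws rotation, scale, translation, flips and (optionally) a mild elastic
#' deformation; the identical spatial transform is applied to both members of
#' the pair (bilinear for the image, nearest-neighbor for the mask).
#' Intensity jitter and noise are then applied to the image only. With a
#' policy whose ranges are all degenerate the function is an exact identity.
#'
#' @param image numeric matrix.
#' @param mask binary matrix, same shape.
#' @param policy an [augment_policy()]; `policy$seed`, when set, makes the
#'   draw deterministic.
#' @return list with `image` and `mask`.
#' @export
augment_pair <- function(image, mask, policy = augment_policy()) {
  check_same_shape(image, mask, "image and mask")
  run <- function() {
    n1 <- nrow(image); n2 <- ncol(image)
    theta <- if (policy$max_rotation_deg > 0) {
      runif(1, -policy$max_rotation_deg, policy$max_rotation_deg) * pi / 180
    } else 0
    sc <- if (diff(policy$scale_range) > 0) {
      runif(1, policy$scale_range[1], policy$scale_range[2])
    } else policy$scale_range[1]
    tr <- if (policy$max_translate_frac > 0) {
      runif(2, -policy$max_translate_frac, policy$max_translate_frac) * c(n1, n2)
    } else c(0, 0)
    hflip <- policy$hflip_prob > 0 && runif(1) < policy$hflip_prob
    vflip <- policy$vflip_prob > 0 && runif(1) < policy$vflip_prob

    img <- image; msk <- mask
    if (hflip) { img <- img[, n2:1, drop = FALSE]; msk <- msk[, n2:1, drop = FALSE] }
    if (vflip) { img <- img[n1:1, , drop = FALSE]; msk <- msk[n1:1, , drop = FALSE] }

    needs_warp <- theta != 0 || sc != 1 || any(tr != 0) || policy$elastic_on
    if (needs_warp) {
      cr <- (n1 + 1) / 2; cc <- (n2 + 1) / 2
      rr <- matrix(rep(seq_len(n1), n2), n1, n2) - cr - tr[1]
      cc2 <- matrix(rep(seq_len(n2), each = n1), n1, n2) - cc - tr[2]
      # inverse map: rotate by -theta, scale by 1/sc
      map_r <- (cos(theta) * rr + sin(theta) * cc2) / sc + cr
      map_c <- (-sin(theta) * rr + cos(theta) * cc2) / sc + cc
      if (policy$elastic_on && policy$elastic_sigma > 0) {
        g <- policy$elastic_grid
        dr <- .resize_bilinear(matrix(rnorm(g * g, 0, policy$elastic_sigma), g, g), n1, n2)
        dc <- .resize_bilinear(matrix(rnorm(g * g, 0, policy$elastic_sigma), g, g), n1, n2)
        map_r <- map_r + dr; map_c <- map_c + dc
      }
      img <- .warp(img, map_r, map_c, "bilinear", fill = 0)
      msk <- .warp(msk, map_r, map_c, "nearest", fill = 0)
    }
    if (policy$intensity_jitter_frac > 0) {
      img <- img * (1 + runif(1, -policy$intensity_jitter_frac,
                              policy$intensity_jitter_frac))
    }
    if (policy$noise_sigma > 0) {
      img <- img + matrix(rnorm(n1 * n2, 0, policy$noise_sigma), n1, n2)
    }
    list(image = img, mask = msk)
  }
  if (!is.null(policy$seed)) with_seed(policy$seed, run()) else run()
}

#' Full preprocessing of one image (and optional mask)
#'
#' Percentile windowing, optional bias-field removal, optional gamma mapping,
#' per-image standardization, then geometric resampling. Augmentation is a
#' separate training-time step ([augment_pair()]), never applied here.
#'
#' @param image numeric matrix.
#' @param mask optional binary matrix.
#' @param config a [preprocess_config()].
#' @return list with `image` and (if supplied) `mask`.
#' @export
preprocess_image <- function(image, mask = NULL, config = preprocess_config()) {
  img <- percentile_window(image, config$window_percentiles[1],
                           config$window_percentiles[2])
  if (config$bias_correction) img <- bias_correct(img)$corrected
  if (!is.null(config$gamma)) img <- clamp01(img)^config$gamma
  img <- normalize_image(img, config$normalization)
  out <- standardize_geometry(img, mask, config$target_size)
  out
}
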