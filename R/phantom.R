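#' Configuration for synthetic hand-radiograph phantoms
#'
#' The phantom generator emulates the population statistics of a small public
#' hand-radiograph collection: roughly 35% foreground coverage per image and a
#' bimodal distribution of per-image mean intensity with modes near 0.30
#' (under-exposed acquisitions) and 0.60 (bright acquisitions).
#'
#' @param image_size pixels per side (square image), at least 64.
#' @param n_fingers number of finger capsules.
#' @param coverage_target mean foreground fraction in (0,1).
#' @param intensity_modes length-2 vector of mean-intensity mode centers.
#' @param bias_strength relative amplitude of the multiplicative low-frequency
#'   bias field (0 disables it).
#' @param noise_sigma additive Gaussian noise sigma on the `[0,1]` scale.
#' @param seed integer seed; all per-sample randomness flows from it.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 256L, n_fingers = 5L,
                           coverage_target = 0.35,
                           intensity_modes = c(0.30, 0.60),
                           bias_strength = 0.15, noise_sigma = 0.02,
                           seed = 1L) {
  stopifnot_scalar(image_size, "image_size", lower = 64)
  stopifnot_scalar(n_fingers, "n_fingers", lower = 1)
  stopifnot_scalar(coverage_target, "coverage_target")
  if (coverage_target <= 0 || coverage_target >= 1) {
    stop("'coverage_target' must be strictly inside (0,1)", call. = FALSE)
  }
  if (length(intensity_modes) != 2L || any(!is.finite(intensity_modes))) {
    stop("'intensity_modes' must be two finite mode centers", call. = FALSE)
  }
  stopifnot_scalar(bias_strength, "bias_strength", lower = 0)
  stopifnot_scalar(noise_sigma, "noise_sigma", lower = 0)
  structure(list(image_size = as.integer(image_size),
                 n_fingers = as.integer(n_fingers),
                 coverage_target = coverage_target,
                 intensity_modes = sort(intensity_modes),
                 bias_strength = bias_strength,
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Distance from each grid point to a segment (a -> b); vectorised over pixels.
.seg_dist <- function(rr, cc, a, b) {
  vx <- b[1] - a[1]; vy <- b[2] - a[2]
  L2 <- vx * vx + vy * vy
  if (L2 < 1e-12) {
    sqrt((rr - a[1])^2 + (cc - a[2])^2)
  } else {
    t <- pmin(pmax(((rr - a[1]) * vx + (cc - a[2]) * vy) / L2, 0), 1)
    sqrt((rr - a[1] - t * vx)^2 + (cc - a[2] - t * vy)^2)
  }
}

# Signed projection of each grid point onto the finger axis, for joint gaps.
.axis_proj <- function(rr, cc, a, b) {
  vx <- b[1] - a[1]; vy <- b[2] - a[2]
  L <- sqrt(vx * vx + vy * vy)
  ((rr - a[1]) * vx + (cc - a[2]) * vy) / L
}

# Rasterise the hand silhouette at global scale g. geo holds the jittered
# geometry sampled once per phantom, so the scale search is deterministic.
.draw_hand <- function(n, geo, g) {
  rr <- matrix(rep(seq_len(n), n), n, n)
  cc <- matrix(rep(seq_len(n), each = n), n, n)
  s <- n * g
  palm_c <- geo$palm_center * n
  pa <- geo$palm_axes * s
  palm <- ((rr - palm_c[1]) / pa[1])^2 + ((cc - palm_c[2]) / pa[2])^2 <= 1
  carp_c <- geo$carp_center * n
  ca <- geo$carp_axes * s
  carpal <- ((rr - carp_c[1]) / ca[1])^2 + ((cc - carp_c[2]) / ca[2])^2 <= 1
  fingers <- matrix(FALSE, n, n)
  for (j in seq_along(geo$finger_angle)) {
    ang <- geo$finger_angle[j]
    len <- geo$finger_len[j] * s
    rad <- geo$finger_rad[j] * s
    base <- c(palm_c[1] - pa[1] * 0.55, palm_c[2] + pa[2] * 1.3 * geo$finger_off[j])
    tip <- base + len * c(-cos(ang), sin(ang))
    cap <- .seg_dist(rr, cc, base, tip) <= rad
    proj <- .axis_proj(rr, cc, base, tip)
    for (fr in geo$joint_at[[j]]) {
      cap <- cap & !(abs(proj - fr * len) <= geo$gap_px / 2)
    }
    fingers <- fingers | cap
  }
  (palm | carpal | fingers) * 1L
}

# Exponentiated sum of low-order 2-D cosine terms with random phase;
# strictly positive, normalised to mean one.
.bias_field <- function(n, strength, n_terms, freqs, phases, weights) {
  if (strength <= 0) return(matrix(1, n, n))
  x <- (seq_len(n) - 0.5) / n
  fld <- matrix(0, n, n)
  for (j in seq_len(n_terms)) {
    term <- outer(cos(2 * pi * freqs[j, 1] * x + phases[j, 1]),
                  cos(2 * pi * freqs[j, 2] * x + phases[j, 2]))
    fld <- fld + weights[j] * term
  }
  fld <- fld / max(sum(abs(weights)), 1e-12) * strength
  fld <- exp(fld)
  fld / mean(fld)
}

#' Generate one synthetic hand-radiograph phantom
#'
#' Draws a hand silhouette (palm ellipse, carpal block, finger capsules with
#' narrow joint gaps), renders soft-tissue halo and brighter bone foreground,
#' multiplies by a smooth positive bias field and adds Gaussian noise. The
#' silhouette scale is solved per sample so that empirical coverage tracks a
#' jittered `coverage_target` (slight left skew, as in the real collection).
#'
#' @param config a [phantom_config()].
#' @param mode optional intensity mode index (1 = dark, 2 = bright); by
#'   default drawn at random from the sample's seed.
#' @return an object of class `phantom_sample` with fields `image`, `mask`,
#'   `patient_id`, `coverage`, `mean_intensity`, `seed`.
#' @export
generate_phantom <- function(config = phantom_config(), mode = NULL) {
  if (!inherits(config, "phantom_config")) config <- do.call(phantom_config, config)
  n <- config$image_size
  with_seed(config$seed, {
    if (is.null(mode)) mode <- sample(1:2, 1L)
    nf <- config$n_fingers
    ang0 <- seq(-0.55, 0.55, length.out = nf)
    geo <- list(
      palm_center = c(0.60, 0.50) + rnorm(2, 0, 0.012),
      palm_axes = c(0.200, 0.165) * exp(rnorm(2, 0, 0.05)),
      carp_center = c(0.84, 0.50) + rnorm(2, 0, 0.012),
      carp_axes = c(0.135, 0.150) * exp(rnorm(2, 0, 0.05)),
      finger_angle = ang0 + rnorm(nf, 0, 0.04),
      finger_len = (0.30 - 0.08 * abs(ang0)) * exp(rnorm(nf, 0, 0.06)),
      finger_rad = 0.042 * exp(rnorm(nf, 0, 0.08)),
      finger_off = seq(-0.85, 0.85, length.out = nf),
      joint_at = replicate(nf, pmin(pmax(c(0.45, 0.72) + rnorm(2, 0, 0.03), 0.2), 0.9),
                           simplify = FALSE),
      gap_px = sample(2:4, 1L)
    )
    z1 <- rnorm(1); z2 <- rnorm(1)
    target <- min(max(config$coverage_target + 0.05 * z1 - 0.02 * abs(z2), 0.05), 0.90)
    # secant-style refinement: coverage scales roughly with g^2
    g <- sqrt(target / 0.35)
    mask <- .draw_hand(n, geo, g)
    for (it in 1:3) {
      cov <- mean(mask)
      if (abs(cov - target) < 0.005 || cov <= 0) break
      g <- g * sqrt(target / cov)
      mask <- .draw_hand(n, geo, g)
    }
    cov <- mean(mask)

    contrast <- 0.33 * exp(rnorm(1, 0, 0.05))
    m_center <- config$intensity_modes[mode] + rnorm(1, 0, 0.015)
    bg <- m_center - cov * contrast
    halo <- EBImage::gblur(mask * 1.0, sigma = max(2, n / 40))
    rim <- EBImage::gblur(mask * 1.0, sigma = 1.2)
    img <- bg + contrast * (0.22 * halo * (1 - mask) + (0.55 + 0.45 * rim) * mask)

    if (config$bias_strength > 0) {
      k <- sample(2:3, 1L)
      freqs <- matrix(sample(0:2, 2 * k, replace = TRUE), k, 2)
      zero <- rowSums(freqs) == 0
      freqs[zero, 1] <- 1L
      field <- .bias_field(n, config$bias_strength, k, freqs,
                           matrix(runif(2 * k, 0, 2 * pi), k, 2),
                           runif(k, 0.5, 1))
      img <- img * field
    }
    if (config$noise_sigma > 0) {
      img <- img + matrix(rnorm(n * n, 0, config$noise_sigma), n, n)
    }
    img <- clamp01(img)
    structure(list(image = img, mask = mask,
                   patient_id = sprintf("p%08d", config$seed),
                   coverage = mean(mask), mean_intensity = mean(img),
                   seed = config$seed, mode = mode),
              class = "phantom_sample")
  })
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("phantom_sample %dx%d seed=%d coverage=%.3f mean=%.3f\n",
              nrow(x$image), ncol(x$image), x$seed, x$coverage, x$mean_intensity))
  invisible(x)
}

#' Generate a phantom dataset on disk
#'
#' Writes 8-bit grayscale PNG images, 0/255 PNG masks and a CSV manifest with
#' header `image,mask,patient_id`. Intensity modes alternate so that half the
#' samples are drawn around each mode center. By default each phantom is its
#' own patient; `images_per_patient > 1` creates multi-image patients, which
#' exists purely to exercise leakage-free patient-level splitting.
#'
#' @param n number of samples (>= 1).
#' @param base_seed integer; sample i uses seed `base_seed + i - 1`.
#' @param out_dir output directory (created if missing).
#' @param config a [phantom_config()] supplying everything but the seed.
#' @param images_per_patient images per synthetic patient id.
#' @param overwrite set `TRUE` to replace an existing manifest.
#' @return path to the manifest CSV, invisibly; the manifest data frame as
#'   attribute `"manifest"`.
#' @export
generate_dataset <- function(n, base_seed = 1L, out_dir,
                             config = phantom_config(),
                             images_per_patient = 1L, overwrite = FALSE) {
  stopifnot_scalar(n, "n", lower = 1)
  manifest_path <- file.path(out_dir, "manifest.csv")
  if (file.exists(manifest_path) && !overwrite) {
    stop("manifest already exists at '", manifest_path,
         "'; use overwrite = TRUE to replace it", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- config
    cfg$seed <- as.integer(base_seed + i - 1L)
    smp <- generate_phantom(cfg, mode = 1L + (i %% 2L))
    img_file <- sprintf("img_%05d.png", i)
    msk_file <- sprintf("mask_%05d.png", i)
    write_gray_png(smp$image, file.path(out_dir, img_file))
    write_mask_png(smp$mask, file.path(out_dir, msk_file))
    pid <- sprintf("pat%05d", (i - 1L) %/% as.integer(images_per_patient) + 1L)
    rows[[i]] <- data.frame(image = img_file, mask = msk_file,
                            patient_id = pid, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, manifest_path, row.names = FALSE, quote = FALSE)
  attr(manifest_path, "manifest") <- manifest
  invisible(manifest_path)
}

#' Summarize per-image coverage and mean intensity of a dataset
#'
#' @param manifest manifest CSV path or a data frame with columns
#'   `image`, `mask`, `patient_id` (paths relative to `dir`).
#' @param dir directory that image paths are relative to; defaults to the
#'   manifest's directory.
#' @return data frame with one row per readable image: `image`, `patient_id`,
#'   `coverage`, `mean_intensity`; skipped rows are listed in attribute
#'   `"missing"` and counted in attribute `"n_warnings"`.
#' @export
summarize_dataset <- function(manifest, dir = NULL) {
  if (is.character(manifest)) {
    if (is.null(dir)) dir <- dirname(manifest)
    manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  }
  if (is.null(dir)) dir <- "."
  rows <- vector("list", nrow(manifest))
  missing <- character(0)
  for (i in seq_len(nrow(manifest))) {
    ip <- file.path(dir, manifest$image[i])
    mp <- file.path(dir, manifest$mask[i])
    if (!file.exists(ip) || !file.exists(mp)) {
      missing <- c(missing, manifest$image[i])
      next
    }
    img <- read_gray(ip)
    msk <- read_mask(mp)
    rows[[i]] <- data.frame(image = manifest$image[i],
                            patient_id = manifest$patient_id[i],
                            coverage = mean(msk),
                            mean_intensity = mean(img),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(image = character(0), patient_id = character(0),
                                      coverage = numeric(0), mean_intensity = numeric(0))
  if (length(missing) > 0) {
    warning(sprintf("%d manifest row(s) skipped (missing files)", length(missing)))
  }
  attr(out, "missing") <- missing
  attr(out, "n_warnings") <- length(missing)
  out
}
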