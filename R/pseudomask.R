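#' Pseudo-mask generation settings
#'
#' Weak-supervision recipe: CLAHE contrast enhancement, global Otsu
#' thresholding with a relaxation factor, light morphological opening and
#' closing, and selection of the largest connected component.
#'
#' @param clahe_clip CLAHE clip limit (> 0).
#' @param clahe_tiles CLAHE tile grid side.
#' @param relax_factor multiplier on the Otsu threshold, in (0, 1].
#' @param open_radius,close_radius disk structuring-element radii in pixels
#'   (0 disables the step).
#' @param keep_largest keep only the largest 8-connected component.
#' @return object of class `pseudomask_config`.
#' @export
pseudomask_config <- function(clahe_clip = 2.0, clahe_tiles = 8L,
                              relax_factor = 0.95, open_radius = 2L,
                              close_radius = 2L, keep_largest = TRUE) {
  stopifnot_scalar(clahe_clip, "clahe_clip", lower = 1e-9)
  stopifnot_scalar(relax_factor, "relax_factor", lower = 1e-9, upper = 1)
  stopifnot_scalar(open_radius, "open_radius", lower = 0)
  stopifnot_scalar(close_radius, "close_radius", lower = 0)
  structure(list(clahe_clip = clahe_clip, clahe_tiles = as.integer(clahe_tiles),
                 relax_factor = relax_factor,
                 open_radius = as.integer(open_radius),
                 close_radius = as.integer(close_radius),
                 keep_largest = isTRUE(keep_largest)),
            class = "pseudomask_config")
}

#' Contrast-limited adaptive histogram equalization
#'
#' Thin wrapper around `EBImage::clahe()`. The image is padded to a multiple
#' of the tile size when necessary and the result is clipped back to `[0,1]`.
#'
#' @param image matrix in `[0,1]`.
#' @param clip clip limit.
#' @param tiles tile grid side; tiles larger than the image are an error.
#' @return enhanced matrix in `[0,1]`.
#' @export
clahe_enhance <- function(image, clip = 2.0, tiles = 8L) {
  n1 <- nrow(image); n2 <- ncol(image)
  if (tiles > n1 || tiles > n2) {
    stop(sprintf("tile grid %d exceeds image size %dx%d", tiles, n1, n2),
         call. = FALSE)
  }
  if (diff(range(image)) < 1e-12) return(image)
  p1 <- ceiling(n1 / tiles) * tiles
  p2 <- ceiling(n2 / tiles) * tiles
  padded <- matrix(0, p1, p2)
  padded[seq_len(n1), seq_len(n2)] <- image
  if (p1 > n1) padded[(n1 + 1):p1, seq_len(n2)] <- image[rep(n1, p1 - n1), ]
  if (p2 > n2) padded[, (n2 + 1):p2] <- padded[, rep(n2, p2 - n2)]
  out <- EBImage::clahe(padded, nx = tiles, ny = tiles, limit = clip)
  clamp01(out[seq_len(n1), seq_len(n2)])
}

#' Otsu threshold of a grayscale image
#'
#' Exhaustive search over a 256-bin histogram on `[0,1]` for the bin edge
#' maximizing between-class variance.
#'
#' @param image matrix with at least two distinct values; values are clipped
#'   to `[0,1]` for binning.
#' @param levels number of histogram bins.
#' @return threshold in (0,1): pixels strictly above belong to the foreground.
#' @export
otsu_threshold <- function(image, levels = 256L) {
  v <- clamp01(as.vector(image))
  if (diff(range(v)) < 1e-12) {
    stop("constant image: no threshold exists", call. = FALSE)
  }
  breaks <- seq(0, 1, length.out = levels + 1L)
  h <- tabulate(pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L),
                     levels), nbins = levels)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(levels + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, levels)
  bcv[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  # the maximum can be a plateau when a histogram gap separates the classes;
  # take the plateau midpoint so the threshold sits between the modes
  top <- which(bcv >= max(bcv) - 1e-12)
  k <- top[ceiling(length(top) / 2)]
  breaks[k + 1L]
}

.disk_brush <- function(radius) {
  size <- 2L * as.integer(radius) + 1L
  EBImage::makeBrush(size, shape = "disc")
}

.largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  if (max(lab) <= 1) return((lab > 0) * 1L)
  sizes <- tabulate(lab[lab > 0])
  best <- max(sizes)
  cand <- which(sizes == best)
  if (length(cand) > 1L) {
    # deterministic tie-break: component whose first pixel (column-major,
    # i.e. lowest column then row) comes first
    firsts <- vapply(cand, function(k) which(lab == k)[1], numeric(1))
    cand <- cand[which.min(firsts)]
  }
  (lab == cand[1]) * 1L
}

#' Generate a pseudo-mask from a grayscale radiograph
#'
#' CLAHE enhancement, global Otsu threshold relaxed by `relax_factor`,
#' morphological opening then closing with disk elements, then (optionally)
#' the largest 8-connected component. Constant images yield an empty mask
#' with a warning; empty masks are data, not errors.
#'
#' @param image matrix in `[0,1]`.
#' @param config a [pseudomask_config()].
#' @return binary matrix; attribute `"threshold"` holds the relaxed threshold
#'   used (NA for constant input).
#' @export
make_pseudo_mask <- function(image, config = pseudomask_config()) {
  if (diff(range(image)) < 1e-12) {
    warning("constant image: returning empty pseudo-mask")
    out <- array(0L, dim(image))
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  enh <- clahe_enhance(image, config$clahe_clip, config$clahe_tiles)
  t_otsu <- otsu_threshold(enh)
  thr <- config$relax_factor * t_otsu
  m <- (enh >= thr) * 1L
  if (config$open_radius > 0) {
    m <- EBImage::opening(m, .disk_brush(config$open_radius))
  }
  if (config$close_radius > 0) {
    m <- EBImage::closing(m, .disk_brush(config$close_radius))
  }
  m <- (m > 0) * 1L
  if (config$keep_largest && any(m > 0)) m <- .largest_component(m)
  out <- m
  attr(out, "threshold") <- thr
  out
}

#' Agreement between pseudo-masks and reference masks
#'
#' Per-image Dice, IoU, boundary F1, boundary pixel accuracy, ASSD and HD95
#' (delegating to the metric suite), plus mean and SD summaries. Pairs where
#' exactly one mask is empty report overlap scores but missing surface
#' distances; missing values are counted and excluded from summaries.
#'
#' @param pseudo_masks list of binary matrices.
#' @param reference_masks list of binary matrices, same length and shapes.
#' @param tolerance boundary tolerance in pixels for boundary F1.
#' @return list with `per_image` (data frame) and `summary`
#'   (mean, sd, n_missing per metric).
#' @export
evaluate_pseudo <- function(pseudo_masks, reference_masks, tolerance = 2) {
  if (length(pseudo_masks) != length(reference_masks)) {
    stop("pseudo and reference mask lists must be paired", call. = FALSE)
  }
  rows <- lapply(seq_along(pseudo_masks), function(i) {
    p <- pseudo_masks[[i]]; y <- reference_masks[[i]]
    ov <- overlap_metrics(p, y)
    bd <- boundary_metrics(p, y, tolerance = tolerance)
    sdm <- surface_distance_metrics(p, y)
    data.frame(image = i, dice = ov$dice, iou = ov$iou,
               boundary_f1 = bd$boundary_f1,
               boundary_accuracy = bd$boundary_accuracy,
               assd = sdm$assd, hd95 = sdm$hd95)
  })
  per_image <- do.call(rbind, rows)
  metric_cols <- setdiff(names(per_image), "image")
  summary <- do.call(rbind, lapply(metric_cols, function(m) {
    v <- per_image[[m]]
    data.frame(metric = m, mean = mean(v, na.rm = TRUE),
               sd = if (sum(!is.na(v)) > 1) sd(v, na.rm = TRUE) else 0,
               n_missing = sum(is.na(v)))
  }))
  list(per_image = per_image, summary = summary)
}
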