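#' Pixel confusion counts between a predicted and a reference mask
#'
#' @param prediction binary matrix.
#' @param reference binary matrix, same shape.
#' @return named list `tp`, `fp`, `fn`, `tn` (integers summing to the pixel
#'   count).
#' @export
confusion_counts <- function(prediction, reference) {
  check_same_shape(prediction, reference, "prediction and reference")
  check_binary_mask(prediction, "prediction")
  check_binary_mask(reference, "reference")
  p <- as.vector(prediction); y <- as.vector(reference)
  tp <- sum(p == 1 & y == 1)
  fp <- sum(p == 1 & y == 0)
  fn <- sum(p == 0 & y == 1)
  tn <- sum(p == 0 & y == 0)
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Overlap metrics (set-form, on binarized masks)
#'
#' Dice = 2TP/(2TP+FP+FN), IoU = TP/(TP+FP+FN), pixel accuracy, precision,
#' recall and F1. When both masks are empty, Dice, IoU, precision and recall
#' are 1 by convention.
#'
#' @param prediction,reference binary matrices of equal shape.
#' @return named list of scalars.
#' @export
overlap_metrics <- function(prediction, reference) {
  cc <- confusion_counts(prediction, reference)
  with(cc, {
    both_empty <- (tp + fp + fn) == 0
    dice <- if (both_empty) 1 else 2 * tp / (2 * tp + fp + fn)
    iou <- if (both_empty) 1 else tp / (tp + fp + fn)
    acc <- (tp + tn) / (tp + fp + fn + tn)
    precision <- if (tp + fp == 0) { if (fn == 0) 1 else 0 } else tp / (tp + fp)
    recall <- if (tp + fn == 0) { if (fp == 0) 1 else 0 } else tp / (tp + fn)
    f1 <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    list(dice = dice, iou = iou, accuracy = acc,
         precision = precision, recall = recall, f1 = f1)
  })
}

#' Background leakage rate
#'
#' Fraction of predicted foreground that is actually background:
#' `FP / (TP + FP)`, i.e. one minus precision; 0 when nothing is predicted.
#'
#' @param prediction,reference binary matrices of equal shape.
#' @return scalar in `[0,1]`.
#' @export
leakage_rate <- function(prediction, reference) {
  cc <- confusion_counts(prediction, reference)
  if (cc$tp + cc$fp == 0) return(0)
  cc$fp / (cc$tp + cc$fp)
}

#' Boundary of a binary mask
#'
#' Mask minus its erosion by a 3x3 cross (pixels outside the image count as
#' background, so foreground touching the border is boundary).
#'
#' @param mask binary matrix.
#' @return binary matrix of boundary pixels.
#' @export
mask_boundary <- function(mask) {
  check_binary_mask(mask)
  n1 <- nrow(mask); n2 <- ncol(mask)
  sh <- function(dr, dc) {
    out <- matrix(0, n1, n2)
    rs <- max(1, 1 + dr):min(n1, n1 + dr)
    cs <- max(1, 1 + dc):min(n2, n2 + dc)
    out[rs, cs] <- mask[rs - dr, cs - dc]
    out
  }
  er <- mask * sh(1, 0) * sh(-1, 0) * sh(0, 1) * sh(0, -1)
  (mask - er) * 1L
}

# Euclidean distance from every pixel to the nearest set pixel of `pts_mask`
# (distance transform); Inf when the set is empty.
.dist_to_set <- function(pts_mask) {
  if (!any(pts_mask > 0)) return(array(Inf, dim(pts_mask)))
  EBImage::distmap(1 - pts_mask, metric = "euclidean")
}

#' Boundary F1 and boundary pixel accuracy
#'
#' Boundary precision (fraction of predicted boundary within `tolerance`
#' pixels of the reference boundary), recall (the converse), their harmonic
#' mean, and the pixel accuracy restricted to the band of pixels within
#' `tolerance` of the reference boundary. Empty-boundary cases follow the
#' empty-mask conventions of [overlap_metrics()].
#'
#' @param prediction,reference binary matrices of equal shape.
#' @param tolerance tolerance in pixels (default 2 at 256x256; scale
#'   linearly with image side for other sizes).
#' @return named list `boundary_f1`, `boundary_precision`,
#'   `boundary_recall`, `boundary_accuracy`.
#' @export
boundary_metrics <- function(prediction, reference, tolerance = 2) {
  check_same_shape(prediction, reference, "prediction and reference")
  bp <- mask_boundary(prediction)
  br <- mask_boundary(reference)
  np <- sum(bp); nr <- sum(br)
  if (np == 0 && nr == 0) {
    return(list(boundary_f1 = 1, boundary_precision = 1, boundary_recall = 1,
                boundary_accuracy = 1))
  }
  d_to_r <- .dist_to_set(br)
  d_to_p <- .dist_to_set(bp)
  precision <- if (np == 0) 0 else mean(d_to_r[bp > 0] <= tolerance)
  recall <- if (nr == 0) 0 else mean(d_to_p[br > 0] <= tolerance)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  band <- if (nr > 0) d_to_r <= tolerance else array(TRUE, dim(reference))
  b_acc <- mean(prediction[band] == reference[band])
  list(boundary_f1 = f1, boundary_precision = precision,
       boundary_recall = recall, boundary_accuracy = b_acc)
}

#' Surface-distance metrics
#'
#' Symmetric surface distances between boundary-pixel centres (Euclidean, in
#' pixel units). ASSD is the mean and HD95 the 95th percentile of the pooled
#' directed distances; surface Dice at tolerance `tau` is the fraction of all
#' boundary points lying within `tau` of the other boundary. Both-empty masks
#' score 0 distances (and surface Dice 1); when exactly one mask is empty the
#' distances are undefined and returned as `NA`.
#'
#' @param prediction,reference binary matrices of equal shape.
#' @param tau surface-Dice tolerance in pixels.
#' @return named list `assd`, `hd95`, `surface_dice`, `directed_hausdorff`
#'   (max over pooled directed distances).
#' @export
surface_distance_metrics <- function(prediction, reference, tau = 2) {
  check_same_shape(prediction, reference, "prediction and reference")
  bp <- mask_boundary(prediction)
  br <- mask_boundary(reference)
  np <- sum(bp); nr <- sum(br)
  if (np == 0 && nr == 0) {
    return(list(assd = 0, hd95 = 0, surface_dice = 1, directed_hausdorff = 0))
  }
  if (np == 0 || nr == 0) {
    return(list(assd = NA_real_, hd95 = NA_real_, surface_dice = NA_real_,
                directed_hausdorff = NA_real_))
  }
  d_pr <- .dist_to_set(br)[bp > 0]   # prediction boundary -> reference
  d_rp <- .dist_to_set(bp)[br > 0]   # reference boundary -> prediction
  pooled <- c(d_pr, d_rp)
  list(assd = mean(pooled),
       hd95 = quantile(pooled, 0.95, names = FALSE),
       surface_dice = (sum(d_pr <= tau) + sum(d_rp <= tau)) / (np + nr),
       directed_hausdorff = max(pooled))
}

#' Generalized (weighted) Dice over several classes
#'
#' `sum_c w_c * 2|P_c n Y_c| / sum_c w_c * (|P_c| + |Y_c|)`; default weights
#' are the inverse squared reference volumes.
#'
#' @param pairs list of lists, each with elements `prediction` and
#'   `reference` (binary matrices) for one class.
#' @param class_weights optional numeric weights; required when every
#'   reference is empty.
#' @return scalar generalized Dice.
#' @export
generalized_dice <- function(pairs, class_weights = NULL) {
  inter <- vapply(pairs, function(pr) {
    check_same_shape(pr$prediction, pr$reference)
    sum(pr$prediction * pr$reference)
  }, numeric(1))
  sizes <- vapply(pairs, function(pr) sum(pr$prediction) + sum(pr$reference),
                  numeric(1))
  vols <- vapply(pairs, function(pr) sum(pr$reference), numeric(1))
  if (is.null(class_weights)) {
    if (all(vols == 0)) {
      stop("all reference classes empty: supply explicit class_weights",
           call. = FALSE)
    }
    class_weights <- 1 / pmax(vols, 1)^2
  }
  sum(class_weights * 2 * inter) / sum(class_weights * sizes)
}

#' ROC-AUC and PR-AUC of a probability map against a binary reference
#'
#' ROC-AUC via the tie-aware rank statistic (normalized Mann-Whitney U);
#' PR-AUC via the interpolated precision envelope. Pixels may be pooled over
#' a whole split (default protocol) or supplied per image by the caller.
#'
#' @param probabilities numeric vector or matrix of scores.
#' @param reference binary labels of the same length.
#' @return named list `roc_auc`, `pr_auc`; both `NA` (with a warning) when
#'   the reference contains a single class.
#' @export
ranking_curves <- function(probabilities, reference) {
  s <- as.vector(probabilities); y <- as.vector(reference)
  .check_pair_lengths(s, y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    warning("single-class reference: AUC undefined")
    return(list(roc_auc = NA_real_, pr_auc = NA_real_))
  }
  r <- rank(s, ties.method = "average")
  roc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # PR curve at descending unique score cutoffs (ties grouped)
  ord <- order(s, decreasing = TRUE)
  ys <- y[ord]; ss <- s[ord]
  grp_end <- cumsum(rle(ss)$lengths)
  tp <- cumsum(ys)[grp_end]
  npred <- grp_end
  prec <- tp / npred
  rec <- tp / n1
  # precision envelope: max precision at recall >= r, integrated stepwise
  prec_env <- rev(cummax(rev(prec)))
  rec0 <- c(0, rec[-length(rec)])
  pr <- sum((rec - rec0) * prec_env)
  list(roc_auc = roc, pr_auc = pr)
}

#' Bootstrap summary of per-image metric values
#'
#' Non-parametric percentile confidence interval of the resampled mean.
#'
#' @param values finite metric values (NAs removed with a count).
#' @param B bootstrap replicates.
#' @param level confidence level.
#' @param seed RNG seed for the resampling.
#' @return named list `mean`, `sd`, `ci_lower`, `ci_upper`, `n`,
#'   `n_missing`.
#' @export
bootstrap_summary <- function(values, B = 2000L, level = 0.95, seed = 1L) {
  n_missing <- sum(is.na(values))
  v <- values[!is.na(values)]
  if (length(v) == 0) stop("no finite values to summarize", call. = FALSE)
  stopifnot_scalar(B, "B", lower = 1)
  means <- with_seed(seed, {
    vapply(seq_len(B), function(b) mean(v[sample.int(length(v), replace = TRUE)]),
           numeric(1))
  })
  alpha <- (1 - level) / 2
  ci <- quantile(means, c(alpha, 1 - alpha), names = FALSE)
  list(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
       ci_lower = ci[1], ci_upper = ci[2], n = length(v),
       n_missing = n_missing)
}

#' Paired Wilcoxon signed-rank test on per-image metrics
#'
#' Two-sided signed-rank test on the per-image differences; zero differences
#' are dropped (standard convention). The null distribution is exact for
#' n <= 25 without ties, and a normal approximation with continuity
#' correction otherwise.
#'
#' @param values_a,values_b equal-length numeric vectors (n >= 5).
#' @return named list `statistic`, `p_value`, `n_effective`.
#' @export
paired_wilcoxon <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) {
    stop("paired inputs must have equal length", call. = FALSE)
  }
  if (length(values_a) < 5) stop("need at least 5 pairs", call. = FALSE)
  d <- values_a - values_b
  d <- d[d != 0]
  if (length(d) == 0) {
    warning("all paired differences are zero")
    return(list(statistic = 0, p_value = 1, n_effective = 0L))
  }
  exact <- length(d) <= 25
  wt <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, alternative = "two.sided",
                       exact = exact, correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_effective = length(d))
}

#' Per-image metric report with bootstrap summaries
#'
#' Evaluates the full metric suite for each prediction/reference pair and
#' summarizes every metric by mean, SD and a bootstrap CI of the mean.
#'
#' @param predictions list of binary matrices.
#' @param references list of binary matrices.
#' @param ids optional image identifiers.
#' @param tolerance boundary tolerance in pixels.
#' @param B bootstrap replicates.
#' @param seed seed for the bootstrap.
#' @return list with `per_image` (data frame), `summary` (data frame with
#'   mean, sd, ci bounds and missing counts per metric).
#' @export
metric_report <- function(predictions, references, ids = NULL, tolerance = 2,
                          B = 2000L, seed = 1L) {
  if (length(predictions) != length(references)) {
    stop("predictions and references must be paired", call. = FALSE)
  }
  if (is.null(ids)) ids <- sprintf("img%04d", seq_along(predictions))
  rows <- lapply(seq_along(predictions), function(i) {
    p <- predictions[[i]]; y <- references[[i]]
    ov <- overlap_metrics(p, y)
    bd <- boundary_metrics(p, y, tolerance)
    sdm <- surface_distance_metrics(p, y)
    data.frame(id = ids[i], dice = ov$dice, iou = ov$iou,
               accuracy = ov$accuracy, precision = ov$precision,
               recall = ov$recall, boundary_f1 = bd$boundary_f1,
               boundary_accuracy = bd$boundary_accuracy,
               leakage = leakage_rate(p, y),
               assd = sdm$assd, hd95 = sdm$hd95,
               surface_dice = sdm$surface_dice,
               stringsAsFactors = FALSE)
  })
  per_image <- do.call(rbind, rows)
  metric_cols <- setdiff(names(per_image), "id")
  summary <- do.call(rbind, lapply(metric_cols, function(m) {
    bs <- bootstrap_summary(per_image[[m]], B = B, seed = seed)
    data.frame(metric = m, mean = bs$mean, sd = bs$sd,
               ci_lower = bs$ci_lower, ci_upper = bs$ci_upper,
               n = bs$n, n_missing = bs$n_missing, stringsAsFactors = FALSE)
  }))
  list(per_image = per_image, summary = summary)
}
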