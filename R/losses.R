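#' Composite-loss configuration
#'
#' Weights of the training objective
#' `0.45 * Dice + 0.35 * BCE + 0.20 * Lovasz-hinge`, plus the parameters of
#' the auxiliary Tversky and Focal-Dice losses.
#'
#' @param w_dice,w_bce,w_lovasz non-negative weights summing to 1.
#' @param epsilon smoothing constant of the soft Dice/Tversky forms.
#' @param alpha,beta Tversky false-positive / false-negative weights.
#' @param gamma Focal-Dice exponent (> 0).
#' @param focal_variant `"one_minus_dice_pow"` implements `1 - Dice^gamma`;
#'   `"pow_one_minus_dice"` implements `(1 - Dice)^gamma`.
#' @return object of class `loss_config`.
#' @export
loss_config <- function(w_dice = 0.45, w_bce = 0.35, w_lovasz = 0.20,
                        epsilon = 1e-6, alpha = 0.5, beta = 0.5, gamma = 1,
                        focal_variant = c("one_minus_dice_pow",
                                          "pow_one_minus_dice")) {
  if (any(c(w_dice, w_bce, w_lovasz) < 0)) {
    stop("loss weights must be non-negative", call. = FALSE)
  }
  if (abs(w_dice + w_bce + w_lovasz - 1) > 1e-9) {
    stop("loss weights must sum to 1", call. = FALSE)
  }
  stopifnot_scalar(epsilon, "epsilon", lower = 1e-300)
  stopifnot_scalar(gamma, "gamma", lower = 1e-300)
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0", call. = FALSE)
  structure(list(w_dice = w_dice, w_bce = w_bce, w_lovasz = w_lovasz,
                 epsilon = epsilon, alpha = alpha, beta = beta, gamma = gamma,
                 focal_variant = match.arg(focal_variant)),
            class = "loss_config")
}

.check_pair_lengths <- function(a, b) {
  if (length(a) != length(b)) {
    stop("prediction and label lengths differ", call. = FALSE)
  }
}

#' Soft Dice loss (squared-denominator form)
#'
#' `1 - (2 * sum(p*y) + eps) / (sum(p^2) + sum(y^2) + eps)`. The smoothing
#' term appears in numerator and denominator so an empty prediction against
#' an empty label scores loss 0.
#'
#' @param probabilities values in `[0,1]`.
#' @param labels binary labels, same length.
#' @param epsilon smoothing constant.
#' @return scalar loss.
#' @export
dice_loss <- function(probabilities, labels, epsilon = 1e-6) {
  .check_pair_lengths(probabilities, labels)
  p <- as.vector(probabilities); y <- as.vector(labels)
  1 - (2 * sum(p * y) + epsilon) / (sum(p * p) + sum(y * y) + epsilon)
}

#' Numerically stable binary cross-entropy on logits
#'
#' Mean of `-(y*log(sigmoid(z)) + (1-y)*log(1-sigmoid(z)))` computed in the
#' logit domain (`max(z,0) - z*y + log1p(exp(-|z|))`), safe for `|z|` up to
#' at least 1e4.
#'
#' @param logits finite logits.
#' @param labels binary labels.
#' @return scalar loss.
#' @export
bce_loss <- function(logits, labels) {
  .check_pair_lengths(logits, labels)
  z <- as.vector(logits); y <- as.vector(labels)
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}

# Discrete Jaccard gradient over a descending-error ordering of the labels.
.lovasz_grad <- function(y_sorted) {
  gts <- sum(y_sorted)
  intersection <- gts - cumsum(y_sorted)
  union <- gts + cumsum(1 - y_sorted)
  jaccard <- 1 - intersection / union
  n <- length(y_sorted)
  if (n > 1) jaccard <- c(jaccard[1], diff(jaccard))
  jaccard
}

#' Lovasz hinge loss for binary segmentation
#'
#' Hinge errors `e_i = 1 - z_i * (2*y_i - 1)` are sorted in descending order;
#' the loss is the dot product of the rectified sorted errors with the
#' discrete Jaccard gradient of the Lovasz extension. Computed per image and
#' averaged when a list of images is supplied.
#'
#' @param logits finite logits (one image), or a list of per-image logits.
#' @param labels binary labels matching `logits`.
#' @return scalar loss (0 when every pixel is classified with margin >= 1).
#' @export
lovasz_hinge <- function(logits, labels) {
  if (is.list(logits)) {
    vals <- mapply(lovasz_hinge, logits, labels)
    return(mean(vals))
  }
  .check_pair_lengths(logits, labels)
  z <- as.vector(logits); y <- as.vector(labels)
  signs <- 2 * y - 1
  e <- 1 - z * signs
  if (all(e <= 0)) return(0)
  ord <- order(e, decreasing = TRUE)
  grad <- .lovasz_grad(y[ord])
  sum(pmax(e[ord], 0) * grad)
}

# gradient of the per-image lovasz hinge w.r.t. logits
.lovasz_hinge_grad <- function(z, y) {
  signs <- 2 * y - 1
  e <- 1 - z * signs
  g <- numeric(length(z))
  if (all(e <= 0)) return(g)
  ord <- order(e, decreasing = TRUE)
  grad <- .lovasz_grad(y[ord])
  active <- e[ord] > 0
  g[ord] <- ifelse(active, grad, 0) * (-signs[ord])
  g
}

#' Tversky loss with soft counts
#'
#' `1 - (TP + eps) / (TP + alpha*FP + beta*FN + eps)` with soft counts
#' `TP = sum(p*y)`, `FP = sum(p*(1-y))`, `FN = sum((1-p)*y)`. With
#' `alpha = beta = 0.5` this is the set-form soft Dice loss.
#'
#' @param probabilities values in `[0,1]`.
#' @param labels binary labels.
#' @param alpha,beta false-positive / false-negative weights.
#' @param epsilon smoothing constant.
#' @return scalar loss in `[0,1]`.
#' @export
tversky_loss <- function(probabilities, labels, alpha = 0.5, beta = 0.5,
                         epsilon = 1e-6) {
  .check_pair_lengths(probabilities, labels)
  p <- as.vector(probabilities); y <- as.vector(labels)
  tp <- sum(p * y); fp <- sum(p * (1 - y)); fn <- sum((1 - p) * y)
  1 - (tp + epsilon) / (tp + alpha * fp + beta * fn + epsilon)
}

#' Focal-Dice loss
#'
#' Default form `1 - Dice^gamma` (set-form soft Dice); the alternative
#' `(1 - Dice)^gamma` is available via `variant`.
#'
#' @param probabilities values in `[0,1]`.
#' @param labels binary labels.
#' @param gamma positive exponent.
#' @param epsilon smoothing constant.
#' @param variant which focal form to use; see [loss_config()].
#' @return scalar loss.
#' @export
focal_dice_loss <- function(probabilities, labels, gamma = 1, epsilon = 1e-6,
                            variant = c("one_minus_dice_pow",
                                        "pow_one_minus_dice")) {
  variant <- match.arg(variant)
  .check_pair_lengths(probabilities, labels)
  p <- as.vector(probabilities); y <- as.vector(labels)
  dice <- (2 * sum(p * y) + epsilon) / (sum(p) + sum(y) + epsilon)
  if (variant == "one_minus_dice_pow") 1 - dice^gamma else (1 - dice)^gamma
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Composite training loss
#'
#' `w_dice * Dice(sigmoid(z), y) + w_bce * BCE(z, y) + w_lovasz * Lovasz(z, y)`
#' with the printed weights 0.45 / 0.35 / 0.20. The Dice term is evaluated on
#' sigmoid-transformed logits; the Lovasz term is computed per image and
#' averaged.
#'
#' @param logits finite logits (one image) or a list of per-image logits.
#' @param labels binary labels matching `logits`.
#' @param config a [loss_config()].
#' @return scalar total loss with attribute `"terms"` holding the per-term
#'   breakdown (`dice`, `bce`, `lovasz`).
#' @export
combo_loss <- function(logits, labels, config = loss_config()) {
  if (!is.list(logits)) { logits <- list(logits); labels <- list(labels) }
  zs <- unlist(logits); ys <- unlist(labels)
  d <- mean(mapply(function(z, y) dice_loss(sigmoid(z), y, config$epsilon),
                   logits, labels))
  b <- bce_loss(zs, ys)
  l <- lovasz_hinge(logits, labels)
  total <- config$w_dice * d + config$w_bce * b + config$w_lovasz * l
  attr(total, "terms") <- c(dice = d, bce = b, lovasz = l)
  total
}

# Gradient of combo_loss w.r.t. the logits of one image (vectorised).
.combo_loss_grad <- function(z, y, config = loss_config()) {
  p <- sigmoid(z)
  eps <- config$epsilon
  num <- 2 * sum(p * y) + eps
  den <- sum(p * p) + sum(y * y) + eps
  ddice_dp <- -(2 * y * den - num * 2 * p) / (den * den)
  dp_dz <- p * (1 - p)
  g_dice <- ddice_dp * dp_dz
  g_bce <- (p - y) / length(z)
  g_lov <- .lovasz_hinge_grad(z, y)
  config$w_dice * g_dice + config$w_bce * g_bce + config$w_lovasz * g_lov
}
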