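#' Training configuration
#'
#' Defaults follow the reference recipe: AdamW, learning rate 1e-4, weight
#' decay 1e-4, decoder dropout 0.1, 15 epochs with a 2-epoch linear warm-up
#' followed by cosine decay, 256x256 inputs, batch size 16, fixed decision
#' threshold 0.5 at validation/test time.
#'
#' @param learning_rate peak learning rate.
#' @param weight_decay decoupled AdamW weight decay.
#' @param epochs total training epochs.
#' @param warmup_epochs linear warm-up epochs (< epochs).
#' @param batch_size mini-batch size.
#' @param input_size input side in pixels.
#' @param loss a [loss_config()].
#' @param threshold_policy `"fixed_0.5"` or `"sweep"`.
#' @param tta average predictions over flip test-time augmentation.
#' @param augmentation an [augment_policy()] applied to training pairs
#'   (spatial transforms mirrored on masks); use [no_augment()] to disable.
#' @param schedule_unit `"step"` (default, smooth) or `"epoch"`.
#' @param early_stopping_patience epochs without val-Dice improvement before
#'   stopping; `Inf` (default) trains the full schedule.
#' @param seed RNG seed for shuffling, dropout and augmentation.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, weight_decay = 1e-4,
                         epochs = 15L, warmup_epochs = 2L, batch_size = 16L,
                         input_size = 256L, loss = loss_config(),
                         threshold_policy = c("fixed_0.5", "sweep"),
                         tta = FALSE, augmentation = augment_policy(),
                         schedule_unit = c("step", "epoch"),
                         early_stopping_patience = Inf, seed = 1L) {
  if (warmup_epochs >= epochs) stop("warmup_epochs must be < epochs", call. = FALSE)
  stopifnot_scalar(batch_size, "batch_size", lower = 1)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 epochs = as.integer(epochs),
                 warmup_epochs = as.integer(warmup_epochs),
                 batch_size = as.integer(batch_size),
                 input_size = as.integer(input_size), loss = loss,
                 threshold_policy = match.arg(threshold_policy),
                 tta = isTRUE(tta), augmentation = augmentation,
                 schedule_unit = match.arg(schedule_unit),
                 early_stopping_patience = early_stopping_patience,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Desk-scale training configuration for smoke runs
#'
#' CPU-scale stand-in for the full recipe: 64x64 inputs, batch 8, no
#' augmentation, and a 1e-3 peak learning rate. The full-scale default of
#' 1e-4 is tuned for fine-tuning a pretrained encoder; a tiny network
#' trained from random initialization for a few hundred steps needs the
#' conventionally larger from-scratch rate.
#'
#' @param seed RNG seed.
#' @param input_size input side in pixels.
#' @param batch_size mini-batch size.
#' @return a [train_config()].
#' @export
smoke_train_config <- function(seed = 1L, input_size = 64L, batch_size = 8L) {
  train_config(learning_rate = 1e-3, epochs = 15L, warmup_epochs = 2L,
               batch_size = batch_size, input_size = input_size,
               augmentation = no_augment(), seed = seed)
}

#' Patient-level stratified train/val/test splits
#'
#' Patients are stratified by their mean foreground-coverage quartile and
#' assigned whole to one split, so no patient's images leak across splits.
#' Image-count targets are `floor(0.70 * N)` for training,
#' round-half-up of `0.15 * N` for validation, and the remainder for test
#' (reproducing 129/28/28 at N = 185 with the default ratios).
#'
#' @param manifest data frame with columns `image`, `patient_id` and either
#'   a `coverage` column or readable mask files (see [summarize_dataset()]).
#' @param ratios train/val/test fractions summing to 1.
#' @param seed shuffling seed.
#' @return object of class `split_assignment`: a data frame mapping each
#'   image to a split, plus a `patients` attribute with per-patient splits.
#' @export
make_splits <- function(manifest, ratios = c(0.70, 0.15, 0.15), seed = 1L) {
  if (abs(sum(ratios) - 1) > 1e-9) stop("ratios must sum to 1", call. = FALSE)
  if (!all(c("image", "patient_id") %in% names(manifest))) {
    stop("manifest needs columns image and patient_id", call. = FALSE)
  }
  pats <- unique(manifest$patient_id)
  if (length(pats) < 3) stop("need at least 3 patients", call. = FALSE)
  if (!"coverage" %in% names(manifest)) manifest$coverage <- 0
  per_pat <- aggregate(coverage ~ patient_id, data = manifest, FUN = mean)
  n_img_per_pat <- table(manifest$patient_id)
  qs <- quantile(per_pat$coverage, c(0.25, 0.5, 0.75), names = FALSE)
  per_pat$stratum <- findInterval(per_pat$coverage, qs) + 1L

  N <- nrow(manifest)
  n_train <- floor(ratios[1] * N)
  n_val <- round_half_up(ratios[2] * N)

  ordered_pats <- with_seed(seed, {
    # shuffle within strata, then interleave strata so every split samples
    # all coverage quartiles
    by_str <- split(per_pat$patient_id, per_pat$stratum)
    by_str <- lapply(by_str, function(p) p[sample.int(length(p))])
    maxlen <- max(vapply(by_str, length, integer(1)))
    out <- character(0)
    for (i in seq_len(maxlen)) {
      for (s in seq_along(by_str)) {
        if (i <= length(by_str[[s]])) out <- c(out, by_str[[s]][i])
      }
    }
    out
  })
  split_of <- character(length(ordered_pats))
  names(split_of) <- ordered_pats
  acc <- 0L
  for (p in ordered_pats) {
    k <- as.integer(n_img_per_pat[[p]])
    split_of[p] <- if (acc < n_train) "train"
      else if (acc < n_train + n_val) "val" else "test"
    acc <- acc + k
  }
  out <- manifest
  out$split <- unname(split_of[out$patient_id])
  structure(out, patients = split_of, class = c("split_assignment", "data.frame"))
}

#' Warm-up plus cosine learning-rate schedule
#'
#' Linear ramp from 0 to the base rate over the warm-up steps, then cosine
#' decay `base * 0.5 * (1 + cos(pi * progress))` reaching 0 at the final
#' step. The schedule is continuous at the junction (both sides equal the
#' base rate).
#'
#' @param step current step, 1-based, `<= total_steps`.
#' @param total_steps total optimization steps.
#' @param warmup_steps steps in the linear warm-up phase.
#' @param base_lr peak learning rate.
#' @return learning rate at `step`.
#' @export
lr_schedule <- function(step, total_steps, warmup_steps, base_lr = 1e-4) {
  if (warmup_steps > 0 && step <= warmup_steps) {
    return(base_lr * step / warmup_steps)
  }
  progress <- (step - warmup_steps) / max(total_steps - warmup_steps, 1)
  base_lr * 0.5 * (1 + cos(pi * progress))
}

.prep_sample <- function(image, size) {
  img <- normalize_image(image, "zscore")
  if (nrow(img) != size) img <- .resize_bilinear(img, size, size)
  img
}

.eval_split <- function(model, samples, size, threshold = 0.5, batch = 8L,
                        tta = FALSE) {
  dices <- numeric(0); ious <- numeric(0); accs <- numeric(0)
  precs <- numeric(0); recs <- numeric(0); losses <- numeric(0)
  preds <- vector("list", length(samples))
  for (i0 in seq(1, length(samples), by = batch)) {
    idx <- i0:min(i0 + batch - 1, length(samples))
    imgs <- lapply(samples[idx], function(s) .prep_sample(s$image, size))
    msks <- lapply(samples[idx], function(s) {
      m <- s$mask
      if (nrow(m) != size) m <- .resize_nearest(m, size, size)
      m
    })
    if (tta) {
      probs <- lapply(seq_along(imgs), function(j) tta_predict(model, imgs[[j]]))
      x <- .stack_batch(imgs)
      out <- model$forward(x, training = FALSE)
    } else {
      x <- .stack_batch(imgs)
      out <- model$forward(x, training = FALSE)
      probs <- lapply(seq_along(idx), function(n) out$probabilities[, , 1L, n])
    }
    for (j in seq_along(idx)) {
      y <- msks[[j]]
      pm <- (probs[[j]] >= threshold) * 1L
      ov <- overlap_metrics(pm, y)
      dices <- c(dices, ov$dice); ious <- c(ious, ov$iou)
      accs <- c(accs, ov$accuracy); precs <- c(precs, ov$precision)
      recs <- c(recs, ov$recall)
      losses <- c(losses, as.numeric(combo_loss(as.vector(out$logits[, , 1L, j]),
                                                as.vector(y))))
      preds[[idx[j]]] <- probs[[j]]
    }
  }
  list(dice = mean(dices), iou = mean(ious), accuracy = mean(accs),
       precision = mean(precs), recall = mean(recs), loss = mean(losses),
       probabilities = preds)
}

#' Train the segmentation model
#'
#' Seeded mini-batch AdamW loop with per-step warm-up/cosine learning rates,
#' per-epoch validation at threshold 0.5, and in-memory checkpointing of the
#' best validation-Dice parameters (validation loss breaks ties). Images are
#' z-score normalized; augmentation draws are mirrored on the masks.
#'
#' @param train_samples,val_samples lists of samples, each with `image` and
#'   `mask` matrices (e.g. [generate_phantom()] outputs).
#' @param model_cfg a [model_config()].
#' @param cfg a [train_config()].
#' @param steps optional cap on total optimization steps (overrides
#'   `epochs * steps_per_epoch` when smaller); validation still runs at
#'   epoch boundaries and once at the end.
#' @param verbose print one line per epoch.
#' @return list with `model` (best-checkpoint parameters restored),
#'   `history` (per-epoch data frame), `best_epoch`, `lr_trace`.
#' @export
train_model <- function(train_samples, val_samples, model_cfg = slim_model_config(),
                        cfg = train_config(), steps = NULL, verbose = FALSE) {
  if (length(train_samples) == 0 || length(val_samples) == 0) {
    stop("train and val splits must be non-empty", call. = FALSE)
  }
  size <- cfg$input_size
  model <- build_model(model_cfg)
  mods <- collect_modules(model)
  opt <- adamw_state(mods)
  steps_per_epoch <- max(1L, ceiling(length(train_samples) / cfg$batch_size))
  total_steps <- steps_per_epoch * cfg$epochs
  if (!is.null(steps)) total_steps <- min(total_steps, as.integer(steps))
  warmup_steps <- if (cfg$schedule_unit == "step") {
    steps_per_epoch * cfg$warmup_epochs
  } else cfg$warmup_epochs
  n_epochs <- ceiling(total_steps / steps_per_epoch)

  pre <- lapply(train_samples, function(s) {
    img <- s$image
    msk <- s$mask
    if (nrow(img) != size) {
      img <- .resize_bilinear(img, size, size)
      msk <- .resize_nearest(msk, size, size)
    }
    list(image = img, mask = msk)
  })

  history <- list()
  lr_trace <- numeric(0)
  best <- list(dice = -Inf, loss = Inf, epoch = NA_integer_, snap = NULL)
  step <- 0L
  no_improve <- 0L
  with_seed(cfg$seed, {
    for (epoch in seq_len(n_epochs)) {
      ord <- sample.int(length(pre))
      ep_loss <- 0; ep_terms <- c(dice = 0, bce = 0, lovasz = 0); nb <- 0L
      for (b0 in seq(1, length(ord), by = cfg$batch_size)) {
        if (step >= total_steps) break
        step <- step + 1L
        idx <- ord[b0:min(b0 + cfg$batch_size - 1, length(ord))]
        imgs <- list(); msks <- list()
        for (i in idx) {
          pair <- list(image = pre[[i]]$image, mask = pre[[i]]$mask)
          pair <- augment_pair(pair$image, pair$mask, cfg$augmentation)
          imgs[[length(imgs) + 1]] <- normalize_image(pair$image, "zscore")
          msks[[length(msks) + 1]] <- pair$mask
        }
        x <- .stack_batch(imgs)
        out <- model$forward(x, training = TRUE)
        g <- array(0, dim(out$logits))
        bl <- 0; bt <- c(dice = 0, bce = 0, lovasz = 0)
        for (n in seq_along(idx)) {
          z <- as.vector(out$logits[, , 1L, n])
          y <- as.vector(msks[[n]])
          l <- combo_loss(z, y, cfg$loss)
          bl <- bl + as.numeric(l) / length(idx)
          bt <- bt + attr(l, "terms") / length(idx)
          g[, , 1L, n] <- matrix(.combo_loss_grad(z, y, cfg$loss),
                                 dim(out$logits)[1]) / length(idx)
        }
        if (!is.finite(bl)) {
          warning("non-finite training loss; aborting with last finite state")
          break
        }
        zero_grads(mods)
        model$backward(g)
        lr <- if (cfg$schedule_unit == "step") {
          lr_schedule(step, total_steps, warmup_steps, cfg$learning_rate)
        } else {
          lr_schedule(epoch, n_epochs, cfg$warmup_epochs, cfg$learning_rate)
        }
        lr_trace <- c(lr_trace, lr)
        opt <- adamw_step(mods, opt, lr, cfg$weight_decay, t = step)
        ep_loss <- ep_loss + bl; ep_terms <- ep_terms + bt; nb <- nb + 1L
      }
      ev <- .eval_split(model, val_samples, size, threshold = 0.5)
      history[[epoch]] <- data.frame(
        epoch = epoch, train_loss = ep_loss / max(nb, 1L),
        loss_dice = ep_terms[["dice"]] / max(nb, 1L),
        loss_bce = ep_terms[["bce"]] / max(nb, 1L),
        loss_lovasz = ep_terms[["lovasz"]] / max(nb, 1L),
        val_dice = ev$dice, val_iou = ev$iou, val_accuracy = ev$accuracy,
        val_precision = ev$precision, val_recall = ev$recall,
        val_loss = ev$loss, lr = lr_trace[length(lr_trace)])
      improved <- ev$dice > best$dice + 1e-6 ||
        (abs(ev$dice - best$dice) <= 1e-6 && ev$loss < best$loss)
      if (improved) {
        best <- list(dice = ev$dice, loss = ev$loss, epoch = epoch,
                     snap = get_param_state(model))
        no_improve <- 0L
      } else {
        no_improve <- no_improve + 1L
      }
      if (verbose) {
        message(sprintf("epoch %d/%d loss %.4f val dice %.4f", epoch,
                        n_epochs, ep_loss / max(nb, 1L), ev$dice))
      }
      if (no_improve >= cfg$early_stopping_patience) break
      if (step >= total_steps) break
    }
  })
  if (!is.null(best$snap)) set_param_state(model, best$snap)
  hist_df <- do.call(rbind, history)
  list(model = model, history = hist_df, best_epoch = best$epoch,
       lr_trace = lr_trace)
}

#' Select the best checkpoint epoch from a training history
#'
#' Argmax of validation Dice; ties within 1e-6 are broken by lower
#' validation loss, remaining ties by the earlier epoch.
#'
#' @param history data frame with `val_dice` and `val_loss` columns.
#' @return best epoch index (row number).
#' @export
select_checkpoint <- function(history) {
  if (nrow(history) == 0) stop("empty history", call. = FALSE)
  d <- history$val_dice
  cand <- which(d >= max(d) - 1e-6)
  if (length(cand) > 1) {
    l <- history$val_loss[cand]
    cand <- cand[l <= min(l) + 1e-12]
  }
  cand[1]
}

#' Sweep the decision threshold on validation predictions
#'
#' @param probabilities list of probability maps.
#' @param references list of binary masks.
#' @param grid candidate thresholds (default 0.05 to 0.95 by 0.05).
#' @return list with `best_threshold` (ties resolved to the middle of the
#'   maximizing set) and `curve` (threshold vs mean Dice data frame).
#' @export
sweep_threshold <- function(probabilities, references,
                            grid = seq(0.05, 0.95, by = 0.05)) {
  if (length(grid) == 0) stop("empty threshold grid", call. = FALSE)
  mean_dice <- vapply(grid, function(t) {
    mean(mapply(function(p, y) overlap_metrics((p >= t) * 1L, y)$dice,
                probabilities, references))
  }, numeric(1))
  top <- which(mean_dice >= max(mean_dice) - 1e-12)
  best <- grid[top[ceiling(length(top) / 2)]]
  list(best_threshold = best,
       curve = data.frame(threshold = grid, mean_dice = mean_dice))
}

#' Flip test-time augmentation
#'
#' Mean of the model's sigmoid outputs over identity, horizontal flip,
#' vertical flip and the double flip, each prediction inverted back to the
#' original frame before averaging. The result is invariant to flipping the
#' input.
#'
#' @param model a model from [build_model()].
#' @param image a single image matrix.
#' @return probability matrix.
#' @export
tta_predict <- function(model, image) {
  n1 <- nrow(image); n2 <- ncol(image)
  variants <- list(
    list(fwd = identity, inv = identity),
    list(fwd = function(m) m[, n2:1], inv = function(m) m[, n2:1]),
    list(fwd = function(m) m[n1:1, ], inv = function(m) m[n1:1, ]),
    list(fwd = function(m) m[n1:1, n2:1], inv = function(m) m[n1:1, n2:1])
  )
  acc <- matrix(0, n1, n2)
  for (v in variants) {
    p <- predict_proba(model, v$fwd(image))[[1]]
    acc <- acc + v$inv(p)
  }
  acc / 4
}

#' Evaluate a trained model on a sample list
#'
#' @param model trained model.
#' @param samples list of samples with `image` and `mask`.
#' @param input_size network input side.
#' @param threshold decision threshold.
#' @param tta use flip test-time augmentation.
#' @return list with scalar summary metrics and `probabilities`.
#' @export
evaluate_model <- function(model, samples, input_size = 64L, threshold = 0.5,
                           tta = FALSE) {
  .eval_split(model, samples, input_size, threshold, tta = tta)
}

#' Ablation harness over backbones, batch sizes and attention settings
#'
#' Trains one model per grid cell with an identical recipe and reports best
#' validation Dice, IoU, boundary F1, leakage rate and profile arithmetic.
#' Cell failures are recorded and the harness continues.
#'
#' @param train_samples,val_samples sample lists.
#' @param backbones character vector of encoder names.
#' @param batch_sizes integer vector.
#' @param attention_modes character vector of attention modes.
#' @param cfg base [train_config()]; batch size is overridden per cell.
#' @param decoder_channels decoder widths used for every cell.
#' @param steps optional per-cell step cap.
#' @return data frame with one row per grid cell, in grid order.
#' @export
run_ablation <- function(train_samples, val_samples,
                         backbones = "slim-test", batch_sizes = c(16L),
                         attention_modes = c("none", "cbam", "scse", "cbam_scse"),
                         cfg = train_config(), decoder_channels = c(32L, 24L, 16L),
                         steps = NULL) {
  rows <- list()
  for (bk in backbones) for (bs in batch_sizes) for (am in attention_modes) {
    cell <- sprintf("%s/bs%d/%s", bk, bs, am)
    res <- tryCatch({
      ccfg <- cfg
      ccfg$batch_size <- as.integer(bs)
      red <- if (bk == "slim-test") 8L else 16L
      mc <- model_config(encoder = encoder_spec(bk),
                         attention = attention_setting(am, cbam_reduction = red,
                                                       scse_reduction = red),
                         decoder_channels = decoder_channels,
                         decoder_dropout = 0.1, seed = cfg$seed)
      fit <- train_model(train_samples, val_samples, mc, ccfg, steps = steps)
      ev <- .eval_split(fit$model, val_samples, ccfg$input_size, 0.5)
      bf1 <- mean(mapply(function(p, s) {
        y <- s$mask
        if (nrow(y) != ccfg$input_size) y <- .resize_nearest(y, ccfg$input_size, ccfg$input_size)
        boundary_metrics((p >= 0.5) * 1L, y)$boundary_f1
      }, ev$probabilities, val_samples))
      leak <- mean(mapply(function(p, s) {
        y <- s$mask
        if (nrow(y) != ccfg$input_size) y <- .resize_nearest(y, ccfg$input_size, ccfg$input_size)
        leakage_rate((p >= 0.5) * 1L, y)
      }, ev$probabilities, val_samples))
      prof <- profile_backbone(bk)
      data.frame(backbone = bk, batch_size = bs, attention = am,
                 val_dice = ev$dice, val_iou = ev$iou, boundary_f1 = bf1,
                 leakage = leak, params_M = prof$params_M,
                 gmacs = prof$gmacs, error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(backbone = bk, batch_size = bs, attention = am,
                 val_dice = NA, val_iou = NA, boundary_f1 = NA, leakage = NA,
                 params_M = NA, gmacs = NA, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    rows[[cell]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
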