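test_that("split arithmetic yields 129/28/28 training/validation/test images at N = 185", {
  man <- data.frame(image = sprintf("i%03d.png", 1:185),
                    patient_id = sprintf("p%03d", 1:185),
                    coverage = runif(185, 0.2, 0.5))
  sp <- make_splits(man, seed = 3)
  expect_equal(as.integer(table(sp$split)[c("train", "val", "test")]),
               c(129L, 28L, 28L))
  sp2 <- make_splits(man, seed = 3)
  expect_identical(sp$split, sp2$split)
  expect_error(make_splits(man[1:2, ]), "at least 3")
  expect_error(make_splits(man, ratios = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("no patient leaks across splits, even with multi-image patients", {
  set.seed(5)
  man <- data.frame(image = sprintf("i%03d.png", 1:60),
                    patient_id = rep(sprintf("p%02d", 1:20), each = 3),
                    coverage = runif(60, 0.2, 0.5))
  sp <- make_splits(man, seed = 11)
  per_pat <- tapply(sp$split, sp$patient_id, function(x) length(unique(x)))
  expect_true(all(per_pat == 1))
  expect_setequal(unique(sp$split), c("train", "val", "test"))
  # stratification: each split spans the coverage range reasonably
  expect_equal(sum(table(sp$split)), 60)
})

test_that("learning-rate schedule hits its anchors exactly", {
  total <- 150; warm <- 20; base <- 1e-4
  expect_equal(lr_schedule(warm, total, warm, base), base)          # warm-up end
  expect_equal(lr_schedule(warm + (total - warm) / 2, total, warm, base),
               base / 2)                                            # cosine mid
  expect_lt(lr_schedule(total, total, warm, base), 1e-12)           # final step
  # continuity at the junction and monotone warm-up
  expect_equal(lr_schedule(warm + 1e-9, total, warm, base), base,
               tolerance = 1e-6)
  ramp <- vapply(1:warm, lr_schedule, numeric(1), total_steps = total,
                 warmup_steps = warm, base_lr = base)
  expect_true(all(diff(ramp) > 0))
})

test_that("checkpoint selection follows dice, then loss, then epoch", {
  h <- data.frame(val_dice = c(0.5, 0.7, 0.6), val_loss = c(1, 1, 1))
  expect_equal(select_checkpoint(h), 2)
  h2 <- data.frame(val_dice = c(0.7, 0.7), val_loss = c(0.4, 0.3))
  expect_equal(select_checkpoint(h2), 2)
  h3 <- data.frame(val_dice = c(0.7, 0.7), val_loss = c(0.3, 0.3))
  expect_equal(select_checkpoint(h3), 1)
  # invariant to trailing non-improving epochs
  h4 <- rbind(h, data.frame(val_dice = c(0.55, 0.2), val_loss = c(1, 1)))
  expect_equal(select_checkpoint(h4), select_checkpoint(h))
})

test_that("threshold sweep finds the generator cut and is order-invariant", {
  set.seed(9)
  probs <- lapply(1:4, function(i) matrix(runif(256), 16))
  refs <- lapply(probs, function(p) (p > 0.3) * 1L)
  sw <- sweep_threshold(probs, refs)
  expect_lte(abs(sw$best_threshold - 0.3), 0.05 + 1e-9)
  sw2 <- sweep_threshold(rev(probs), rev(refs))
  expect_equal(sw$curve$mean_dice, sw2$curve$mean_dice)
  # binary probabilities: all thresholds tie, the midpoint rule applies
  bp <- list(matrix(rep(c(0, 1), 32), 8))
  swb <- sweep_threshold(bp, list((bp[[1]] > 0) * 1L))
  expect_equal(swb$best_threshold, 0.5)
  expect_error(sweep_threshold(probs, refs, grid = numeric(0)), "empty")
})

test_that("flip TTA averages aligned passes and symmetrizes the output", {
  model <- build_model(slim_model_config("none", seed = 4))
  s <- generate_phantom(phantom_config(image_size = 64, seed = 3))
  img <- normalize_image(s$image, "zscore")
  tta <- tta_predict(model, img)
  # explicit four-pass computation
  n <- 64
  manual <- (predict_proba(model, img)[[1]] +
             predict_proba(model, img[, n:1])[[1]][, n:1] +
             predict_proba(model, img[n:1, ])[[1]][n:1, ] +
             predict_proba(model, img[n:1, n:1])[[1]][n:1, n:1]) / 4
  expect_equal(tta, manual, tolerance = 1e-12)
  # symmetrization: TTA of the flipped input is the flipped TTA
  tta_f <- tta_predict(model, img[, n:1])
  expect_equal(tta_f, tta[, n:1], tolerance = 1e-12)
})

test_that("smoke training learns phantom segmentation deterministically", {
  tr <- test_phantoms(1:16, size = 64)
  va <- test_phantoms(101:106, size = 64)
  cfg <- smoke_train_config(seed = 21)
  cfg$epochs <- 3L
  fit <- train_model(tr, va, slim_model_config("cbam_scse", seed = 21), cfg)
  expect_equal(nrow(fit$history), 3)
  # learning happens: validation dice improves over the first epoch
  expect_gt(fit$history$val_dice[3], fit$history$val_dice[1])
  # logged lr sequence matches the schedule pointwise
  spe <- ceiling(16 / cfg$batch_size)
  want <- vapply(seq_len(spe * 3), lr_schedule, numeric(1),
                 total_steps = spe * cfg$epochs,
                 warmup_steps = spe * cfg$warmup_epochs,
                 base_lr = cfg$learning_rate)
  expect_equal(fit$lr_trace, want[seq_along(fit$lr_trace)], tolerance = 1e-12)
  # identical seeds give identical loss trajectories
  fit2 <- train_model(tr, va, slim_model_config("cbam_scse", seed = 21), cfg)
  expect_identical(fit$history$train_loss, fit2$history$train_loss)
  expect_identical(fit$history$val_dice, fit2$history$val_dice)
})

test_that("ablation harness instantiates the four attention settings", {
  tr <- test_phantoms(1:8, size = 64)
  va <- test_phantoms(101:103, size = 64)
  tab <- run_ablation(tr, va, backbones = "slim-test", batch_sizes = 4L,
                      attention_modes = c("none", "cbam", "scse", "cbam_scse"),
                      cfg = smoke_train_config(seed = 2, batch_size = 4L),
                      steps = 4L)
  expect_equal(nrow(tab), 4)
  expect_true(all(is.finite(tab$val_dice)))
  expect_true(all(is.finite(tab$boundary_f1)))
  expect_true(all(is.na(tab$error)))
  tab2 <- run_ablation(tr, va, backbones = "slim-test", batch_sizes = 4L,
                       attention_modes = c("none", "cbam", "scse", "cbam_scse"),
                       cfg = smoke_train_config(seed = 2, batch_size = 4L),
                       steps = 4L)
  expect_equal(tab$val_dice, tab2$val_dice)
})
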