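#' Assemble a run report from a completed run directory
#'
#' Collates the configuration echo, training history, per-image metric
#' tables, pseudo-mask agreement and (when present) ablation table into one
#' JSON-ready structure. Missing pieces are listed, not fatal; an empty
#' directory is an error.
#'
#' @param run_dir run directory produced by [end_to_end_demo()] or the
#'   command-line tools.
#' @return named list (class `run_report`); written alongside as
#'   `report.json` by [end_to_end_demo()].
#' @export
assemble_report <- function(run_dir) {
  if (!dir.exists(run_dir) || length(list.files(run_dir)) == 0) {
    stop(sprintf("run directory '%s' is empty or missing", run_dir),
         call. = FALSE)
  }
  pieces <- list(
    config = "config_echo.yaml",
    history = "history.csv",
    test_metrics = "test_metrics.csv",
    test_summary = "test_summary.json",
    pseudo_agreement = "pseudo_agreement.csv",
    ablation = "ablation.csv"
  )
  report <- list(missing = character(0), files = character(0))
  for (nm in names(pieces)) {
    path <- file.path(run_dir, pieces[[nm]])
    if (!file.exists(path)) {
      report$missing <- c(report$missing, pieces[[nm]])
      next
    }
    report$files <- c(report$files, pieces[[nm]])
    report[[nm]] <- switch(nm,
      config = yaml::read_yaml(path),
      test_summary = jsonlite::read_json(path, simplifyVector = TRUE),
      read.csv(path, stringsAsFactors = FALSE)
    )
  }
  class(report) <- "run_report"
  report
}

#' End-to-end demonstration pipeline on synthetic phantoms
#'
#' Generates phantoms, derives CLAHE+Otsu pseudo-masks, builds leakage-free
#' patient-level splits, trains the compact attention model on the
#' pseudo-masks (weak supervision), evaluates the test split against the
#' true phantom masks under both threshold policies and flip TTA, and writes
#' a full run report. Runs offline on one CPU.
#'
#' @param seed global seed.
#' @param out_dir run directory (created; must not contain a manifest).
#' @param n_phantoms number of phantoms.
#' @param image_size phantom/network input side (multiple of 32).
#' @param epochs training epochs.
#' @return path to `report.json`, invisibly; the report object as attribute
#'   `"report"`.
#' @export
end_to_end_demo <- function(seed = 1L, out_dir = tempfile("raxseg_demo_"),
                            n_phantoms = 60L, image_size = 64L,
                            epochs = 10L) {
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("demo stage '%s' failed: %s", what, conditionMessage(e)),
           call. = FALSE)
    })
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  phantom_dir <- file.path(out_dir, "phantoms")
  stage("phantoms", {
    generate_dataset(n_phantoms, base_seed = seed,
                     out_dir = phantom_dir,
                     config = phantom_config(image_size = image_size,
                                             seed = seed))
  })
  manifest <- read.csv(file.path(phantom_dir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  samples <- stage("load", lapply(seq_len(nrow(manifest)), function(i) {
    list(image = read_gray(file.path(phantom_dir, manifest$image[i])),
         mask = read_mask(file.path(phantom_dir, manifest$mask[i])),
         patient_id = manifest$patient_id[i])
  }))

  pm_dir <- file.path(out_dir, "pseudomasks")
  dir.create(pm_dir, showWarnings = FALSE)
  pseudo <- stage("pseudomask", lapply(seq_along(samples), function(i) {
    pm <- make_pseudo_mask(samples[[i]]$image)
    write_mask_png(pm, file.path(pm_dir, manifest$mask[i]))
    pm
  }))
  agree <- stage("pseudo-agreement", {
    evaluate_pseudo(pseudo, lapply(samples, `[[`, "mask"))
  })
  write.csv(agree$per_image, file.path(out_dir, "pseudo_agreement.csv"),
            row.names = FALSE)

  manifest$coverage <- vapply(samples, function(s) mean(s$mask), numeric(1))
  splits <- stage("splits", make_splits(manifest, seed = seed))
  train_idx <- which(splits$split == "train")
  val_idx <- which(splits$split == "val")
  test_idx <- which(splits$split == "test")

  # weak supervision: train/validate on pseudo-masks, test on true masks
  weak <- lapply(seq_along(samples), function(i) {
    list(image = samples[[i]]$image, mask = pseudo[[i]])
  })
  tcfg <- smoke_train_config(seed = seed, input_size = image_size)
  tcfg$epochs <- as.integer(epochs)
  fit <- stage("train", {
    train_model(weak[train_idx], weak[val_idx],
                slim_model_config("cbam_scse", seed = seed), tcfg)
  })
  write.csv(fit$history, file.path(out_dir, "history.csv"), row.names = FALSE)

  stage("eval", {
    ev_fixed <- evaluate_model(fit$model, samples[test_idx], image_size, 0.5)
    sw <- sweep_threshold(
      evaluate_model(fit$model, weak[val_idx], image_size, 0.5)$probabilities,
      lapply(weak[val_idx], `[[`, "mask"))
    ev_swept <- evaluate_model(fit$model, samples[test_idx], image_size,
                               sw$best_threshold)
    ev_tta <- evaluate_model(fit$model, samples[test_idx], image_size, 0.5,
                             tta = TRUE)
    preds <- lapply(ev_fixed$probabilities, function(p) (p >= 0.5) * 1L)
    rep_test <- metric_report(preds, lapply(samples[test_idx], `[[`, "mask"),
                              ids = manifest$image[test_idx], B = 500L,
                              seed = seed)
    write.csv(rep_test$per_image, file.path(out_dir, "test_metrics.csv"),
              row.names = FALSE)
    summary_json <- list(
      threshold_fixed = 0.5,
      threshold_swept = sw$best_threshold,
      test_dice_fixed = ev_fixed$dice,
      test_dice_swept = ev_swept$dice,
      test_dice_tta = ev_tta$dice,
      test_iou_fixed = ev_fixed$iou,
      best_epoch = fit$best_epoch,
      metric_summary = rep_test$summary,
      n_train = length(train_idx), n_val = length(val_idx),
      n_test = length(test_idx)
    )
    jsonlite::write_json(summary_json, file.path(out_dir, "test_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  cfg <- parse_and_validate(NULL, list(
    run = list(seed = seed),
    phantom = list(image_size = image_size),
    preprocess = list(target_size = image_size),
    train = list(input_size = image_size, epochs = as.integer(epochs),
                 batch_size = tcfg$batch_size,
                 learning_rate = tcfg$learning_rate)
  ))
  write_config_echo(cfg, file.path(out_dir, "config_echo.yaml"))

  report <- assemble_report(out_dir)
  path <- file.path(out_dir, "report.json")
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  attr(path, "report") <- report
  invisible(path)
}
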