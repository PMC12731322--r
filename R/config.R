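# Run-level configuration: a flat key/value document with dotted sections
# (YAML), validated against the known schema with the reference defaults.

.run_defaults <- function() {
  list(
    "run.name" = "raxseg-run",
    "run.seed" = 1L,
    "phantom.image_size" = 256L,
    "phantom.n_fingers" = 5L,
    "phantom.coverage_target" = 0.35,
    "phantom.bias_strength" = 0.15,
    "phantom.noise_sigma" = 0.02,
    "preprocess.p_low" = 1,
    "preprocess.p_high" = 99,
    "preprocess.bias_correction" = TRUE,
    "preprocess.normalization" = "zscore",
    "preprocess.target_size" = 256L,
    "pseudomask.clahe_clip" = 2.0,
    "pseudomask.clahe_tiles" = 8L,
    "pseudomask.relax_factor" = 0.95,
    "pseudomask.open_radius" = 2L,
    "pseudomask.close_radius" = 2L,
    "pseudomask.keep_largest" = TRUE,
    "model.encoder" = "efficientnet-b3",
    "model.attention" = "cbam_scse",
    "model.decoder_dropout" = 0.1,
    "model.deep_supervision" = FALSE,
    "loss.w_dice" = 0.45,
    "loss.w_bce" = 0.35,
    "loss.w_lovasz" = 0.20,
    "train.learning_rate" = 1e-4,
    "train.weight_decay" = 1e-4,
    "train.epochs" = 15L,
    "train.warmup_epochs" = 2L,
    "train.batch_size" = 16L,
    "train.input_size" = 256L,
    "train.threshold_policy" = "fixed_0.5",
    "train.tta" = FALSE
  )
}

.flatten_config <- function(x, prefix = NULL) {
  out <- list()
  for (nm in names(x)) {
    key <- if (is.null(prefix)) nm else paste(prefix, nm, sep = ".")
    if (is.list(x[[nm]])) {
      out <- c(out, .flatten_config(x[[nm]], key))
    } else {
      out[[key]] <- x[[nm]]
    }
  }
  out
}

#' Parse and validate a run configuration
#'
#' Reads a YAML configuration (sections become dotted keys), fills in the
#' reference defaults, applies command-line overrides (which win), and
#' validates every value. Unknown keys are an error, never silently ignored.
#'
#' @param config_file optional YAML path; `NULL` uses pure defaults.
#' @param cli_overrides named list of `key = value` overrides using dotted
#'   key paths.
#' @return named list (class `run_config`) with every known key populated.
#' @export
parse_and_validate <- function(config_file = NULL, cli_overrides = list()) {
  cfg <- .run_defaults()
  supplied <- list()
  if (!is.null(config_file)) {
    if (!file.exists(config_file)) {
      stop(sprintf("config file '%s' not found", config_file), call. = FALSE)
    }
    supplied <- .flatten_config(yaml::read_yaml(config_file))
  }
  supplied <- utils::modifyList(supplied, .flatten_config(cli_overrides))
  unknown <- setdiff(names(supplied), names(cfg))
  if (length(unknown) > 0) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  for (nm in names(supplied)) {
    tmpl <- cfg[[nm]]
    val <- supplied[[nm]]
    if (is.numeric(tmpl)) {
      if (!is.numeric(val) || length(val) != 1 || !is.finite(val)) {
        stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
      }
      if (is.integer(tmpl)) val <- as.integer(val)
    } else if (is.logical(tmpl) && !is.logical(val)) {
      stop(sprintf("'%s' must be logical", nm), call. = FALSE)
    }
    cfg[[nm]] <- val
  }
  ws <- cfg[["loss.w_dice"]] + cfg[["loss.w_bce"]] + cfg[["loss.w_lovasz"]]
  if (abs(ws - 1) > 1e-9) {
    stop(sprintf("loss.w_dice + loss.w_bce + loss.w_lovasz must sum to 1 (got %s)",
                 format(ws)), call. = FALSE)
  }
  if (cfg[["train.warmup_epochs"]] >= cfg[["train.epochs"]]) {
    stop("train.warmup_epochs must be below train.epochs", call. = FALSE)
  }
  if (!cfg[["model.attention"]] %in% c("none", "cbam", "scse", "cbam_scse")) {
    stop("model.attention must be one of none/cbam/scse/cbam_scse", call. = FALSE)
  }
  if (cfg[["pseudomask.relax_factor"]] <= 0 || cfg[["pseudomask.relax_factor"]] > 1) {
    stop("pseudomask.relax_factor must be in (0, 1]", call. = FALSE)
  }
  class(cfg) <- "run_config"
  cfg
}

#' Write a run configuration echo to YAML
#'
#' @param cfg a `run_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config_echo <- function(cfg, path) {
  nested <- list()
  for (nm in names(cfg)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    nested[[parts[1]]][[parts[2]]] <- cfg[[nm]]
  }
  yaml::write_yaml(nested, path)
  invisible(path)
}
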