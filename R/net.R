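#' Encoder specification
#'
#' Known backbones expose four feature stages E1..E4 at strides 4/8/16/32.
#' `slim-test` is a tiny (< 100k parameter) convolutional encoder meant for
#' CPU tests and smoke training. The named large backbones are realized as
#' randomly initialized pyramid encoders with the reference architectures'
#' stage widths and strides (no pretrained weights are shipped);
#' [profile_backbone()] reports the reference architectures' exact parameter
#' and multiply-accumulate arithmetic.
#'
#' @param name one of `"efficientnet-b0"`, `"efficientnet-b3"`,
#'   `"resnet50"`, `"convnext-tiny"`, `"slim-test"`.
#' @param pretrained must be `FALSE`; accepted for interface compatibility.
#' @return object of class `encoder_spec` with `stage_channels` and
#'   `stage_strides`.
#' @export
encoder_spec <- function(name = c("slim-test", "efficientnet-b0",
                                  "efficientnet-b3", "resnet50",
                                  "convnext-tiny"),
                         pretrained = FALSE) {
  known <- list(
    "slim-test" = c(16L, 24L, 32L, 48L),
    "efficientnet-b0" = c(24L, 40L, 112L, 320L),
    "efficientnet-b3" = c(32L, 48L, 136L, 384L),
    "resnet50" = c(256L, 512L, 1024L, 2048L),
    "convnext-tiny" = c(96L, 192L, 384L, 768L)
  )
  if (length(name) > 1) name <- name[1]
  if (!name %in% names(known)) {
    stop(sprintf("unknown encoder '%s'; choices: %s", name,
                 paste(names(known), collapse = ", ")), call. = FALSE)
  }
  if (isTRUE(pretrained)) {
    stop("pretrained weights are not shipped; use pretrained = FALSE",
         call. = FALSE)
  }
  structure(list(name = name, stage_channels = known[[name]],
                 stage_strides = c(4L, 8L, 16L, 32L), pretrained = FALSE),
            class = "encoder_spec")
}

#' Attention setting of the decoder
#'
#' @param mode `"none"`, `"cbam"`, `"scse"` or `"cbam_scse"`. `"cbam"`
#'   contains no squeeze-excitation anywhere; `"scse"` adds the encoder-skip
#'   gate in up block 1 and post-convolution gates in blocks 2-3.
#' @param cbam_reduction,scse_reduction channel reductions of the gates.
#' @param cbam_spatial_kernel odd spatial-gate kernel.
#' @return object of class `attention_setting`.
#' @export
attention_setting <- function(mode = c("cbam_scse", "none", "cbam", "scse"),
                              cbam_reduction = 16L, cbam_spatial_kernel = 7L,
                              scse_reduction = 16L) {
  mode <- match.arg(mode)
  if (cbam_spatial_kernel %% 2L == 0L) {
    stop("cbam_spatial_kernel must be odd", call. = FALSE)
  }
  structure(list(mode = mode, cbam_reduction = as.integer(cbam_reduction),
                 cbam_spatial_kernel = as.integer(cbam_spatial_kernel),
                 scse_reduction = as.integer(scse_reduction)),
            class = "attention_setting")
}

#' Model configuration
#'
#' @param encoder an [encoder_spec()] or encoder name.
#' @param attention an [attention_setting()].
#' @param decoder_channels three positive channel widths for the three
#'   up-sampling blocks.
#' @param out_channels output channels (only 1, binary, is exercised).
#' @param decoder_dropout dropout rate applied at the end of each up block.
#' @param deep_supervision attach auxiliary sigmoid heads after up blocks
#'   1 and 2 (loss weights 0.4 and 0.2 during training).
#' @param seed weight-initialization seed.
#' @return object of class `model_config`.
#' @export
model_config <- function(encoder = encoder_spec("efficientnet-b3"),
                         attention = attention_setting("cbam_scse"),
                         decoder_channels = c(256L, 128L, 64L),
                         out_channels = 1L, decoder_dropout = 0.1,
                         deep_supervision = FALSE, seed = 1L) {
  if (is.character(encoder)) encoder <- encoder_spec(encoder)
  if (length(decoder_channels) != 3L || any(decoder_channels <= 0)) {
    stop("decoder_channels must be three positive widths", call. = FALSE)
  }
  stopifnot_scalar(decoder_dropout, "decoder_dropout", 0, 1)
  structure(list(encoder = encoder, attention = attention,
                 decoder_channels = as.integer(decoder_channels),
                 out_channels = as.integer(out_channels),
                 decoder_dropout = decoder_dropout,
                 deep_supervision = isTRUE(deep_supervision),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Compact model configuration for CPU-scale experiments
#'
#' `slim-test` encoder with a narrow decoder; used by the smoke-training
#' tests and the end-to-end demo.
#'
#' @param attention attention mode name or [attention_setting()].
#' @param seed initialization seed.
#' @return a [model_config()].
#' @export
slim_model_config <- function(attention = "cbam_scse", seed = 1L) {
  if (is.character(attention)) {
    attention <- attention_setting(attention, cbam_reduction = 8L,
                                   scse_reduction = 8L)
  }
  model_config(encoder = encoder_spec("slim-test"), attention = attention,
               decoder_channels = c(32L, 24L, 16L), decoder_dropout = 0.1,
               seed = seed)
}

.conv_bn_silu <- function(cin, cout, k = 3L, stride = 1L) {
  mod_sequential(list(conv = mod_conv2d(cin, cout, k, stride, bias = FALSE),
                      bn = mod_batchnorm(cout), act = mod_silu()))
}

# Four-stage pyramid encoder: stem at stride 2, one stage per further
# halving; E1..E4 tapped at strides 4/8/16/32.
.make_pyramid_encoder <- function(stage_channels, stem_ch, convs_per_stage = 1L) {
  stem <- .conv_bn_silu(1L, stem_ch, stride = 2L)
  stages <- list()
  cin <- stem_ch
  for (i in 1:4) {
    blocks <- list(.conv_bn_silu(cin, stage_channels[i], stride = 2L))
    if (convs_per_stage > 1L) {
      for (j in seq_len(convs_per_stage - 1L)) {
        blocks <- c(blocks, list(.conv_bn_silu(stage_channels[i],
                                               stage_channels[i])))
      }
    }
    stages[[i]] <- mod_sequential(blocks)
    cin <- stage_channels[i]
  }
  m <- new_module("encoder", children = c(list(stem = stem),
                                          stats::setNames(stages, paste0("s", 1:4))))
  m$stage_channels <- stage_channels
  m$forward <- function(x, training = FALSE) {
    h <- m$children$stem$forward(x, training)
    e1 <- m$children$s1$forward(h, training)
    e2 <- m$children$s2$forward(e1, training)
    e3 <- m$children$s3$forward(e2, training)
    e4 <- m$children$s4$forward(e3, training)
    list(e1 = e1, e2 = e2, e3 = e3, e4 = e4)
  }
  m$backward <- function(g) {
    # g: list ge1..ge4 (NULL entries allowed)
    zero <- function(ref) array(0, dim(ref))
    g4 <- g$e4
    g3 <- m$children$s4$backward(g4)
    if (!is.null(g$e3)) g3 <- g3 + g$e3
    g2 <- m$children$s3$backward(g3)
    if (!is.null(g$e2)) g2 <- g2 + g$e2
    g1 <- m$children$s2$backward(g2)
    if (!is.null(g$e1)) g1 <- g1 + g$e1
    gh <- m$children$s1$backward(g1)
    m$children$stem$backward(gh)
  }
  m
}

#' Build a feature-pyramid encoder
#'
#' @param spec an [encoder_spec()] or encoder name.
#' @return an encoder module whose `forward(x)` returns the feature pyramid
#'   `list(e1, e2, e3, e4)` at strides 4/8/16/32.
#' @export
build_encoder <- function(spec = encoder_spec("slim-test")) {
  if (is.character(spec)) spec <- encoder_spec(spec)
  if (spec$name == "slim-test") {
    .make_pyramid_encoder(spec$stage_channels, stem_ch = 12L,
                          convs_per_stage = 1L)
  } else {
    .make_pyramid_encoder(spec$stage_channels,
                          stem_ch = max(16L, spec$stage_channels[1] %/% 2L),
                          convs_per_stage = 2L)
  }
}

# One attention-gated up-sampling block. Block 1 gates the encoder skip with
# scSE before concatenation (modes scse / cbam_scse); blocks 2-3 apply CBAM
# to the concatenated tensor and scSE after the convolution pair.
.make_up_block <- function(up_ch, skip_ch, out_ch, index, attention, dropout) {
  mode <- attention$mode
  use_cbam <- mode %in% c("cbam", "cbam_scse") && index > 1L
  use_scse_skip <- mode %in% c("scse", "cbam_scse") && index == 1L
  use_scse_out <- mode %in% c("scse", "cbam_scse") && index > 1L
  children <- list(
    up = mod_upsample(2L),
    conv1 = .conv_bn_silu(up_ch + skip_ch, out_ch),
    conv2 = .conv_bn_silu(out_ch, out_ch),
    drop = mod_dropout(dropout)
  )
  if (use_scse_skip) children$scse_skip <- mod_scse(skip_ch, attention$scse_reduction)
  if (use_cbam) children$cbam <- mod_cbam(up_ch + skip_ch,
                                          attention$cbam_reduction,
                                          attention$cbam_spatial_kernel)
  if (use_scse_out) children$scse_out <- mod_scse(out_ch, attention$scse_reduction)
  m <- new_module("up_block", children = children)
  m$up_ch <- up_ch
  m$forward <- function(u, skip, training = FALSE) {
    s <- if (!is.null(m$children$scse_skip)) {
      m$children$scse_skip$forward(skip, training)
    } else skip
    uu <- m$children$up$forward(u, training)
    if (!all(dim(uu)[1:2] == dim(s)[1:2])) {
      stop(sprintf("spatial mismatch after upsample: %s vs skip %s",
                   paste(dim(uu)[1:2], collapse = "x"),
                   paste(dim(s)[1:2], collapse = "x")), call. = FALSE)
    }
    z <- concat_channels(uu, s)
    if (!is.null(m$children$cbam)) z <- m$children$cbam$forward(z, training)
    z <- m$children$conv1$forward(z, training)
    z <- m$children$conv2$forward(z, training)
    if (!is.null(m$children$scse_out)) z <- m$children$scse_out$forward(z, training)
    m$children$drop$forward(z, training)
  }
  m$backward <- function(gy) {
    g <- m$children$drop$backward(gy)
    if (!is.null(m$children$scse_out)) g <- m$children$scse_out$backward(g)
    g <- m$children$conv2$backward(g)
    g <- m$children$conv1$backward(g)
    if (!is.null(m$children$cbam)) g <- m$children$cbam$backward(g)
    sp <- split_channels(g, m$up_ch)
    gu <- m$children$up$backward(sp[[1]])
    gskip <- sp[[2]]
    if (!is.null(m$children$scse_skip)) gskip <- m$children$scse_skip$backward(gskip)
    list(gu = gu, gskip = gskip)
  }
  m
}

#' Build the hybrid attention segmentation network
#'
#' Feature-pyramid encoder, three attention-gated up-sampling blocks
#' consuming skips E3, E2, E1 (ending at stride 4), a parameter-free
#' bilinear x4 upsample, and a 1x1 sigmoid head at full resolution.
#'
#' @param config a [model_config()].
#' @return a model object with `forward`/`backward` closures; use
#'   [predict_proba()] for inference.
#' @export
build_model <- function(config = model_config()) {
  with_seed(config$seed, {
    enc <- build_encoder(config$encoder)
    ch <- config$encoder$stage_channels
    dc <- config$decoder_channels
    up1 <- .make_up_block(ch[4], ch[3], dc[1], 1L, config$attention,
                          config$decoder_dropout)
    up2 <- .make_up_block(dc[1], ch[2], dc[2], 2L, config$attention,
                          config$decoder_dropout)
    up3 <- .make_up_block(dc[2], ch[1], dc[3], 3L, config$attention,
                          config$decoder_dropout)
    final_up <- mod_upsample(4L)
    head <- mod_conv2d(dc[3], config$out_channels, k = 1L, bias = TRUE)
    children <- list(encoder = enc, up1 = up1, up2 = up2, up3 = up3,
                     final_up = final_up, head = head)
    if (config$deep_supervision) {
      children$aux1 <- mod_conv2d(dc[1], config$out_channels, k = 1L, bias = TRUE)
      children$aux2 <- mod_conv2d(dc[2], config$out_channels, k = 1L, bias = TRUE)
    }
    m <- new_module("hybrid_unet", children = children)
    m$config <- config
    m$forward <- function(x, training = FALSE) {
      d <- dim(x)
      if (d[1] %% 32L != 0L || d[2] %% 32L != 0L) {
        stop(sprintf("input side %dx%d not divisible by 32; pad the input",
                     d[1], d[2]), call. = FALSE)
      }
      f <- m$children$encoder$forward(x, training)
      d3 <- m$children$up1$forward(f$e4, f$e3, training)
      d2 <- m$children$up2$forward(d3, f$e2, training)
      d1 <- m$children$up3$forward(d2, f$e1, training)
      u <- m$children$final_up$forward(d1, training)
      logits <- m$children$head$forward(u, training)
      out <- list(logits = logits, probabilities = sigmoid(logits))
      if (!is.null(m$children$aux1)) {
        out$aux <- list(sigmoid(m$children$aux1$forward(d3, training)),
                        sigmoid(m$children$aux2$forward(d2, training)))
        m$cache_aux <- TRUE
      }
      out
    }
    m$backward <- function(glogits, gaux = NULL) {
      gu <- m$children$head$backward(glogits)
      gd1 <- m$children$final_up$backward(gu)
      b3 <- m$children$up3$backward(gd1)
      gd2 <- b3$gu
      if (!is.null(gaux) && !is.null(m$children$aux2)) {
        gd2 <- gd2 + m$children$aux2$backward(gaux[[2]])
      }
      b2 <- m$children$up2$backward(gd2)
      gd3 <- b2$gu
      if (!is.null(gaux) && !is.null(m$children$aux1)) {
        gd3 <- gd3 + m$children$aux1$backward(gaux[[1]])
      }
      b1 <- m$children$up1$backward(gd3)
      m$children$encoder$backward(list(e1 = b3$gskip, e2 = b2$gskip,
                                       e3 = b1$gskip, e4 = b1$gu))
    }
    m
  })
}

#' Predict foreground probabilities for a batch of images
#'
#' @param model a model from [build_model()].
#' @param images a single matrix or list of matrices (sides divisible by 32).
#' @return list of probability matrices in (0,1).
#' @export
predict_proba <- function(model, images) {
  if (is.matrix(images)) images <- list(images)
  x <- .stack_batch(images)
  out <- model$forward(x, training = FALSE)
  lapply(seq_along(images), function(n) out$probabilities[, , 1L, n])
}

.stack_batch <- function(images) {
  d <- dim(images[[1]])
  x <- array(0, c(d[1], d[2], 1L, length(images)))
  for (n in seq_along(images)) x[, , 1L, n] <- images[[n]]
  x
}
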