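# Architecture profiling: exact layer-by-layer parameter and
# multiply-accumulate arithmetic for the standard ImageNet classification
# form of each encoder backbone (1000-class head included), at the
# architecture's standard input resolution. Convolution and linear layers
# contribute MACs; normalisation and activations contribute parameters only.

.layer_conv <- function(k, cin, cout, hw, groups = 1L, bias = FALSE) {
  list(type = "conv", params = k * k * (cin / groups) * cout + if (bias) cout else 0,
       macs = k * k * (cin / groups) * cout * hw * hw)
}
.layer_norm <- function(C) list(type = "norm", params = 2 * C, macs = 0)
.layer_linear <- function(cin, cout, bias = TRUE) {
  list(type = "linear", params = cin * cout + if (bias) cout else 0,
       macs = cin * cout)
}
.layer_raw <- function(params) list(type = "raw", params = params, macs = 0)

.sum_layers <- function(layers) {
  list(params = sum(vapply(layers, `[[`, numeric(1), "params")),
       macs = sum(vapply(layers, `[[`, numeric(1), "macs")))
}

.arch_resnet50 <- function(input = 224L) {
  L <- list(.layer_conv(7, 3, 64, input / 2), .layer_norm(64))
  hw <- input / 4
  bottleneck <- function(cin, width, cout, hw_in, stride) {
    hw_out <- hw_in / stride
    ls <- list(.layer_conv(1, cin, width, hw_in), .layer_norm(width),
               .layer_conv(3, width, width, hw_out), .layer_norm(width),
               .layer_conv(1, width, cout, hw_out), .layer_norm(cout))
    if (cin != cout || stride != 1) {
      ls <- c(ls, list(.layer_conv(1, cin, cout, hw_out), .layer_norm(cout)))
    }
    ls
  }
  stages <- list(c(64, 64, 256, 3, 1), c(256, 128, 512, 4, 2),
                 c(512, 256, 1024, 6, 2), c(1024, 512, 2048, 3, 2))
  for (st in stages) {
    cin <- st[1]; width <- st[2]; cout <- st[3]; reps <- st[4]; stride <- st[5]
    L <- c(L, bottleneck(cin, width, cout, hw, stride))
    hw <- hw / stride
    for (r in seq_len(reps - 1)) L <- c(L, bottleneck(cout, width, cout, hw, 1))
  }
  c(L, list(.layer_linear(2048, 1000)))
}

.arch_convnext_tiny <- function(input = 224L) {
  dims <- c(96, 192, 384, 768)
  depths <- c(3, 3, 9, 3)
  L <- list(.layer_conv(4, 3, dims[1], input / 4, bias = TRUE),
            .layer_norm(dims[1]))
  hw <- input / 4
  block <- function(d, hw) {
    list(.layer_conv(7, d, d, hw, groups = d, bias = TRUE),  # depthwise
         .layer_norm(d),
         .layer_linear(d, 4 * d), .layer_linear(4 * d, d),
         .layer_raw(d)) |>
      (\(ls) { ls[[3]]$macs <- ls[[3]]$macs * hw * hw
               ls[[4]]$macs <- ls[[4]]$macs * hw * hw; ls })()
  }
  for (s in 1:4) {
    if (s > 1) {
      L <- c(L, list(.layer_norm(dims[s - 1]),
                     .layer_conv(2, dims[s - 1], dims[s], hw / 2, bias = TRUE)))
      hw <- hw / 2
    }
    for (r in seq_len(depths[s])) L <- c(L, block(dims[s], hw))
  }
  c(L, list(.layer_norm(768) , .layer_linear(768, 1000)))
}

.round_filters <- function(f, width_mult, divisor = 8L) {
  if (width_mult == 1) return(as.integer(f))
  v <- f * width_mult
  newv <- max(divisor, (floor(v + divisor / 2) %/% divisor) * divisor)
  if (newv < 0.9 * v) newv <- newv + divisor
  as.integer(newv)
}

.arch_efficientnet <- function(width_mult, depth_mult, input) {
  expand <- c(1, 6, 6, 6, 6, 6, 6)
  kernels <- c(3, 3, 5, 3, 5, 5, 3)
  strides <- c(1, 2, 2, 2, 1, 2, 1)
  filters <- c(16, 24, 40, 80, 112, 192, 320)
  repeats <- c(1, 2, 2, 3, 3, 4, 1)
  rf <- function(f) .round_filters(f, width_mult)
  rr <- function(r) as.integer(ceiling(depth_mult * r))
  stem <- rf(32)
  hw <- input / 2
  L <- list(.layer_conv(3, 3, stem, hw), .layer_norm(stem))
  cin <- stem
  mbconv <- function(cin, cout, k, stride, e, hw_in) {
    hw_out <- hw_in / stride
    mid <- cin * e
    ls <- list()
    if (e != 1) {
      ls <- c(ls, list(.layer_conv(1, cin, mid, hw_in), .layer_norm(mid)))
    }
    ls <- c(ls, list(.layer_conv(k, mid, mid, hw_out, groups = mid),
                     .layer_norm(mid)))
    sq <- max(1L, as.integer(cin * 0.25))
    ls <- c(ls, list(.layer_conv(1, mid, sq, 1, bias = TRUE),
                     .layer_conv(1, sq, mid, 1, bias = TRUE)))
    c(ls, list(.layer_conv(1, mid, cout, hw_out), .layer_norm(cout)))
  }
  for (s in 1:7) {
    cout <- rf(filters[s])
    for (r in seq_len(rr(repeats[s]))) {
      stride <- if (r == 1) strides[s] else 1
      L <- c(L, mbconv(cin, cout, kernels[s], stride, expand[s], hw))
      hw <- hw / stride
      cin <- cout
    }
  }
  headc <- rf(1280)
  c(L, list(.layer_conv(1, cin, headc, hw), .layer_norm(headc),
            .layer_linear(headc, 1000)))
}

.slim_encoder_layers <- function(input = 256L) {
  chans <- c(12L, 16L, 24L, 32L, 48L)
  hw <- input / 2
  L <- list(.layer_conv(3, 1, chans[1], hw), .layer_norm(chans[1]))
  for (i in 2:5) {
    hw <- hw / 2
    L <- c(L, list(.layer_conv(3, chans[i - 1], chans[i], hw),
                   .layer_norm(chans[i])))
  }
  L
}

#' Profile an encoder backbone
#'
#' Reports trainable parameters and forward-pass multiply-accumulate
#' operations of the standard ImageNet classification network (1000-class
#' head included) at the architecture's standard input resolution: 224x224
#' for `resnet50`, `convnext-tiny` and `efficientnet-b0`; 300x300 for
#' `efficientnet-b3`. FLOP figures reported as MAC counts; the FP32
#' checkpoint size is `4 bytes x params`. `slim-test` profiles the package's
#' tiny test encoder (no classification head) at 256x256.
#'
#' @param name backbone name (see [encoder_spec()]).
#' @return list with `params`, `macs`, `params_M`, `gmacs`, `fp32_mb`,
#'   `input_size`.
#' @export
profile_backbone <- function(name) {
  spec <- switch(name,
    "resnet50" = list(layers = .arch_resnet50(), input = 224L),
    "convnext-tiny" = list(layers = .arch_convnext_tiny(), input = 224L),
    "efficientnet-b0" = list(layers = .arch_efficientnet(1, 1, 224L),
                             input = 224L),
    "efficientnet-b3" = list(layers = .arch_efficientnet(1.2, 1.4, 300L),
                             input = 300L),
    "slim-test" = list(layers = .slim_encoder_layers(), input = 256L),
    stop(sprintf("unknown architecture '%s'", name), call. = FALSE)
  )
  tot <- .sum_layers(spec$layers)
  list(params = tot$params, macs = tot$macs,
       params_M = tot$params / 1e6, gmacs = tot$macs / 1e9,
       fp32_mb = tot$params * 4 / 1e6, input_size = spec$input)
}

#' Profile table for several backbones
#'
#' @param names character vector of backbone names.
#' @return data frame with one row per backbone.
#' @export
profile_table <- function(names = c("convnext-tiny", "resnet50",
                                    "efficientnet-b0", "efficientnet-b3")) {
  do.call(rbind, lapply(names, function(nm) {
    p <- profile_backbone(nm)
    data.frame(backbone = nm, params_M = p$params_M, gmacs = p$gmacs,
               fp32_mb = p$fp32_mb, input_size = p$input_size,
               stringsAsFactors = FALSE)
  }))
}
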