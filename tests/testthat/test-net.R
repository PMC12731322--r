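test_that("encoder specs validate names and stage geometry", {
  sp <- encoder_spec("efficientnet-b3")
  expect_equal(sp$stage_strides, c(4L, 8L, 16L, 32L))
  expect_equal(length(sp$stage_channels), 4)
  expect_true(all(diff(sp$stage_strides) > 0))
  expect_error(encoder_spec("vgg16"), "unknown encoder")
  expect_error(encoder_spec("resnet50", pretrained = TRUE), "pretrained")
})

test_that("encoders emit pyramids at strides 4/8/16/32 with declared channels", {
  enc <- build_encoder("slim-test")
  x <- array(rnorm(64 * 64 * 2), c(64, 64, 1, 2))
  f <- enc$forward(x)
  expect_equal(dim(f$e1), c(16, 16, 16, 2))
  expect_equal(dim(f$e2), c(8, 8, 24, 2))
  expect_equal(dim(f$e3), c(4, 4, 32, 2))
  expect_equal(dim(f$e4), c(2, 2, 48, 2))
  expect_lt(n_parameters(enc), 1e5)
  # deterministic in eval mode: identical images give identical pyramids
  x2 <- x; x2[, , , 2] <- x[, , , 1]
  f2 <- enc$forward(x2)
  expect_equal(f2$e4[, , , 1], f2$e4[, , , 2])
  # a named large backbone has the reference stage widths; e4 at 256 input
  # sits at stride 32 (8x8)
  b3 <- build_encoder("efficientnet-b3")
  fb <- b3$forward(array(rnorm(256 * 256), c(256, 256, 1, 1)))
  expect_equal(dim(fb$e4)[1:3], c(8, 8, 384))
})

test_that("CBAM gates attenuate, preserve shape and hit the zero-weight form", {
  set.seed(3)
  cb <- mod_cbam(32, reduction = 8, spatial_kernel = 7)
  x <- array(rnorm(16 * 16 * 32 * 2), c(16, 16, 32, 2))
  y <- cb$forward(x)
  expect_equal(dim(y), dim(x))
  expect_true(all(abs(y) <= abs(x) + 1e-12))  # two sigmoid gates in (0,1)
  # zero weights and biases everywhere: both gates 0.5, output x/4
  for (m in raxseg:::collect_modules(cb)) for (nm in names(m$par)) m$par[[nm]][] <- 0
  y0 <- cb$forward(x)
  expect_equal(y0, x * 0.25, tolerance = 1e-12)
  expect_error(mod_cbam(8, reduction = 16), "reduction")
  expect_error(mod_cbam(32, spatial_kernel = 4), "odd")
})

test_that("scSE is additive, bounded per branch, identity at zero weights", {
  set.seed(4)
  sc <- mod_scse(32, reduction = 8)
  x <- array(rnorm(8 * 8 * 32 * 2), c(8, 8, 32, 2))
  y <- sc$forward(x)
  expect_equal(dim(y), dim(x))
  # each branch is x times a sigmoid, so the sum is bounded by 2|x|
  expect_true(all(abs(y) <= 2 * abs(x) + 1e-12))
  for (m in raxseg:::collect_modules(sc)) for (nm in names(m$par)) m$par[[nm]][] <- 0
  expect_equal(sc$forward(x), x, tolerance = 1e-12)
  expect_error(mod_scse(4, reduction = 16), "reduction")
})

test_that("attention placement per mode is structurally correct", {
  has <- function(model, pat) {
    any(grepl(pat, names(raxseg:::collect_modules(model))))
  }
  m_none <- build_model(slim_model_config("none"))
  m_cbam <- build_model(slim_model_config("cbam"))
  m_scse <- build_model(slim_model_config("scse"))
  m_both <- build_model(slim_model_config("cbam_scse"))
  expect_false(has(m_none, "cbam|scse"))
  expect_true(has(m_cbam, "cbam"))
  expect_false(has(m_cbam, "scse"))   # CBAM-only has no squeeze-excitation
  expect_true(has(m_scse, "scse_skip") && has(m_scse, "scse_out"))
  expect_false(has(m_scse, "cbam"))
  expect_true(has(m_both, "cbam") && has(m_both, "scse_skip"))
})

test_that("forward pass honours shape, range and determinism contracts", {
  model <- build_model(slim_model_config("cbam_scse", seed = 5))
  x <- array(rnorm(64 * 64 * 2), c(64, 64, 1, 2))
  out <- model$forward(x)
  expect_equal(dim(out$logits), c(64, 64, 1, 2))
  expect_true(all(out$probabilities > 0 & out$probabilities < 1))
  out2 <- model$forward(x)
  expect_identical(out$logits, out2$logits)
  expect_error(model$forward(array(0, c(60, 60, 1, 1))), "divisible by 32")
  # attention-gated and ungated models differ on the same weights seed
  m0 <- build_model(slim_model_config("none", seed = 5))
  o0 <- m0$forward(x)
  expect_gt(max(abs(o0$logits - out$logits)), 0)
  # parameter count is invariant to input resolution
  p1 <- n_parameters(model)
  invisible(model$forward(array(0, c(32, 32, 1, 1))))
  expect_identical(n_parameters(model), p1)
})

test_that("deep supervision produces auxiliary probability maps", {
  cfg <- slim_model_config("none")
  cfg$deep_supervision <- TRUE
  model <- build_model(cfg)
  out <- model$forward(array(rnorm(64 * 64), c(64, 64, 1, 1)))
  expect_length(out$aux, 2)
  expect_equal(dim(out$aux[[1]])[1], 4)    # stride 16 after up block 1
  expect_equal(dim(out$aux[[2]])[1], 8)    # stride 8 after up block 2
  expect_true(all(out$aux[[1]] > 0 & out$aux[[1]] < 1))
})

test_that("model gradients match finite differences through every gate", {
  cfg <- slim_model_config("cbam_scse", seed = 3)
  cfg$decoder_dropout <- 0
  model <- build_model(cfg)
  set.seed(7)
  x <- array(rnorm(32 * 32 * 2), c(32, 32, 1, 2))
  ys <- lapply(1:2, function(i) matrix(rbinom(32 * 32, 1, 0.4), 32))
  loss_fn <- function() {
    out <- model$forward(x, training = TRUE)
    mean(vapply(1:2, function(n) {
      as.numeric(combo_loss(as.vector(out$logits[, , 1, n]),
                            as.vector(ys[[n]])))
    }, numeric(1)))
  }
  out <- model$forward(x, training = TRUE)
  g <- array(0, dim(out$logits))
  for (n in 1:2) {
    g[, , 1, n] <- matrix(raxseg:::.combo_loss_grad(
      as.vector(out$logits[, , 1, n]), as.vector(ys[[n]])), 32) / 2
  }
  mods <- raxseg:::collect_modules(model)
  raxseg:::zero_grads(mods)
  model$backward(g)
  set.seed(8)
  for (nm in sample(names(mods), 6)) {
    m <- mods[[nm]]
    pn <- sample(names(m$par), 1)
    i <- sample(length(m$par[[pn]]), 1)
    eps <- 1e-5
    orig <- m$par[[pn]][i]
    m$par[[pn]][i] <- orig + eps; lp <- loss_fn()
    m$par[[pn]][i] <- orig - eps; lm <- loss_fn()
    m$par[[pn]][i] <- orig
    num <- (lp - lm) / (2 * eps)
    ana <- m$grad[[pn]][i]
    expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-3)
  }
})

test_that("one optimization step on a phantom decreases the combo loss", {
  s <- generate_phantom(phantom_config(image_size = 64, seed = 2))
  cfg <- slim_model_config("cbam_scse", seed = 2)
  model <- build_model(cfg)
  x <- raxseg:::.stack_batch(list(normalize_image(s$image, "zscore")))
  y <- as.vector(s$mask)
  mods <- raxseg:::collect_modules(model)
  opt <- raxseg:::adamw_state(mods)
  losses <- numeric(3)
  for (t in 1:3) {
    out <- model$forward(x, training = TRUE)
    z <- as.vector(out$logits[, , 1, 1])
    losses[t] <- as.numeric(combo_loss(z, y))
    g <- array(raxseg:::.combo_loss_grad(z, y), dim(out$logits))
    raxseg:::zero_grads(mods)
    model$backward(g)
    opt <- raxseg:::adamw_step(mods, opt, 1e-3, 1e-4, t = t)
  }
  out <- model$forward(x, training = TRUE)
  final <- as.numeric(combo_loss(as.vector(out$logits[, , 1, 1]), y))
  expect_lt(final, losses[1])
})

test_that("profiling matches the built slim encoder parameter count", {
  enc <- build_encoder("slim-test")
  expect_identical(profile_backbone("slim-test")$params, n_parameters(enc))
  expect_error(profile_backbone("alexnet"), "unknown")
  # FP32 size convention: 4 bytes per parameter
  p <- profile_backbone("resnet50")
  expect_equal(p$fp32_mb, p$params * 4 / 1e6)
  tab <- profile_table()
  expect_equal(nrow(tab), 4)
  expect_true(all(is.finite(tab$gmacs)))
})
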