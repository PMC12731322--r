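test_that("CLAHE keeps range, preserves constants and boosts local contrast", {
  const <- matrix(0.4, 64, 64)
  expect_identical(clahe_enhance(const), const)
  s <- test_phantoms(4, size = 256)[[1]]
  enh <- clahe_enhance(s$image)
  expect_true(all(enh >= 0 & enh <= 1))
  # per-tile interquartile range increases on at least half the tiles
  tiles <- 8
  side <- 256 / tiles
  iqr_gain <- 0L; n_tiles <- 0L
  for (i in seq_len(tiles)) for (j in seq_len(tiles)) {
    rs <- ((i - 1) * side + 1):(i * side)
    cs <- ((j - 1) * side + 1):(j * side)
    n_tiles <- n_tiles + 1L
    if (IQR(enh[rs, cs]) >= IQR(s$image[rs, cs])) iqr_gain <- iqr_gain + 1L
  }
  expect_gte(iqr_gain, n_tiles / 2)
  # a low-contrast tile does not lose intensity spread
  two <- matrix(0.5, 32, 64)
  two[, 1:32] <- 0.5 + 0.01 * matrix(rnorm(32 * 32), 32)
  two[, 33:64] <- matrix(runif(32 * 32), 32)
  enh2 <- clahe_enhance(clamp_img(two), clip = 2, tiles = 2)
  expect_gte(sd(enh2[, 1:32]), sd(two[, 1:32]) * 0.99)
  expect_error(clahe_enhance(matrix(0.1, 4, 4), tiles = 8), "tile grid")
})

test_that("otsu threshold maximizes between-class variance", {
  expect_error(otsu_threshold(matrix(1, 4, 4)), "no threshold")
  # two well-separated values
  v <- matrix(rep(c(0.2, 0.8), each = 50), 10, 10)
  t1 <- otsu_threshold(v)
  expect_gt(t1, 0.2); expect_lt(t1, 0.8)
  # two-Gaussian mixture lands between the modes
  set.seed(2)
  img <- matrix(c(rnorm(500, 0.25, 0.05), rnorm(500, 0.75, 0.05)), 50, 20)
  t2 <- otsu_threshold(img)
  expect_gte(t2, 0.4); expect_lte(t2, 0.6)
  # the returned threshold attains the brute-force variance maximum over all
  # 256 bin edges (direct set-splitting on bin-quantized pixels)
  for (sd_ in 1:5) {
    set.seed(sd_)
    x <- matrix(runif(400)^2, 20, 20)
    t <- otsu_threshold(x)
    breaks <- seq(0, 1, length.out = 257)
    mids <- (breaks[-1] + breaks[-257]) / 2
    vq <- mids[pmin(pmax(findInterval(as.vector(x), breaks,
                                      rightmost.closed = TRUE), 1), 256)]
    best <- max(vapply(breaks[2:256], function(e) bcv_direct(vq, e),
                       numeric(1)))
    expect_lt(abs(bcv_direct(vq, t) - best), 1e-12)
  }
})

test_that("pseudo-mask pipeline honours threshold relaxation and morphology", {
  s <- test_phantoms(11, size = 128)[[1]]
  enh <- clahe_enhance(s$image)
  t <- otsu_threshold(enh)
  m_strict <- enh >= t
  m_relax <- enh >= 0.95 * t
  expect_true(all(m_relax[m_strict]))   # relaxed mask is a superset
  cfg <- pseudomask_config()
  pm <- make_pseudo_mask(s$image, cfg)
  pm2 <- make_pseudo_mask(s$image, cfg)
  expect_identical(pm, pm2)             # deterministic
  # opening shrinks, closing then grows back
  raw <- (enh >= attr(pm, "threshold")) * 1L
  opened <- (EBImage::opening(raw, EBImage::makeBrush(5, "disc")) > 0) * 1L
  closed <- (EBImage::closing(opened, EBImage::makeBrush(5, "disc")) > 0) * 1L
  expect_lte(sum(opened), sum(raw))
  expect_gte(sum(closed), sum(opened))
})

test_that("largest-component selection keeps exactly the biggest blob", {
  img <- matrix(0.1, 64, 64)
  img[10:21, 10:19] <- 0.9          # 120 px blob
  img[40:47, 40:44] <- 0.9          # 40 px blob
  pm <- make_pseudo_mask(img, pseudomask_config(open_radius = 0,
                                                close_radius = 0))
  lab <- EBImage::bwlabel(pm)
  expect_equal(max(lab), 1)
  expect_true(all(pm[12:19, 12:17] == 1))
  expect_true(all(pm[40:47, 40:44] == 0))
})

test_that("noise-free phantoms yield faithful pseudo-masks", {
  for (sd_ in c(2, 8, 21)) {
    s <- generate_phantom(phantom_config(seed = sd_, noise_sigma = 0,
                                         bias_strength = 0))
    pm <- make_pseudo_mask(s$image)
    expect_gte(overlap_metrics(pm, s$mask)$dice, 0.90)
  }
})

test_that("constant images give an empty mask with a warning, not an error", {
  expect_warning(pm <- make_pseudo_mask(matrix(0.3, 32, 32)), "empty")
  expect_equal(sum(pm), 0)
})

test_that("pseudo-vs-reference agreement report covers the metric suite", {
  masks <- lapply(test_phantoms(c(3, 6), size = 64), `[[`, "mask")
  perfect <- evaluate_pseudo(masks, masks)
  expect_true(all(perfect$per_image$dice == 1))
  expect_true(all(perfect$per_image$boundary_f1 == 1))
  expect_true(all(perfect$per_image$hd95 == 0))
  # a 2-px shifted square has HD95 exactly 2
  sq <- matrix(0L, 32, 32); sq[8:20, 8:20] <- 1L
  sh <- matrix(0L, 32, 32); sh[10:22, 8:20] <- 1L
  rep2 <- evaluate_pseudo(list(sq), list(sh))
  expect_equal(rep2$per_image$hd95, 2)
  # empty pseudo-mask: overlap 0, distances reported missing and counted
  rep3 <- evaluate_pseudo(list(matrix(0L, 16, 16)), list(disk_mask(16, 8, 8, 4)))
  expect_equal(rep3$per_image$dice, 0)
  expect_true(is.na(rep3$per_image$hd95))
  expect_equal(rep3$summary$n_missing[rep3$summary$metric == "hd95"], 1)
  expect_error(evaluate_pseudo(masks, masks[1]), "paired")
})
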