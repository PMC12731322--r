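test_that("confusion counts and overlap metrics match hand arithmetic", {
  p <- matrix(c(1, 1, 0, 0), 2); y <- matrix(c(1, 0, 1, 0), 2)
  cc <- confusion_counts(p, y)
  expect_equal(unlist(cc), c(tp = 1, fp = 1, fn = 1, tn = 1))
  ov <- overlap_metrics(p, y)
  expect_equal(ov$dice, 0.5)
  expect_equal(ov$iou, 1 / 3)
  expect_equal(ov$accuracy, 0.5)
  ones <- matrix(1, 4, 4)
  expect_equal(confusion_counts(ones, ones)$tp, 16)
  ovp <- overlap_metrics(ones, ones)
  expect_equal(ovp$dice, 1); expect_equal(ovp$iou, 1)
  # empty-empty convention
  z <- matrix(0, 3, 3)
  ovz <- overlap_metrics(z, z)
  expect_equal(ovz$dice, 1); expect_equal(ovz$precision, 1)
  expect_error(confusion_counts(matrix(0, 2, 2), matrix(0, 3, 3)), "shapes")
  expect_error(confusion_counts(matrix(0.5, 2, 2), matrix(0, 2, 2)), "binary")
})

test_that("Dice and IoU satisfy their algebraic identity on random pairs", {
  set.seed(8)
  for (i in 1:25) {
    p <- random_mask(12); y <- random_mask(12)
    ov <- overlap_metrics(p, y)
    expect_equal(ov$dice, 2 * ov$iou / (1 + ov$iou), tolerance = 1e-12)
    cc <- confusion_counts(p, y)
    if (cc$tn > 0) expect_gte(ov$accuracy, ov$iou)
  }
})

test_that("leakage rate is one minus precision and monotone in FP", {
  p <- matrix(0L, 4, 4); p[1, 1:4] <- 1L
  y <- matrix(0L, 4, 4); y[1, 1:3] <- 1L
  expect_equal(leakage_rate(p, y), 0.25)   # TP=3, FP=1
  expect_equal(leakage_rate(y, y), 0)
  expect_equal(leakage_rate(1L - y, y), 1)
  expect_equal(leakage_rate(matrix(0L, 4, 4), y), 0)  # convention
  # adding false positives strictly increases leakage, decreases precision
  p2 <- p; p2[2, 1] <- 1L
  expect_gt(leakage_rate(p2, y), leakage_rate(p, y))
  expect_lt(overlap_metrics(p2, y)$precision, overlap_metrics(p, y)$precision)
})

test_that("boundary F1 matches the brute-force point-distance oracle", {
  sq <- matrix(0L, 16, 16); sq[4:13, 4:13] <- 1L
  sh <- matrix(0L, 16, 16); sh[5:14, 4:13] <- 1L   # 1 px shift
  expect_equal(boundary_metrics(sq, sq)$boundary_f1, 1)
  expect_equal(boundary_metrics(sq, sh, tolerance = 2)$boundary_f1, 1)
  expect_lt(boundary_metrics(sq, sh, tolerance = 0)$boundary_f1, 1)
  set.seed(13)
  for (i in 1:40) {
    p <- random_mask(sample(8:32, 1)); y <- random_mask(nrow(p))
    tol <- sample(0:3, 1)
    expect_equal(boundary_metrics(p, y, tol)$boundary_f1,
                 brute_boundary_f1(p, y, tol), tolerance = 1e-9)
  }
})

test_that("surface distances match the exhaustive pairwise oracle", {
  sq <- matrix(0L, 20, 20); sq[5:12, 5:12] <- 1L
  sh <- matrix(0L, 20, 20); sh[8:15, 5:12] <- 1L   # 3 px shift
  sm <- surface_distance_metrics(sq, sh)
  expect_equal(sm$directed_hausdorff, 3)
  expect_equal(surface_distance_metrics(sq, sq)$assd, 0)
  expect_equal(surface_distance_metrics(sq, sq)$hd95, 0)
  z <- matrix(0L, 8, 8)
  expect_equal(surface_distance_metrics(z, z)$assd, 0)     # both empty
  expect_true(is.na(surface_distance_metrics(z, sq[1:8, 1:8])$assd))
  set.seed(14)
  for (i in 1:100) {
    n <- sample(8:32, 1)
    p <- random_mask(n); y <- random_mask(n)
    got <- surface_distance_metrics(p, y)
    want <- brute_surface(p, y)
    if (is.na(want$assd)) {
      expect_true(is.na(got$assd))
    } else {
      expect_equal(got$assd, want$assd, tolerance = 1e-9)
      expect_equal(got$hd95, want$hd95, tolerance = 1e-9)
      expect_equal(got$directed_hausdorff, want$dmax, tolerance = 1e-9)
    }
  }
})

test_that("generalized Dice reduces, combines and demands weights", {
  p <- random_mask(10); y <- random_mask(10)
  gd1 <- generalized_dice(list(list(prediction = p, reference = y)))
  expect_equal(gd1, overlap_metrics(p, y)$dice, tolerance = 1e-12)
  two_perfect <- list(list(prediction = p, reference = p),
                      list(prediction = y, reference = y))
  expect_equal(generalized_dice(two_perfect), 1)
  # hand-set weights against manual arithmetic
  p1 <- matrix(c(1, 1, 0, 0), 2); y1 <- matrix(c(1, 0, 1, 0), 2)
  p2 <- matrix(c(1, 0, 0, 0), 2); y2 <- matrix(c(1, 1, 0, 0), 2)
  gd <- generalized_dice(list(list(prediction = p1, reference = y1),
                              list(prediction = p2, reference = y2)),
                         class_weights = c(1, 3))
  expect_equal(gd, (1 * 2 * 1 + 3 * 2 * 1) / (1 * 4 + 3 * 3), tolerance = 1e-12)
  empty <- matrix(0L, 2, 2)
  expect_error(generalized_dice(list(list(prediction = p1, reference = empty))),
               "explicit")
})

test_that("ROC-AUC equals Mann-Whitney enumeration, PR-AUC is sane", {
  rc <- ranking_curves(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))
  expect_equal(rc$roc_auc, 0.75)
  expect_equal(ranking_curves(c(0.9, 0.8, 0.2), c(1, 1, 0))$roc_auc, 1)
  expect_equal(ranking_curves(rep(0.5, 10), rep(c(0, 1), 5))$roc_auc, 0.5)
  expect_warning(ranking_curves(runif(5), rep(1, 5)), "single-class")
  set.seed(15)
  for (i in 1:50) {
    n <- sample(4:8, 1)
    s <- round(runif(n), 1)   # coarse scores force ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(ranking_curves(s, y)$roc_auc, auc_enum(s, y),
                 tolerance = 1e-12)
  }
  # perfect ranking has PR-AUC 1
  expect_equal(ranking_curves(c(0.9, 0.8, 0.1), c(1, 1, 0))$pr_auc, 1)
})

test_that("ROC-AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(16)
  s <- runif(200); y <- rbinom(200, 1, 0.3 + 0.4 * s)
  ours <- ranking_curves(s, y)$roc_auc
  theirs <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("bootstrap summary is seeded and covers the mean at nominal rate", {
  bs <- bootstrap_summary(rep(0.8, 30))
  expect_equal(c(bs$ci_lower, bs$ci_upper), c(0.8, 0.8))
  expect_equal(bs$sd, 0)
  v <- rnorm(40)
  b1 <- bootstrap_summary(v, B = 200, seed = 9)
  b2 <- bootstrap_summary(v, B = 200, seed = 9)
  expect_identical(b1, b2)
  expect_lte(b1$ci_lower, b1$mean); expect_gte(b1$ci_upper, b1$mean)
  # coverage simulation: ~95% of intervals catch the true mean
  set.seed(21)
  hits <- 0L
  for (r in 1:500) {
    x <- rnorm(50, mean = 1)
    ci <- bootstrap_summary(x, B = 400, seed = r)
    if (ci$ci_lower <= 1 && 1 <= ci$ci_upper) hits <- hits + 1L
  }
  expect_gte(hits / 500, 0.92)
  expect_lte(hits / 500, 0.98)
  expect_error(bootstrap_summary(NA_real_), "no finite")
})

test_that("paired Wilcoxon matches sign-assignment enumeration", {
  a <- c(1, 2, 3, 4, 5, 6)
  res <- paired_wilcoxon(a + a, a)   # all positive differences, n = 6 exact
  expect_equal(res$p_value, 2 / 64)
  expect_warning(res0 <- paired_wilcoxon(a, a), "zero")
  expect_equal(res0$p_value, 1)
  set.seed(17)
  x <- rnorm(12); yv <- x + rnorm(12, 0.3)
  expect_equal(paired_wilcoxon(x, yv)$p_value,
               paired_wilcoxon(yv, x)$p_value)   # symmetry
  expect_error(paired_wilcoxon(1:3, 4:6), "at least 5")
})

test_that("metric_report summarizes per-image values with bootstrap CIs", {
  masks <- lapply(test_phantoms(c(5, 9, 13), size = 64), `[[`, "mask")
  preds <- lapply(masks, function(m) {
    m2 <- m; m2[1:4, ] <- 0L; m2
  })
  rep_ <- metric_report(preds, masks, B = 200, seed = 2)
  expect_equal(nrow(rep_$per_image), 3)
  expect_true(all(c("dice", "hd95", "leakage") %in% rep_$summary$metric))
  srow <- rep_$summary[rep_$summary$metric == "dice", ]
  expect_lte(srow$ci_lower, srow$mean)
  expect_gte(srow$ci_upper, srow$mean)
})
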