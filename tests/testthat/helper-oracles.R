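# Independent brute-force oracles and shared fixtures for the test suite.

# Exhaustive prefix-Jaccard oracle for the Lovasz hinge: flips the top-i
# sorted-error pixels one at a time and accumulates Jaccard drops.
lovasz_oracle <- function(z, y) {
  e <- 1 - z * (2 * y - 1)
  ord <- order(e, decreasing = TRUE)
  jac <- function(mis) {
    pred <- y
    pred[mis] <- 1 - pred[mis]
    u <- sum(pred | y)
    if (u == 0) 1 else sum(pred & y) / u
  }
  loss <- 0
  j_prev <- 1
  for (i in seq_along(z)) {
    j_i <- jac(ord[seq_len(i)])
    loss <- loss + max(0, e[ord[i]]) * (j_prev - j_i)
    j_prev <- j_i
  }
  loss
}

# All-pairs Euclidean distances between the boundary pixels of two masks.
brute_surface <- function(p, y) {
  bp <- which(mask_boundary(p) > 0, arr.ind = TRUE)
  br <- which(mask_boundary(y) > 0, arr.ind = TRUE)
  if (nrow(bp) == 0 && nrow(br) == 0) {
    return(list(assd = 0, hd95 = 0, dmax = 0, d_pr = numeric(0),
                d_rp = numeric(0)))
  }
  if (nrow(bp) == 0 || nrow(br) == 0) {
    return(list(assd = NA_real_, hd95 = NA_real_, dmax = NA_real_))
  }
  dmat <- sqrt(outer(bp[, 1], br[, 1], "-")^2 + outer(bp[, 2], br[, 2], "-")^2)
  d_pr <- apply(dmat, 1, min)
  d_rp <- apply(dmat, 2, min)
  pooled <- c(d_pr, d_rp)
  list(assd = mean(pooled), hd95 = quantile(pooled, 0.95, names = FALSE),
       dmax = max(pooled), d_pr = d_pr, d_rp = d_rp)
}

brute_boundary_f1 <- function(p, y, tol) {
  bs <- brute_surface(p, y)
  if (length(bs$d_pr) == 0 && length(bs$d_rp) == 0) return(1)
  prec <- if (length(bs$d_pr) == 0) 0 else mean(bs$d_pr <= tol)
  rec <- if (length(bs$d_rp) == 0) 0 else mean(bs$d_rp <= tol)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

# Mann-Whitney enumeration of ROC-AUC (ties count one half).
auc_enum <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Exhaustive between-class variance for one candidate threshold.
bcv_direct <- function(v, t) {
  lo <- v[v < t]
  hi <- v[v >= t]
  if (length(lo) == 0 || length(hi) == 0) return(-Inf)
  w0 <- length(lo) / length(v)
  w0 * (1 - w0) * (mean(lo) - mean(hi))^2
}

clamp_img <- function(x) pmin(pmax(x, 0), 1)

random_mask <- function(n, p = 0.4) {
  m <- matrix(rbinom(n * n, 1, p), n, n)
  # close tiny specks a bit so boundaries are non-degenerate
  m
}

disk_mask <- function(n, cx, cy, r) {
  g <- expand.grid(r = seq_len(n), c = seq_len(n))
  m <- matrix(0L, n, n)
  m[(g$r - cx)^2 + (g$c - cy)^2 <= r^2] <- 1L
  m
}

# Cached small phantom sets shared across test files.
.fixture_env <- new.env()

test_phantoms <- function(seeds, size = 64, ...) {
  key <- paste0("ph_", size, "_", paste(seeds, collapse = "_"),
                paste(c(...), collapse = "_"))
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- lapply(seeds, function(i) {
      generate_phantom(phantom_config(image_size = size, seed = i, ...))
    })
  }
  .fixture_env[[key]]
}
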