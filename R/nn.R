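# Minimal CPU neural-network kernels for the segmentation model.
#
# Feature maps are 4-D arrays dim = (H, W, C, N), column-major. Convolution
# uses cached im2col index maps plus BLAS matrix products; every module is an
# environment with `par`/`grad` lists and `forward`/`backward` closures, so
# the optimizer can update parameters in place.

.nn_cache <- new.env(parent = emptyenv())

.conv_geom <- function(H, W, k, s) {
  p <- (k - 1L) %/% 2L
  list(p = p,
       Ho = (H + 2L * p - k) %/% s + 1L,
       Wo = (W + 2L * p - k) %/% s + 1L)
}

.conv_index <- function(H, W, C, k, s) {
  g <- .conv_geom(H, W, k, s)
  key <- paste("ci", H, W, C, k, s, sep = "_")
  hit <- .nn_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L * g$p; Wp <- W + 2L * g$p
  or <- rep(seq_len(g$Ho), times = g$Wo)
  oc <- rep(seq_len(g$Wo), each = g$Ho)
  shift <- (or - 1L) * s + ((oc - 1L) * s) * Hp
  j <- seq_len(k * k * C) - 1L
  u <- (j %% k) + 1L
  v <- (j %/% k) %% k + 1L
  cch <- j %/% (k * k)
  base_k <- u + (v - 1L) * Hp + cch * (Hp * Wp)
  idx <- outer(shift, base_k, "+")
  storage.mode(idx) <- "integer"
  grp <- as.vector(idx)
  ug <- sort(unique(grp))
  out <- list(idx = idx, grp = grp, ug = ug, Hp = Hp, Wp = Wp,
              Ho = g$Ho, Wo = g$Wo, p = g$p)
  .nn_cache[[key]] <- out
  out
}

.pad_hw <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4]))
  out[(p + 1):(p + d[1]), (p + 1):(p + d[2]), , ] <- x
  out
}

new_module <- function(type, par = list(), state = list(), children = list()) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$par <- par
  e$grad <- lapply(par, function(p) array(0, dim(p) %||% length(p)))
  e$state <- state
  e$children <- children
  class(e) <- "nn_module"
  e
}

# He-normal conv kernel; weight layout (k, k, Cin, Cout) flattened to a
# (k*k*Cin) x Cout matrix matching the im2col column order.
mod_conv2d <- function(in_ch, out_ch, k = 3L, stride = 1L, bias = TRUE) {
  sdv <- sqrt(2 / (k * k * in_ch))
  par <- list(W = matrix(rnorm(k * k * in_ch * out_ch, 0, sdv),
                         k * k * in_ch, out_ch))
  if (bias) par$b <- numeric(out_ch)
  m <- new_module("conv2d", par)
  m$k <- as.integer(k); m$stride <- as.integer(stride)
  m$in_ch <- as.integer(in_ch); m$out_ch <- as.integer(out_ch)
  m$forward <- function(x, training = FALSE) {
    d <- dim(x)
    ci <- .conv_index(d[1], d[2], d[3], m$k, m$stride)
    xp <- .pad_hw(x, ci$p)
    N <- d[4]
    plane <- ci$Hp * ci$Wp * d[3]
    dim(xp) <- c(plane, N)
    nrows <- ci$Ho * ci$Wo
    Xcol <- matrix(0, nrows * N, nrow(m$par$W))
    for (n in seq_len(N)) {
      v <- xp[, n]
      Xcol[((n - 1) * nrows + 1):(n * nrows), ] <- v[ci$idx]
    }
    y <- Xcol %*% m$par$W
    if (!is.null(m$par$b)) y <- sweep(y, 2, m$par$b, "+")
    m$cache <- list(Xcol = Xcol, ci = ci, d = d, plane = plane)
    out <- array(0, c(ci$Ho, ci$Wo, m$out_ch, N))
    for (n in seq_len(N)) {
      out[, , , n] <- y[((n - 1) * nrows + 1):(n * nrows), ]
    }
    out
  }
  m$backward <- function(gy) {
    cc <- m$cache
    ci <- cc$ci; d <- cc$d; N <- d[4]
    nrows <- ci$Ho * ci$Wo
    gmat <- matrix(0, nrows * N, m$out_ch)
    for (n in seq_len(N)) {
      gmat[((n - 1) * nrows + 1):(n * nrows), ] <- gy[, , , n]
    }
    m$grad$W <- m$grad$W + crossprod(cc$Xcol, gmat)
    if (!is.null(m$par$b)) m$grad$b <- m$grad$b + colSums(gmat)
    dXcol <- tcrossprod(gmat, m$par$W)
    flat <- matrix(0, nrows * ncol(dXcol), N)
    for (n in seq_len(N)) {
      flat[, n] <- dXcol[((n - 1) * nrows + 1):(n * nrows), ]
    }
    acc <- rowsum(flat, ci$grp, reorder = TRUE)
    dxp <- matrix(0, cc$plane, N)
    dxp[ci$ug, ] <- acc
    dim(dxp) <- c(ci$Hp, ci$Wp, d[3], N)
    p <- ci$p
    if (p > 0) dxp <- dxp[(p + 1):(p + d[1]), (p + 1):(p + d[2]), , , drop = FALSE]
    dxp
  }
  m
}

mod_batchnorm <- function(C, momentum = 0.1, eps = 1e-5) {
  m <- new_module("batchnorm",
                  par = list(gamma = rep(1, C), beta = rep(0, C)),
                  state = list(mean = rep(0, C), var = rep(1, C)))
  m$momentum <- momentum; m$eps <- eps; m$C <- C
  m$forward <- function(x, training = FALSE) {
    d <- dim(x)
    xm <- aperm(x, c(1, 2, 4, 3))
    dim(xm) <- c(d[1] * d[2] * d[4], d[3])
    if (training) {
      mu <- colMeans(xm)
      xc <- sweep(xm, 2, mu)
      va <- colMeans(xc * xc)
      m$state$mean <- (1 - m$momentum) * m$state$mean + m$momentum * mu
      m$state$var <- (1 - m$momentum) * m$state$var + m$momentum * va
    } else {
      mu <- m$state$mean; va <- m$state$var
      xc <- sweep(xm, 2, mu)
    }
    istd <- 1 / sqrt(va + m$eps)
    xhat <- sweep(xc, 2, istd, "*")
    ym <- sweep(sweep(xhat, 2, m$par$gamma, "*"), 2, m$par$beta, "+")
    m$cache <- list(xhat = xhat, istd = istd, d = d, training = training)
    y <- array(ym, c(d[1], d[2], d[4], d[3]))
    aperm(y, c(1, 2, 4, 3))
  }
  m$backward <- function(gy) {
    cc <- m$cache; d <- cc$d
    gm <- aperm(gy, c(1, 2, 4, 3))
    dim(gm) <- c(d[1] * d[2] * d[4], d[3])
    m$grad$gamma <- m$grad$gamma + colSums(gm * cc$xhat)
    m$grad$beta <- m$grad$beta + colSums(gm)
    gxh <- sweep(gm, 2, m$par$gamma, "*")
    if (cc$training) {
      nB <- nrow(gm)
      t1 <- sweep(gxh, 2, colMeans(gxh))
      t2 <- sweep(cc$xhat, 2, colMeans(gxh * cc$xhat), "*")
      gx <- sweep(t1 - t2, 2, cc$istd, "*")
    } else {
      gx <- sweep(gxh, 2, cc$istd, "*")
    }
    gx <- array(gx, c(d[1], d[2], d[4], d[3]))
    aperm(gx, c(1, 2, 4, 3))
  }
  m
}

mod_silu <- function() {
  m <- new_module("silu")
  m$forward <- function(x, training = FALSE) {
    s <- 1 / (1 + exp(-x))
    m$cache <- list(x = x, s = s)
    x * s
  }
  m$backward <- function(gy) {
    cc <- m$cache
    gy * cc$s * (1 + cc$x * (1 - cc$s))
  }
  m
}

mod_dropout <- function(p = 0.1) {
  m <- new_module("dropout")
  m$p <- p
  m$forward <- function(x, training = FALSE) {
    if (!training || m$p <= 0) { m$cache <- NULL; return(x) }
    keep <- array(rbinom(length(x), 1, 1 - m$p), dim(x)) / (1 - m$p)
    m$cache <- keep
    x * keep
  }
  m$backward <- function(gy) {
    if (is.null(m$cache)) gy else gy * m$cache
  }
  m
}

# Bilinear up/down-sampling by separable interpolation matrices.
mod_upsample <- function(factor = 2L) {
  m <- new_module("upsample")
  m$factor <- factor
  apply_sep <- function(x, A, B) {
    d <- dim(x)
    dim(x) <- c(d[1], d[2] * d[3] * d[4])
    y <- A %*% x
    y <- array(y, c(nrow(A), d[2], d[3], d[4]))
    y <- aperm(y, c(2, 1, 3, 4))
    d2 <- dim(y)
    dim(y) <- c(d2[1], d2[2] * d2[3] * d2[4])
    y <- B %*% y
    y <- array(y, c(nrow(B), d2[2], d2[3], d2[4]))
    aperm(y, c(2, 1, 3, 4))
  }
  m$forward <- function(x, training = FALSE) {
    d <- dim(x)
    key <- paste("up", d[1], d[2], m$factor, sep = "_")
    AB <- .nn_cache[[key]]
    if (is.null(AB)) {
      AB <- list(A = .interp_matrix(d[1] * m$factor, d[1]),
                 B = .interp_matrix(d[2] * m$factor, d[2]))
      .nn_cache[[key]] <- AB
    }
    m$cache <- AB
    apply_sep(x, AB$A, AB$B)
  }
  m$backward <- function(gy) {
    AB <- m$cache
    apply_sep(gy, t(AB$A), t(AB$B))
  }
  m
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

split_channels <- function(g, c1) {
  d <- dim(g)
  list(g[, , seq_len(c1), , drop = FALSE],
       g[, , (c1 + 1):d[3], , drop = FALSE])
}

# Two-layer shared MLP on (C, N) descriptor matrices (CBAM channel gate and
# the channel squeeze-excitation branch).
mod_mlp2 <- function(C, hidden) {
  par <- list(W1 = matrix(rnorm(hidden * C, 0, sqrt(2 / C)), hidden, C),
              b1 = numeric(hidden),
              W2 = matrix(rnorm(C * hidden, 0, sqrt(2 / hidden)), C, hidden),
              b2 = numeric(C))
  m <- new_module("mlp2", par)
  m$forward <- function(x, training = FALSE) {
    h <- m$par$W1 %*% x + m$par$b1
    hr <- pmax(h, 0)
    y <- m$par$W2 %*% hr + m$par$b2
    m$cache <- list(x = x, h = h, hr = hr)
    y
  }
  m$backward <- function(gy) {
    cc <- m$cache
    m$grad$W2 <- m$grad$W2 + tcrossprod(gy, cc$hr)
    m$grad$b2 <- m$grad$b2 + rowSums(gy)
    gh <- crossprod(m$par$W2, gy) * (cc$h > 0)
    m$grad$W1 <- m$grad$W1 + tcrossprod(gh, cc$x)
    m$grad$b1 <- m$grad$b1 + rowSums(gh)
    crossprod(m$par$W1, gh)
  }
  m
}

.gap <- function(x) {  # (H,W,C,N) -> (C,N)
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3] * d[4])
  matrix(colMeans(x), d[3], d[4])
}

.gmp <- function(x) {  # global max pool with argmax indices
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3] * d[4])
  wmx <- max.col(t(x), ties.method = "first")
  vals <- x[cbind(wmx, seq_len(d[3] * d[4]))]
  list(vals = matrix(vals, d[3], d[4]), which = wmx, d = d)
}

#' Convolutional block attention (CBAM)
#'
#' Sequential channel-then-spatial gating: the channel gate is
#' `sigmoid(MLP(avgpool) + MLP(maxpool))` with a shared two-layer MLP;
#' the spatial gate convolves the channel-wise average and maximum maps with
#' a `spatial_kernel` x `spatial_kernel` kernel and applies a sigmoid mask.
#'
#' @param C feature channels.
#' @param reduction channel reduction of the shared MLP (must not exceed C).
#' @param spatial_kernel odd kernel size of the spatial gate.
#' @return an internal network module; apply via `module$forward(x)` where
#'   `x` is a `(H, W, C, N)` array.
#' @export
mod_cbam <- function(C, reduction = 16L, spatial_kernel = 7L) {
  if (C < reduction) stop("channels < reduction in CBAM", call. = FALSE)
  if (spatial_kernel %% 2L == 0L) stop("spatial kernel must be odd", call. = FALSE)
  hidden <- max(1L, C %/% reduction)
  mlp <- mod_mlp2(C, hidden)
  conv <- mod_conv2d(2L, 1L, k = spatial_kernel, stride = 1L, bias = TRUE)
  m <- new_module("cbam", children = list(mlp = mlp, conv = conv))
  m$C <- C
  m$forward <- function(x, training = FALSE) {
    d <- dim(x)
    avg <- .gap(x)
    mx <- .gmp(x)
    a1 <- mlp$forward(avg, training)
    a2 <- mlp$forward(mx$vals, training)   # overwrites mlp cache: recompute in bwd
    gch <- 1 / (1 + exp(-(a1 + a2)))
    gb <- array(rep(as.vector(gch), each = d[1] * d[2]), d)
    x1 <- x * gb
    cavg <- array(0, c(d[1], d[2], 1L, d[4]))
    cmax <- array(0, c(d[1], d[2], 1L, d[4]))
    wmax <- array(0L, c(d[1], d[2], d[4]))
    for (n in seq_len(d[4])) {
      sl <- x1[, , , n, drop = FALSE]
      dim(sl) <- c(d[1] * d[2], d[3])
      cavg[, , 1L, n] <- rowMeans(sl)
      wk <- max.col(sl, ties.method = "first")
      cmax[, , 1L, n] <- sl[cbind(seq_len(d[1] * d[2]), wk)]
      wmax[, , n] <- wk
    }
    smap <- conv$forward(concat_channels(cavg, cmax), training)
    sgate <- 1 / (1 + exp(-smap))
    sb <- array(rep(as.vector(sgate), times = 1), c(d[1], d[2], 1L, d[4]))
    sfull <- array(0, d)
    for (cc in seq_len(d[3])) sfull[, , cc, ] <- sb[, , 1L, ]
    y <- x1 * sfull
    m$cache <- list(x = x, avg = avg, mx = mx, gch = gch, gb = gb, x1 = x1,
                    sgate = sgate, sfull = sfull, wmax = wmax, d = d,
                    training = training)
    y
  }
  m$backward <- function(gy) {
    cc <- m$cache; d <- cc$d
    # spatial gate
    gx1_a <- gy * cc$sfull
    gs_full <- gy * cc$x1
    gs <- array(0, c(d[1], d[2], 1L, d[4]))
    for (n in seq_len(d[4])) {
      sl <- gs_full[, , , n, drop = FALSE]
      dim(sl) <- c(d[1] * d[2], d[3])
      gs[, , 1L, n] <- rowSums(sl)
    }
    gsmap <- gs * cc$sgate * (1 - cc$sgate)
    gcat <- conv$backward(gsmap)
    sp <- split_channels(gcat, 1L)
    gavg_map <- sp[[1]]; gmax_map <- sp[[2]]
    gx1_b <- array(0, d)
    for (n in seq_len(d[4])) {
      ga <- as.vector(gavg_map[, , 1L, n]) / d[3]
      gm <- as.vector(gmax_map[, , 1L, n])
      blk <- matrix(0, d[1] * d[2], d[3])
      blk <- blk + ga
      wk <- as.vector(cc$wmax[, , n])
      blk[cbind(seq_len(d[1] * d[2]), wk)] <-
        blk[cbind(seq_len(d[1] * d[2]), wk)] + gm
      gx1_b[, , , n] <- array(blk, c(d[1], d[2], d[3]))
    }
    gx1 <- gx1_a + gx1_b
    # channel gate
    ggb <- gx1 * cc$x
    gx_a <- gx1 * cc$gb
    gch_mat <- matrix(0, d[3], d[4])
    for (n in seq_len(d[4])) {
      sl <- ggb[, , , n, drop = FALSE]
      dim(sl) <- c(d[1] * d[2], d[3])
      gch_mat[, n] <- colSums(sl)
    }
    ga <- gch_mat * cc$gch * (1 - cc$gch)
    # shared MLP used twice: replay each branch before backpropagating it
    mlp$forward(cc$avg, cc$training)
    gavg <- mlp$backward(ga)
    mlp$forward(cc$mx$vals, cc$training)
    gmaxv <- mlp$backward(ga)
    gx_b <- array(rep(as.vector(gavg) / (d[1] * d[2]), each = d[1] * d[2]), d)
    gx_c <- array(0, d)
    dim(gx_c) <- c(d[1] * d[2], d[3] * d[4])
    gx_c[cbind(((cc$mx$which - 1) %% (d[1] * d[2])) + 1, seq_len(d[3] * d[4]))] <-
      as.vector(gmaxv)
    dim(gx_c) <- d
    gx_a + gx_b + gx_c
  }
  m
}

#' Concurrent spatial and channel squeeze-excitation (scSE)
#'
#' Additive combination of a channel squeeze-excitation branch (sigmoid MLP
#' gate on globally pooled descriptors) and a spatial gate (sigmoid 1x1
#' convolution): `y = x * g_channel + x * g_spatial`.
#'
#' @param C feature channels.
#' @param reduction channel reduction (must not exceed C).
#' @return an internal network module.
#' @export
mod_scse <- function(C, reduction = 16L) {
  if (C < reduction) stop("channels < reduction in scSE", call. = FALSE)
  hidden <- max(1L, C %/% reduction)
  mlp <- mod_mlp2(C, hidden)
  conv <- mod_conv2d(C, 1L, k = 1L, stride = 1L, bias = TRUE)
  m <- new_module("scse", children = list(mlp = mlp, conv = conv))
  m$C <- C
  m$forward <- function(x, training = FALSE) {
    d <- dim(x)
    z <- .gap(x)
    a <- mlp$forward(z, training)
    gch <- 1 / (1 + exp(-a))
    gb <- array(rep(as.vector(gch), each = d[1] * d[2]), d)
    smap <- conv$forward(x, training)
    sg <- 1 / (1 + exp(-smap))
    sfull <- array(0, d)
    for (cc in seq_len(d[3])) sfull[, , cc, ] <- sg[, , 1L, ]
    y <- x * gb + x * sfull
    m$cache <- list(x = x, gch = gch, gb = gb, sg = sg, sfull = sfull, d = d)
    y
  }
  m$backward <- function(gy) {
    cc <- m$cache; d <- cc$d
    gx <- gy * cc$gb + gy * cc$sfull
    # channel branch
    ggb <- gy * cc$x
    gch_mat <- matrix(0, d[3], d[4])
    for (n in seq_len(d[4])) {
      sl <- ggb[, , , n, drop = FALSE]
      dim(sl) <- c(d[1] * d[2], d[3])
      gch_mat[, n] <- colSums(sl)
    }
    ga <- gch_mat * cc$gch * (1 - cc$gch)
    gz <- mlp$backward(ga)
    gx <- gx + array(rep(as.vector(gz) / (d[1] * d[2]), each = d[1] * d[2]), d)
    # spatial branch
    gsf <- gy * cc$x
    gs <- array(0, c(d[1], d[2], 1L, d[4]))
    for (n in seq_len(d[4])) {
      sl <- gsf[, , , n, drop = FALSE]
      dim(sl) <- c(d[1] * d[2], d[3])
      gs[, , 1L, n] <- rowSums(sl)
    }
    gsm <- gs * cc$sg * (1 - cc$sg)
    gx + conv$backward(gsm)
  }
  m
}

mod_sequential <- function(...) {
  mods <- list(...)
  if (length(mods) == 1L && is.list(mods[[1]]) && !inherits(mods[[1]], "nn_module")) {
    mods <- mods[[1]]
  }
  m <- new_module("sequential", children = mods)
  m$forward <- function(x, training = FALSE) {
    for (mm in m$children) x <- mm$forward(x, training)
    x
  }
  m$backward <- function(gy) {
    for (mm in rev(m$children)) gy <- mm$backward(gy)
    gy
  }
  m
}

# Flatten a module tree to a named list of leaf modules with parameters.
collect_modules <- function(mod, prefix = "root") {
  out <- list()
  if (length(mod$par) > 0) out[[prefix]] <- mod
  for (nm in names(mod$children)) {
    out <- c(out, collect_modules(mod$children[[nm]],
                                  paste(prefix, nm, sep = ".")))
  }
  if (is.null(names(mod$children)) && length(mod$children) > 0) {
    for (i in seq_along(mod$children)) {
      out <- c(out, collect_modules(mod$children[[i]],
                                    paste(prefix, i, sep = ".")))
    }
  }
  out
}

#' Count trainable parameters of a built model or module
#' @param mod a module or model object.
#' @return total number of trainable parameters.
#' @export
n_parameters <- function(mod) {
  mods <- collect_modules(mod)
  sum(vapply(mods, function(m) sum(vapply(m$par, length, numeric(1))), numeric(1)))
}

zero_grads <- function(mods) {
  for (m in mods) for (nm in names(m$grad)) m$grad[[nm]][] <- 0
  invisible(NULL)
}

#' Snapshot model parameters and normalisation statistics
#' @param mod a model object.
#' @return opaque snapshot list for [set_param_state()].
#' @export
get_param_state <- function(mod) {
  mods <- collect_modules(mod)
  lapply(mods, function(m) list(par = m$par, state = m$state))
}

#' Restore model parameters from a snapshot
#' @param mod a model object built with the same configuration.
#' @param snapshot snapshot from [get_param_state()].
#' @return the model, invisibly.
#' @export
set_param_state <- function(mod, snapshot) {
  mods <- collect_modules(mod)
  stopifnot(identical(names(mods), names(snapshot)))
  for (nm in names(mods)) {
    mods[[nm]]$par <- snapshot[[nm]]$par
    mods[[nm]]$state <- snapshot[[nm]]$state
  }
  invisible(mod)
}

# AdamW with decoupled weight decay; decay is skipped for 1-D parameters
# (biases, normalisation scales), following common practice.
adamw_state <- function(mods) {
  lapply(mods, function(m) lapply(m$par, function(p) {
    list(m = array(0, dim(p) %||% length(p)), v = array(0, dim(p) %||% length(p)))
  }))
}

adamw_step <- function(mods, opt, lr, weight_decay = 1e-4,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8, t = 1) {
  b1t <- 1 - beta1^t; b2t <- 1 - beta2^t
  for (nm in names(mods)) {
    m <- mods[[nm]]
    for (pn in names(m$par)) {
      g <- m$grad[[pn]]
      st <- opt[[nm]][[pn]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      opt[[nm]][[pn]] <- st
      upd <- (st$m / b1t) / (sqrt(st$v / b2t) + eps)
      p <- m$par[[pn]]
      if (is.null(dim(p))) upd <- as.vector(upd)
      if (!is.null(dim(p)) && length(dim(p)) >= 2 && weight_decay > 0) {
        p <- p - lr * weight_decay * p
      }
      m$par[[pn]] <- p - lr * upd
    }
  }
  opt
}
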