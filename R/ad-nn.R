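# Differentiable network layers on H x W x C x N arrays: convolutions
# (Rcpp/Armadillo kernels), pooling, batch normalization, resizing and the
# channel/spatial broadcast ops used by the attention blocks.

#' @useDynLib msssl, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

ad_conv2d <- function(x, w, b, stride = 1L, pad = 1L) {
  xv <- vof(x); wv <- vof(w); bv <- vof(b)
  v <- conv2d_fw_cpp(xv, wv, bv, as.integer(stride), as.integer(pad))
  if (!is_ad(x) && !is_ad(w) && !is_ad(b)) return(v)
  ps <- list(); ix <- iw <- ib <- 0L
  if (is_ad(x)) { ps <- c(ps, list(x)); ix <- length(ps) }
  if (is_ad(w)) { ps <- c(ps, list(w)); iw <- length(ps) }
  if (is_ad(b)) { ps <- c(ps, list(b)); ib <- length(ps) }
  new_node(v, ps, function(g) {
    bw <- conv2d_bw_cpp(xv, wv, g, as.integer(stride), as.integer(pad))
    out <- vector("list", length(ps))
    if (ix) out[[ix]] <- bw$dx
    if (iw) out[[iw]] <- bw$dw
    if (ib) out[[ib]] <- bw$db
    out
  })
}

ad_convt2d <- function(x, w, b, stride = 2L, pad = 1L, outpad = 1L) {
  xv <- vof(x); wv <- vof(w); bv <- vof(b)
  v <- convt2d_fw_cpp(xv, wv, bv, as.integer(stride), as.integer(pad),
                      as.integer(outpad))
  if (!is_ad(x) && !is_ad(w) && !is_ad(b)) return(v)
  ps <- list(); ix <- iw <- ib <- 0L
  if (is_ad(x)) { ps <- c(ps, list(x)); ix <- length(ps) }
  if (is_ad(w)) { ps <- c(ps, list(w)); iw <- length(ps) }
  if (is_ad(b)) { ps <- c(ps, list(b)); ib <- length(ps) }
  new_node(v, ps, function(g) {
    bw <- convt2d_bw_cpp(xv, wv, g, as.integer(stride), as.integer(pad),
                         as.integer(outpad))
    out <- vector("list", length(ps))
    if (ix) out[[ix]] <- bw$dx
    if (iw) out[[iw]] <- bw$dw
    if (ib) out[[ib]] <- bw$db
    out
  })
}

ad_maxpool2d <- function(x, k = 3L, stride = 2L, pad = 1L) {
  xv <- vof(x)
  fw <- maxpool2d_fw_cpp(xv, as.integer(k), as.integer(stride), as.integer(pad))
  if (!is_ad(x)) return(fw$y)
  xd <- dim(xv)
  new_node(fw$y, list(x), function(g) {
    list(maxpool2d_bw_cpp(fw$argmax, g, as.integer(xd)))
  })
}

# ---- batch normalization ----------------------------------------------------

# Buffers (running mean/var) live in `buffers[[name]]` and are updated in
# place when training; inference standardizes with the running statistics.
# Statistics are per channel over (H, W, N); the single-pass kernels live in
# C++ (bn_fw_cpp / bn_bw_cpp).
ad_batchnorm2d <- function(x, gamma, beta, buffers, name, training = TRUE,
                           momentum = 0.1, eps = 1e-5) {
  xv <- vof(x)
  d <- dim(xv)
  C <- d[3]
  M <- d[1] * d[2] * d[4]
  gv <- vof(gamma); bv <- vof(beta)
  bst <- buffers[[name]]
  if (is.null(bst)) bst <- list(mean = rep(0, C), var = rep(1, C))
  fw <- bn_fw_cpp(xv, gv, bv, bst$mean, bst$var, training, eps)
  if (training) {
    bst$mean <- (1 - momentum) * bst$mean + momentum * fw$mu
    bst$var <- (1 - momentum) * bst$var +
      momentum * fw$var * M / max(M - 1, 1)
    buffers[[name]] <- bst
  }
  v <- fw$y
  if (!is_ad(x) && !is_ad(gamma) && !is_ad(beta)) return(v)
  ps <- list(); ix <- ig <- ib <- 0L
  if (is_ad(x)) { ps <- c(ps, list(x)); ix <- length(ps) }
  if (is_ad(gamma)) { ps <- c(ps, list(gamma)); ig <- length(ps) }
  if (is_ad(beta)) { ps <- c(ps, list(beta)); ib <- length(ps) }
  new_node(v, ps, function(g) {
    bw <- bn_bw_cpp(xv, g, fw$mu, fw$inv, gv, training)
    out <- vector("list", length(ps))
    if (ix) out[[ix]] <- bw$dx
    if (ig) out[[ig]] <- bw$dgamma
    if (ib) out[[ib]] <- bw$dbeta
    out
  })
}

# Group normalization: per-sample, per-group statistics, so activations of
# one batch element never depend on another (keeps the pretraining loss free
# of cross-sample coupling). Implemented by reinterpreting each (group,
# sample) slab as a "channel" of the batch-norm kernel, then applying the
# per-channel gain/offset.
ad_groupnorm2d <- function(x, gamma, beta, groups = NULL, eps = 1e-5) {
  d <- dim(vof(x))
  C <- d[3]; N <- d[4]
  G <- groups %||% max(1L, C %/% 8L)
  while (C %% G != 0L) G <- G - 1L
  Cg <- C %/% G
  scratch <- new.env(parent = emptyenv())
  xr <- ad_reshape(x, c(d[1] * d[2] * Cg, 1, G * N, 1))
  xn <- ad_batchnorm2d(xr, rep(1, G * N), rep(0, G * N), scratch, "gn",
                       training = TRUE, momentum = 0, eps = eps)
  xn <- ad_reshape(xn, d)
  sc <- ad_matmul(ad_reshape(gamma, c(C, 1)), matrix(1, 1, N))
  y <- ad_scale_chan(xn, sc)
  ad_add_bias_chan(y, beta)
}

# ---- resizing ---------------------------------------------------------------

# Interpolation matrix for 1-D bilinear resampling with half-pixel centers.
bilinear_matrix <- function(n_out, n_in) {
  R <- matrix(0, n_out, n_in)
  if (n_in == 1L) {
    R[, 1] <- 1
    return(R)
  }
  for (i in seq_len(n_out)) {
    s <- (i - 0.5) * n_in / n_out - 0.5
    s <- min(max(s, 0), n_in - 1)
    i0 <- floor(s)
    f <- s - i0
    j0 <- i0 + 1
    j1 <- min(i0 + 2, n_in)
    R[i, j0] <- R[i, j0] + (1 - f)
    R[i, j1] <- R[i, j1] + f
  }
  R
}

resize_apply <- function(x, Rh, Rw) {
  d <- dim(x)
  y1 <- Rh %*% matrix(x, d[1])
  y1 <- array(y1, c(nrow(Rh), d[2], d[3], d[4]))
  y2 <- aperm(y1, c(2, 1, 3, 4))
  y2 <- Rw %*% matrix(y2, d[2])
  y2 <- array(y2, c(nrow(Rw), nrow(Rh), d[3], d[4]))
  aperm(y2, c(2, 1, 3, 4))
}

ad_bilinear_resize <- function(x, out_h, out_w) {
  xv <- vof(x)
  d <- dim(xv)
  if (d[1] == out_h && d[2] == out_w) return(x)
  Rh <- bilinear_matrix(out_h, d[1])
  Rw <- bilinear_matrix(out_w, d[2])
  v <- resize_apply(xv, Rh, Rw)
  if (!is_ad(x)) return(v)
  new_node(v, list(x), function(g) list(resize_apply(g, t(Rh), t(Rw))))
}

ad_upsample_nearest2 <- function(x) {
  xv <- vof(x)
  d <- dim(xv)
  ih <- rep(seq_len(d[1]), each = 2)
  iw <- rep(seq_len(d[2]), each = 2)
  v <- xv[ih, iw, , , drop = FALSE]
  if (!is_ad(x)) return(v)
  new_node(v, list(x), function(g) {
    o1 <- seq(1, 2 * d[1], by = 2)
    o2 <- seq(1, 2 * d[2], by = 2)
    gh <- g[o1, , , , drop = FALSE] + g[o1 + 1, , , , drop = FALSE]
    list(gh[, o2, , , drop = FALSE] + gh[, o2 + 1, , , drop = FALSE])
  })
}

# ---- channel / spatial broadcast ops ----------------------------------------

ad_concat_chan <- function(lst) {
  vals <- lapply(lst, vof)
  d1 <- dim(vals[[1]])
  chans <- vapply(vals, function(v) dim(v)[3], integer(1))
  Call <- sum(chans)
  v <- array(0, c(d1[1], d1[2], Call, d1[4]))
  at <- 0L
  for (i in seq_along(vals)) {
    v[, , at + seq_len(chans[i]), ] <- vals[[i]]
    at <- at + chans[i]
  }
  if (!any(vapply(lst, is_ad, logical(1)))) return(v)
  ends <- cumsum(chans)
  starts <- ends - chans + 1L
  nodes <- which(vapply(lst, is_ad, logical(1)))
  ps <- lst[nodes]
  new_node(v, ps, function(g) {
    lapply(nodes, function(i) g[, , starts[i]:ends[i], , drop = FALSE])
  })
}

ad_add_bias_chan <- function(x, b) {
  xv <- vof(x); bv <- vof(b)
  d <- dim(xv)
  HW <- d[1] * d[2]
  full <- rep(rep(bv, each = HW), times = d[4])
  v <- xv + full
  if (!is_ad(x) && !is_ad(b)) return(v)
  ps <- list(); ix <- ib <- 0L
  if (is_ad(x)) { ps <- c(ps, list(x)); ix <- length(ps) }
  if (is_ad(b)) { ps <- c(ps, list(b)); ib <- length(ps) }
  new_node(v, ps, function(g) {
    out <- vector("list", length(ps))
    if (ix) out[[ix]] <- g
    if (ib) out[[ib]] <- rowSums(matrix(colSums(matrix(g, HW)), d[3]))
    out
  })
}

# global average pool over space -> C x N matrix
ad_spatial_meanpool <- function(x) {
  xv <- vof(x)
  d <- dim(xv)
  HW <- d[1] * d[2]
  v <- matrix(colMeans(matrix(xv, HW)), d[3], d[4])
  if (!is_ad(x)) return(v)
  new_node(v, list(x), function(g) {
    gg <- rep(as.vector(g) / HW, each = HW)
    dim(gg) <- d
    list(gg)
  })
}

# global max pool over space -> C x N matrix
ad_spatial_maxpool <- function(x) {
  xv <- vof(x)
  d <- dim(xv)
  HW <- d[1] * d[2]
  xm <- matrix(xv, HW)
  cm <- colmax_cpp(xm)
  am <- cm$idx + 1L
  v <- matrix(cm$max, d[3], d[4])
  if (!is_ad(x)) return(v)
  new_node(v, list(x), function(g) {
    gm <- matrix(0, HW, ncol(xm))
    gm[cbind(am, seq_len(ncol(xm)))] <- as.vector(g)
    dim(gm) <- d
    list(gm)
  })
}

# scale every spatial position of channel c, sample n by s[c, n]
ad_scale_chan <- function(x, s) {
  xv <- vof(x); sv <- vof(s)
  d <- dim(xv)
  HW <- d[1] * d[2]
  sfull <- rep(as.vector(sv), each = HW)
  v <- xv * sfull
  dim(v) <- d
  if (!is_ad(x) && !is_ad(s)) return(v)
  ps <- list(); ix <- is <- 0L
  if (is_ad(x)) { ps <- c(ps, list(x)); ix <- length(ps) }
  if (is_ad(s)) { ps <- c(ps, list(s)); is <- length(ps) }
  new_node(v, ps, function(g) {
    out <- vector("list", length(ps))
    if (ix) {
      gx <- g * sfull
      dim(gx) <- d
      out[[ix]] <- gx
    }
    if (is) out[[is]] <- matrix(colSums(matrix(g * xv, HW)), d[3], d[4])
    out
  })
}

# channel-wise mean and max maps -> H x W x 1 x N
# (native layout: matrix(x, HW) has one column per (channel, sample) pair,
# so per-sample blocks of C columns reduce without any permutation)
ad_chan_mean <- function(x) {
  xv <- vof(x)
  d <- dim(xv)
  HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  xm <- matrix(xv, HW)
  v <- array(0, c(d[1], d[2], 1, N))
  for (n in seq_len(N))
    v[, , 1, n] <- .rowMeans(xm[, (n - 1) * C + seq_len(C), drop = FALSE],
                             HW, C)
  if (!is_ad(x)) return(v)
  new_node(v, list(x), function(g) {
    gm <- matrix(0, HW, C * N)
    gv <- matrix(g, HW) / C
    for (n in seq_len(N)) gm[, (n - 1) * C + seq_len(C)] <- gv[, n]
    dim(gm) <- d
    list(gm)
  })
}

ad_chan_max <- function(x) {
  xv <- vof(x)
  d <- dim(xv)
  HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  xm <- matrix(xv, HW)
  v <- array(0, c(d[1], d[2], 1, N))
  am <- matrix(0L, HW, N)
  for (n in seq_len(N)) {
    blk <- xm[, (n - 1) * C + seq_len(C), drop = FALSE]
    am[, n] <- max.col(blk, ties.method = "first")
    v[, , 1, n] <- blk[cbind(seq_len(HW), am[, n])]
  }
  if (!is_ad(x)) return(v)
  new_node(v, list(x), function(g) {
    gm <- matrix(0, HW, C * N)
    gv <- matrix(g, HW)
    for (n in seq_len(N))
      gm[cbind(seq_len(HW), (n - 1) * C + am[, n])] <- gv[, n]
    dim(gm) <- d
    list(gm)
  })
}

# scale every channel of position (h, w), sample n by s[h, w, 1, n]
ad_scale_spatial <- function(x, s) {
  xv <- vof(x); sv <- vof(s)
  d <- dim(xv)
  C <- d[3]
  sfull <- sv[, , rep(1L, C), , drop = FALSE]
  dim(sfull) <- d
  v <- xv * sfull
  if (!is_ad(x) && !is_ad(s)) return(v)
  ps <- list(); ix <- is <- 0L
  if (is_ad(x)) { ps <- c(ps, list(x)); ix <- length(ps) }
  if (is_ad(s)) { ps <- c(ps, list(s)); is <- length(ps) }
  new_node(v, ps, function(g) {
    out <- vector("list", length(ps))
    if (ix) out[[ix]] <- g * sfull
    if (is) {
      HW <- d[1] * d[2]
      gx <- matrix(g * xv, HW)
      ds <- array(0, c(d[1], d[2], 1, d[4]))
      for (n in seq_len(d[4]))
        ds[, , 1, n] <- .rowSums(gx[, (n - 1) * C + seq_len(C), drop = FALSE],
                                 HW, C)
      out[[is]] <- ds
    }
    out
  })
}
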