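# Minimal reverse-mode automatic differentiation over plain R arrays.
#
# A node is an environment holding the forward value, its parent nodes and a
# backward closure mapping the output gradient to the parents' gradients.
# Every op has a fast no-tape path: if none of its inputs is a node it returns
# a plain array, which is how the gradient-free momentum teacher is evaluated.

.ad <- new.env(parent = emptyenv())
.ad$id <- 0
.ad$visit <- 0L

new_node <- function(value, parents = list(), backfn = NULL, name = NULL) {
  e <- new.env(parent = emptyenv())
  .ad$id <- .ad$id + 1
  e$id <- .ad$id
  e$value <- value
  e$parents <- parents
  e$backfn <- backfn
  e$grad <- NULL
  e$name <- name
  class(e) <- "ad_node"
  e
}

#' @keywords internal
ad_leaf <- function(value, name = NULL) new_node(value, name = name)

is_ad <- function(x) inherits(x, "ad_node")

vof <- function(x) if (is_ad(x)) x$value else x

#' Run reverse-mode accumulation from a scalar root node.
#' @keywords internal
ad_backward <- function(root, seed = 1) {
  stopifnot(is_ad(root), length(root$value) == 1L)
  .ad$visit <- .ad$visit + 1L
  epoch <- .ad$visit
  nodes <- vector("list", 512L)
  nn <- 0L
  stack <- vector("list", 64L)
  sp <- 1L
  stack[[1L]] <- root
  root$.seen <- epoch
  while (sp > 0L) {
    nd <- stack[[sp]]
    sp <- sp - 1L
    nn <- nn + 1L
    if (nn > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[nn]] <- nd
    for (p in nd$parents) {
      if (!identical(p$.seen, epoch)) {
        p$.seen <- epoch
        sp <- sp + 1L
        if (sp > length(stack)) stack <- c(stack, vector("list", length(stack)))
        stack[[sp]] <- p
      }
    }
  }
  nodes <- nodes[seq_len(nn)]
  ids <- vapply(nodes, function(n) n$id, numeric(1))
  nodes <- nodes[order(ids, decreasing = TRUE)]
  for (nd in nodes) nd$grad <- NULL
  root$grad <- seed
  for (nd in nodes) {
    g <- nd$grad
    if (is.null(g) || is.null(nd$backfn)) next
    gs <- nd$backfn(g)
    ps <- nd$parents
    for (i in seq_along(ps)) {
      gi <- gs[[i]]
      if (is.null(gi)) next
      p <- ps[[i]]
      p$grad <- if (is.null(p$grad)) gi else p$grad + gi
    }
  }
  invisible(root)
}

keep_dim <- function(template, x) {
  d <- dim(template)
  if (!is.null(d)) dim(x) <- d
  x
}

# ---- elementwise ------------------------------------------------------------

ad_add <- function(a, b) {
  v <- vof(a) + vof(b)
  if (!is_ad(a) && !is_ad(b)) return(v)
  ps <- list()
  ia <- ib <- 0L
  if (is_ad(a)) { ps <- c(ps, list(a)); ia <- length(ps) }
  if (is_ad(b)) { ps <- c(ps, list(b)); ib <- length(ps) }
  new_node(v, ps, function(g) {
    out <- vector("list", length(ps))
    if (ia) out[[ia]] <- g
    if (ib) out[[ib]] <- g
    out
  })
}

ad_sub <- function(a, b) ad_add(a, ad_scale(b, -1))

ad_mul <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  v <- av * bv
  if (!is_ad(a) && !is_ad(b)) return(v)
  ps <- list(); ia <- ib <- 0L
  if (is_ad(a)) { ps <- c(ps, list(a)); ia <- length(ps) }
  if (is_ad(b)) { ps <- c(ps, list(b)); ib <- length(ps) }
  new_node(v, ps, function(g) {
    out <- vector("list", length(ps))
    if (ia) out[[ia]] <- g * bv
    if (ib) out[[ib]] <- g * av
    out
  })
}

ad_div <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  v <- av / bv
  if (!is_ad(a) && !is_ad(b)) return(v)
  ps <- list(); ia <- ib <- 0L
  if (is_ad(a)) { ps <- c(ps, list(a)); ia <- length(ps) }
  if (is_ad(b)) { ps <- c(ps, list(b)); ib <- length(ps) }
  new_node(v, ps, function(g) {
    out <- vector("list", length(ps))
    if (ia) out[[ia]] <- g / bv
    if (ib) out[[ib]] <- -g * av / (bv * bv)
    out
  })
}

# multiply by a plain scalar constant
ad_scale <- function(a, s) {
  v <- vof(a) * s
  if (!is_ad(a)) return(v)
  new_node(v, list(a), function(g) list(g * s))
}

# add a plain constant
ad_addc <- function(a, c) {
  v <- vof(a) + c
  if (!is_ad(a)) return(v)
  new_node(v, list(a), function(g) list(g))
}

ad_relu <- function(a) {
  av <- vof(a)
  v <- relu_fw_cpp(av)
  if (is.null(dim(av))) v <- as.vector(v)
  if (!is_ad(a)) return(v)
  new_node(v, list(a), function(g) list(relu_bw_cpp(g, v)))
}

ad_sigmoid <- function(a) {
  av <- vof(a)
  v <- 1 / (1 + exp(-av))
  if (!is_ad(a)) return(v)
  new_node(v, list(a), function(g) list(g * v * (1 - v)))
}

ad_exp <- function(a) {
  v <- exp(vof(a))
  if (!is_ad(a)) return(v)
  new_node(v, list(a), function(g) list(g * v))
}

ad_log <- function(a) {
  av <- vof(a)
  v <- log(av)
  if (!is_ad(a)) return(v)
  new_node(v, list(a), function(g) list(g / av))
}

ad_abs <- function(a) {
  av <- vof(a)
  v <- abs(av)
  if (!is_ad(a)) return(v)
  s <- sign(av)
  new_node(v, list(a), function(g) list(g * s))
}

# numerically stable log(1 + exp(x))
ad_softplus <- function(a) {
  av <- vof(a)
  v <- ifelse(av > 0, av + log1p(exp(-av)), log1p(exp(av)))
  v <- keep_dim(av, v)
  if (!is_ad(a)) return(v)
  s <- 1 / (1 + exp(-av))
  new_node(v, list(a), function(g) list(g * s))
}

# exact Gaussian-error linear unit: x * pnorm(x)
ad_gelu <- function(a) {
  av <- vof(a)
  ph <- stats::pnorm(av)
  v <- keep_dim(av, av * ph)
  if (!is_ad(a)) return(v)
  d <- ph + av * stats::dnorm(av)
  new_node(v, list(a), function(g) list(g * d))
}

# ---- matrix / shape ---------------------------------------------------------

ad_matmul <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  v <- av %*% bv
  if (!is_ad(a) && !is_ad(b)) return(v)
  ps <- list(); ia <- ib <- 0L
  if (is_ad(a)) { ps <- c(ps, list(a)); ia <- length(ps) }
  if (is_ad(b)) { ps <- c(ps, list(b)); ib <- length(ps) }
  new_node(v, ps, function(g) {
    out <- vector("list", length(ps))
    if (ia) out[[ia]] <- g %*% t(bv)
    if (ib) out[[ib]] <- crossprod(av, g)
    out
  })
}

ad_t <- function(a) {
  v <- t(vof(a))
  if (!is_ad(a)) return(v)
  new_node(v, list(a), function(g) list(t(g)))
}

# X (R x D) + bias b (length D), broadcast across rows
ad_addbias_rows <- function(x, b) {
  xv <- vof(x); bv <- vof(b)
  v <- sweep(xv, 2L, bv, "+")
  if (!is_ad(x) && !is_ad(b)) return(v)
  ps <- list(); ix <- ib <- 0L
  if (is_ad(x)) { ps <- c(ps, list(x)); ix <- length(ps) }
  if (is_ad(b)) { ps <- c(ps, list(b)); ib <- length(ps) }
  new_node(v, ps, function(g) {
    out <- vector("list", length(ps))
    if (ix) out[[ix]] <- g
    if (ib) out[[ib]] <- colSums(g)
    out
  })
}

ad_reshape <- function(a, dims) {
  av <- vof(a)
  od <- dim(av)
  v <- av
  dim(v) <- dims
  if (!is_ad(a)) return(v)
  new_node(v, list(a), function(g) {
    dim(g) <- od
    list(g)
  })
}

ad_aperm <- function(a, perm) {
  av <- vof(a)
  v <- aperm(av, perm)
  if (!is_ad(a)) return(v)
  inv <- order(perm)
  new_node(v, list(a), function(g) list(aperm(g, inv)))
}

ad_slice_rows <- function(a, idx) {
  av <- vof(a)
  v <- av[idx, , drop = FALSE]
  if (!is_ad(a)) return(v)
  nr <- nrow(av); nc <- ncol(av)
  new_node(v, list(a), function(g) {
    out <- matrix(0, nr, nc)
    out[idx, ] <- g
    list(out)
  })
}

ad_slice_cols <- function(a, idx) {
  av <- vof(a)
  v <- av[, idx, drop = FALSE]
  if (!is_ad(a)) return(v)
  nr <- nrow(av); nc <- ncol(av)
  new_node(v, list(a), function(g) {
    out <- matrix(0, nr, nc)
    out[, idx] <- g
    list(out)
  })
}

ad_rbind <- function(lst) {
  vals <- lapply(lst, vof)
  v <- do.call(rbind, vals)
  if (!any(vapply(lst, is_ad, logical(1)))) return(v)
  rows <- vapply(vals, nrow, integer(1))
  ends <- cumsum(rows)
  starts <- ends - rows + 1L
  nodes <- which(vapply(lst, is_ad, logical(1)))
  ps <- lst[nodes]
  new_node(v, ps, function(g) {
    lapply(nodes, function(i) g[starts[i]:ends[i], , drop = FALSE])
  })
}

ad_cbind <- function(lst) {
  vals <- lapply(lst, vof)
  v <- do.call(cbind, vals)
  if (!any(vapply(lst, is_ad, logical(1)))) return(v)
  cols <- vapply(vals, ncol, integer(1))
  ends <- cumsum(cols)
  starts <- ends - cols + 1L
  nodes <- which(vapply(lst, is_ad, logical(1)))
  ps <- lst[nodes]
  new_node(v, ps, function(g) {
    lapply(nodes, function(i) g[, starts[i]:ends[i], drop = FALSE])
  })
}

# ---- reductions -------------------------------------------------------------

ad_sum <- function(a) {
  av <- vof(a)
  v <- sum(av)
  if (!is_ad(a)) return(v)
  d <- dim(av); n <- length(av)
  new_node(v, list(a), function(g) {
    out <- rep(as.numeric(g), n)
    if (!is.null(d)) dim(out) <- d
    list(out)
  })
}

ad_mean <- function(a) ad_scale(ad_sum(a), 1 / length(vof(a)))

# ---- row-wise softmax family ------------------------------------------------

softmax_rows_val <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

ad_softmax_rows <- function(a) {
  av <- vof(a)
  v <- softmax_rows_val(av)
  if (!is_ad(a)) return(v)
  new_node(v, list(a), function(g) {
    s <- rowSums(g * v)
    list((g - s) * v)
  })
}

ad_logsoftmax_rows <- function(a) {
  av <- vof(a)
  m <- apply(av, 1L, max)
  z <- av - m
  lse <- log(rowSums(exp(z)))
  v <- z - lse
  if (!is_ad(a)) return(v)
  p <- exp(v)
  new_node(v, list(a), function(g) {
    list(g - p * rowSums(g))
  })
}

# row-wise layer normalization with learned gain/offset over the feature axis
ad_layernorm_rows <- function(x, gamma, beta, eps = 1e-6) {
  xv <- vof(x)
  gv <- vof(gamma); bv <- vof(beta)
  D <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  varr <- rowMeans(xc * xc)
  inv <- 1 / sqrt(varr + eps)
  xhat <- xc * inv
  v <- sweep(sweep(xhat, 2L, gv, "*"), 2L, bv, "+")
  if (!is_ad(x) && !is_ad(gamma) && !is_ad(beta)) return(v)
  ps <- list(); ix <- ig <- ib <- 0L
  if (is_ad(x)) { ps <- c(ps, list(x)); ix <- length(ps) }
  if (is_ad(gamma)) { ps <- c(ps, list(gamma)); ig <- length(ps) }
  if (is_ad(beta)) { ps <- c(ps, list(beta)); ib <- length(ps) }
  new_node(v, ps, function(g) {
    out <- vector("list", length(ps))
    gh <- sweep(g, 2L, gv, "*")
    if (ix) {
      t1 <- rowMeans(gh)
      t2 <- rowMeans(gh * xhat)
      out[[ix]] <- inv * (gh - t1 - xhat * t2)
    }
    if (ig) out[[ig]] <- colSums(g * xhat)
    if (ib) out[[ib]] <- colSums(g)
    out
  })
}
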