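# Parameter initialization and the decoupled-weight-decay adaptive optimizer
# used for pretraining, fine-tuning and the linear heads.

init_trunc_normal <- function(dims, sd = 0.02) {
  n <- prod(dims)
  x <- stats::rnorm(n, 0, sd)
  out <- abs(x) > 2 * sd
  while (any(out)) {
    x[out] <- stats::rnorm(sum(out), 0, sd)
    out <- abs(x) > 2 * sd
  }
  array(x, dims)
}

# Kaiming/He fan-in init for conv weights (kh, kw, Cin, Cout)
init_conv <- function(kh, kw, cin, cout) {
  fan_in <- kh * kw * cin
  array(stats::rnorm(kh * kw * cin * cout, 0, sqrt(2 / fan_in)),
        c(kh, kw, cin, cout))
}

# Deconv weights (kh, kw, Cout, Cin); fan-in is kh*kw*Cin / stride^2-ish,
# plain He fan-in on the input channels works fine at this scale
init_deconv <- function(kh, kw, cout, cin) {
  fan_in <- kh * kw * cin
  array(stats::rnorm(kh * kw * cout * cin, 0, sqrt(2 / fan_in)),
        c(kh, kw, cout, cin))
}

init_linear <- function(din, dout) {
  matrix(stats::rnorm(din * dout, 0, sqrt(2 / din)), din, dout)
}

zeros <- function(...) {
  d <- c(...)
  if (length(d) == 1L) numeric(d) else array(0, d)
}

lift_params <- function(params) {
  out <- lapply(names(params), function(nm) ad_leaf(params[[nm]], nm))
  names(out) <- names(params)
  out
}

collect_grads <- function(lifted) {
  out <- lapply(lifted, function(nd) {
    if (is.null(nd$grad)) {
      g <- nd$value
      g[] <- 0
      g
    } else nd$grad
  })
  names(out) <- names(lifted)
  out
}

#' @keywords internal
adamw_state <- function(params, lr = 5e-4, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8, weight_decay = 0.04) {
  e <- new.env(parent = emptyenv())
  e$m <- lapply(params, function(p) { p[] <- 0; p })
  e$v <- lapply(params, function(p) { p[] <- 0; p })
  e$t <- 0L
  e$lr <- lr
  e$beta1 <- beta1
  e$beta2 <- beta2
  e$eps <- eps
  e$weight_decay <- weight_decay
  class(e) <- "adamw_state"
  e
}

# no weight decay on biases, gains, offsets, cls/pos tokens
decay_mask <- function(names) {
  !grepl("(\\.b$|\\.b[0-9]$|\\.g$|\\.beta$|\\.gamma$|\\.cls$|\\.pos$|bias)", names)
}

adamw_step <- function(opt, params, grads, lr = NULL) {
  opt$t <- opt$t + 1L
  lr <- lr %||% opt$lr
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t
  bc2 <- 1 - b2^opt$t
  dm <- decay_mask(names(params))
  for (i in seq_along(params)) {
    nm <- names(params)[i]
    g <- grads[[nm]]
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g * g
    mhat <- opt$m[[nm]] / bc1
    vhat <- opt$v[[nm]] / bc2
    upd <- mhat / (sqrt(vhat) + opt$eps)
    if (dm[i]) upd <- upd + opt$weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * upd
  }
  params
}

# half-cosine decay from base_lr to floor_frac*base_lr over total steps,
# with linear warmup
cosine_lr <- function(step, total, base_lr, warmup = 10L, floor_frac = 0.01) {
  if (step < warmup) return(base_lr * step / max(warmup, 1L))
  tt <- min(1, (step - warmup) / max(total - warmup, 1L))
  floor_lr <- base_lr * floor_frac
  floor_lr + 0.5 * (base_lr - floor_lr) * (1 + cos(pi * tt))
}
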