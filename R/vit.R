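# Global Feature Extractor: a vision transformer over non-overlapping image
# patches, returning the class ("global") token, the patch-token grid used by
# multi-scale fusion, and optionally all self-attention tensors. Also the
# 3-layer projection head whose output feeds the self-distillation objective.

#' ViT configuration
#'
#' @param variant `"S"` (embed 384, depth 12, 6 heads) or `"B"` (embed 768,
#'   depth 12, 12 heads); with `patch_size` 16 or 32 this covers the
#'   ViT-S16/S32/B16/B32 backbones. `embed_dim`, `depth`, `heads` may be
#'   overridden explicitly for reduced desk-scale encoders.
#' @param patch_size 16 or 32.
#' @param input_size square input side; must be divisible by `patch_size`.
#' @param embed_dim,depth,heads optional overrides.
#' @param proj_hidden,proj_dim projection-head widths.
#' @export
vit_config <- function(variant = c("S", "B"), patch_size = 16,
                       input_size = 224, embed_dim = NULL, depth = NULL,
                       heads = NULL, proj_hidden = 2048, proj_dim = 256) {
  variant <- match.arg(variant)
  if (!patch_size %in% c(16, 32)) stop("patch_size must be 16 or 32")
  if (input_size %% patch_size != 0)
    stop("input_size must be divisible by patch_size")
  std <- if (variant == "S") c(384, 12, 6) else c(768, 12, 12)
  embed_dim <- embed_dim %||% std[1]
  depth <- depth %||% std[2]
  heads <- heads %||% std[3]
  if (embed_dim %% heads != 0) stop("embed_dim must be divisible by heads")
  structure(list(variant = variant, patch_size = as.integer(patch_size),
                 input_size = as.integer(input_size),
                 embed_dim = as.integer(embed_dim),
                 depth = as.integer(depth), heads = as.integer(heads),
                 proj_hidden = as.integer(proj_hidden),
                 proj_dim = as.integer(proj_dim)),
            class = "vit_config")
}

#' Split an image into flattened patch tokens
#'
#' Tokens are in row-major grid order (the column index moves fastest);
#' each token is the flattened `p x p x C` patch.
#'
#' @param img H x W x C array (or H x W x C x N batch).
#' @param patch_size patch side `p`; must divide H and W.
#' @return a `(H/p)(W/p) x p*p*C` matrix (rows stacked per sample for a
#'   batch) with attribute `grid = c(H/p, W/p)`.
#' @export
patchify <- function(img, patch_size) {
  d <- dim(img)
  single <- length(d) == 3
  if (single) {
    dim(img) <- c(d, 1)
    d <- dim(img)
  }
  p <- as.integer(patch_size)
  if (d[1] %% p != 0 || d[2] %% p != 0)
    stop("image side not divisible by patch size")
  Hp <- d[1] %/% p
  Wp <- d[2] %/% p
  a <- array(img, c(p, Hp, p, Wp, d[3], d[4]))
  a <- aperm(a, c(1, 3, 5, 4, 2, 6)) # (pi, pj, c, wp, hp, n)
  toks <- t(matrix(a, p * p * d[3]))
  attr(toks, "grid") <- c(Hp, Wp)
  toks
}

#' Reassemble an image from patch tokens
#' @param tokens matrix from [patchify()] (one sample).
#' @param patch_size patch side.
#' @param H,W,C image dimensions.
#' @export
unpatchify <- function(tokens, patch_size, H, W, C = 3) {
  p <- as.integer(patch_size)
  Hp <- H %/% p
  Wp <- W %/% p
  a <- array(t(tokens), c(p, p, C, Wp, Hp, 1))
  a <- aperm(a, c(1, 5, 2, 4, 3, 6))
  array(a, c(H, W, C))
}

# parameter set for the GFE (+ its projection head)
gfe_init <- function(cfg) {
  D <- cfg$embed_dim
  p <- cfg$patch_size
  Np <- (cfg$input_size %/% p)^2
  P <- list()
  P[["gfe.patch_proj.W"]] <- init_trunc_normal(c(p * p * 3, D))
  P[["gfe.patch_proj.b"]] <- zeros(D)
  P[["gfe.cls"]] <- init_trunc_normal(c(1, D))
  P[["gfe.pos"]] <- init_trunc_normal(c(1 + Np, D))
  for (l in seq_len(cfg$depth)) {
    pre <- sprintf("gfe.block%d.", l)
    P[[paste0(pre, "ln1.g")]] <- rep(1, D)
    P[[paste0(pre, "ln1.b")]] <- zeros(D)
    P[[paste0(pre, "attn.Wqkv")]] <- init_trunc_normal(c(D, 3 * D))
    P[[paste0(pre, "attn.bqkv")]] <- zeros(3 * D)
    P[[paste0(pre, "attn.Wo")]] <- init_trunc_normal(c(D, D))
    P[[paste0(pre, "attn.bo")]] <- zeros(D)
    P[[paste0(pre, "ln2.g")]] <- rep(1, D)
    P[[paste0(pre, "ln2.b")]] <- zeros(D)
    P[[paste0(pre, "mlp.W1")]] <- init_trunc_normal(c(D, 4 * D))
    P[[paste0(pre, "mlp.b1")]] <- zeros(4 * D)
    P[[paste0(pre, "mlp.W2")]] <- init_trunc_normal(c(4 * D, D))
    P[[paste0(pre, "mlp.b2")]] <- zeros(D)
  }
  P[["gfe.ln.g"]] <- rep(1, D)
  P[["gfe.ln.b"]] <- zeros(D)
  P[["proj.W1"]] <- init_trunc_normal(c(D, cfg$proj_hidden))
  P[["proj.b1"]] <- zeros(cfg$proj_hidden)
  P[["proj.W2"]] <- init_trunc_normal(c(cfg$proj_hidden, cfg$proj_hidden))
  P[["proj.b2"]] <- zeros(cfg$proj_hidden)
  P[["proj.W3"]] <- init_trunc_normal(c(cfg$proj_hidden, cfg$proj_dim))
  P[["proj.b3"]] <- zeros(cfg$proj_dim)
  P
}

linear_rows <- function(x, P, wname, bname) {
  ad_addbias_rows(ad_matmul(x, P[[wname]]), P[[bname]])
}

# one multi-head self-attention over the (N*T) x D token matrix
mha_forward <- function(x, P, pre, T, N, heads, collect = FALSE) {
  D <- ncol(vof(x))
  dh <- D %/% heads
  qkv <- linear_rows(x, P, paste0(pre, "attn.Wqkv"), paste0(pre, "attn.bqkv"))
  out_samples <- vector("list", N)
  attn <- if (collect) array(0, c(heads, T, T, N)) else NULL
  for (n in seq_len(N)) {
    rows <- (n - 1) * T + seq_len(T)
    qkv_n <- ad_slice_rows(qkv, rows)
    head_outs <- vector("list", heads)
    for (h in seq_len(heads)) {
      cols <- (h - 1) * dh + seq_len(dh)
      Q <- ad_slice_cols(qkv_n, cols)
      K <- ad_slice_cols(qkv_n, D + cols)
      V <- ad_slice_cols(qkv_n, 2 * D + cols)
      A <- ad_softmax_rows(ad_scale(ad_matmul(Q, ad_t(K)), 1 / sqrt(dh)))
      if (collect) attn[h, , , n] <- vof(A)
      head_outs[[h]] <- ad_matmul(A, V)
    }
    out_samples[[n]] <- ad_cbind(head_outs)
  }
  o <- ad_rbind(out_samples)
  o <- linear_rows(o, P, paste0(pre, "attn.Wo"), paste0(pre, "attn.bo"))
  list(out = o, attn = attn)
}

#' Run the ViT global feature extractor
#'
#' @param x standardized raster, H x W x 3 (or H x W x 3 x N batch), with
#'   H = W = `cfg$input_size`.
#' @param params parameter list from [init_msssl_model()] (arrays, or tape
#'   nodes during training).
#' @param cfg a [vit_config()].
#' @param collect_attention if `TRUE`, return every layer's softmax
#'   attention as a `(depth, heads, 1+Np, 1+Np, N)` array.
#' @return a `token_embeddings` object: `tokens` ((1+Np)N x D, global token
#'   first within each sample block), `grid`, `T`, `N`, `dim`, `attention`.
#' @export
gfe_forward <- function(x, params, cfg, collect_attention = FALSE) {
  xv <- vof(x)
  if (length(dim(xv)) == 3) dim(xv) <- c(dim(xv), 1)
  d <- dim(xv)
  if (d[1] != cfg$input_size || d[2] != cfg$input_size)
    stop("input size does not match ViT configuration")
  N <- d[4]
  p <- cfg$patch_size
  Hp <- d[1] %/% p
  Np <- Hp * (d[2] %/% p)
  T <- Np + 1
  D <- cfg$embed_dim

  toks <- patchify(xv, p)
  E <- linear_rows(toks, params, "gfe.patch_proj.W", "gfe.patch_proj.b")
  crep <- ad_matmul(matrix(1, N, 1), params[["gfe.cls"]])
  stacked <- ad_rbind(list(crep, E))
  idx <- unlist(lapply(seq_len(N), function(n)
    c(n, N + (n - 1) * Np + seq_len(Np))))
  X <- ad_slice_rows(stacked, idx)
  X <- ad_add(X, ad_slice_rows(params[["gfe.pos"]], rep(seq_len(T), N)))

  attention <- if (collect_attention)
    array(0, c(cfg$depth, cfg$heads, T, T, N)) else NULL
  for (l in seq_len(cfg$depth)) {
    pre <- sprintf("gfe.block%d.", l)
    h1 <- ad_layernorm_rows(X, params[[paste0(pre, "ln1.g")]],
                            params[[paste0(pre, "ln1.b")]])
    mh <- mha_forward(h1, params, pre, T, N, cfg$heads,
                      collect = collect_attention)
    if (collect_attention) attention[l, , , , ] <- mh$attn
    X <- ad_add(X, mh$out)
    h2 <- ad_layernorm_rows(X, params[[paste0(pre, "ln2.g")]],
                            params[[paste0(pre, "ln2.b")]])
    m <- linear_rows(h2, params, paste0(pre, "mlp.W1"), paste0(pre, "mlp.b1"))
    m <- ad_gelu(m)
    m <- linear_rows(m, params, paste0(pre, "mlp.W2"), paste0(pre, "mlp.b2"))
    X <- ad_add(X, m)
  }
  X <- ad_layernorm_rows(X, params[["gfe.ln.g"]], params[["gfe.ln.b"]])
  structure(list(tokens = X, grid = c(Hp, d[2] %/% p), T = T, N = N,
                 dim = D, attention = attention),
            class = "token_embeddings")
}

# rows of the global (class) token, one per sample
gfe_cls_token <- function(emb) {
  idx <- (seq_len(emb$N) - 1) * emb$T + 1
  ad_slice_rows(emb$tokens, idx)
}

# patch-token rows (global token dropped)
gfe_patch_tokens <- function(emb) {
  idx <- unlist(lapply(seq_len(emb$N), function(n)
    (n - 1) * emb$T + 1 + seq_len(emb$T - 1)))
  ad_slice_rows(emb$tokens, idx)
}

#' Projection head on the global token
#'
#' Three linear layers (hidden width, hidden width, projection dim) with
#' GELU nonlinearities between them.
#'
#' @param x N x D matrix (global-token rows).
#' @param params model parameters.
#' @param cfg a [vit_config()].
#' @return N x proj_dim matrix (node during training).
#' @export
projection_head <- function(x, params, cfg) {
  h <- ad_gelu(linear_rows(x, params, "proj.W1", "proj.b1"))
  h <- ad_gelu(linear_rows(h, params, "proj.W2", "proj.b2"))
  linear_rows(h, params, "proj.W3", "proj.b3")
}
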