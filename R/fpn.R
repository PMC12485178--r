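# Fine-grained Feature Extractor: a ResNet backbone (basic blocks for
# resnet18, bottlenecks for resnet50) feeding a top-down feature pyramid
# with 1x1 lateral projections, nearest-neighbor upsampling, elementwise
# sums and 3x3 smoothing. P2/P3/P5 (strides 4/8/32) are exposed, and the
# multi-scale fusion that merges the pyramid with the ViT patch-token grid.

#' FFE configuration
#'
#' @param backbone `"resnet18"` or `"resnet50"`.
#' @param base_width channel width of the first stage (64 for the standard
#'   backbones; smaller for desk-scale encoders).
#' @param c_fpn common pyramid channel width (FPN convention: 256).
#' @export
ffe_config <- function(backbone = c("resnet50", "resnet18"), base_width = 64,
                       c_fpn = 256) {
  backbone <- match.arg(backbone)
  structure(list(backbone = backbone, base_width = as.integer(base_width),
                 c_fpn = as.integer(c_fpn)),
            class = "ffe_config")
}

resnet_plan <- function(cfg) {
  w <- cfg$base_width
  if (cfg$backbone == "resnet18") {
    list(kind = "basic", blocks = c(2, 2, 2, 2),
         mid = w * c(1, 2, 4, 8), out = w * c(1, 2, 4, 8))
  } else {
    list(kind = "bottleneck", blocks = c(3, 4, 6, 3),
         mid = w * c(1, 2, 4, 8), out = 4 * w * c(1, 2, 4, 8))
  }
}

ffe_init <- function(cfg) {
  plan <- resnet_plan(cfg)
  w <- cfg$base_width
  P <- list()
  add_norm <- function(nm, C) {
    P[[paste0(nm, ".g")]] <<- rep(1, C)
    P[[paste0(nm, ".b")]] <<- zeros(C)
  }
  P[["ffe.stem.conv"]] <- init_conv(7, 7, 3, w)
  add_norm("ffe.stem.gn", w)
  cin <- w
  for (s in 1:4) {
    for (b in seq_len(plan$blocks[s])) {
      pre <- sprintf("ffe.s%db%d.", s, b)
      stride <- if (s > 1 && b == 1) 2L else 1L
      cout <- plan$out[s]
      if (plan$kind == "basic") {
        P[[paste0(pre, "conv1")]] <- init_conv(3, 3, cin, cout)
        add_norm(paste0(pre, "gn1"), cout)
        P[[paste0(pre, "conv2")]] <- init_conv(3, 3, cout, cout)
        add_norm(paste0(pre, "gn2"), cout)
      } else {
        mid <- plan$mid[s]
        P[[paste0(pre, "conv1")]] <- init_conv(1, 1, cin, mid)
        add_norm(paste0(pre, "gn1"), mid)
        P[[paste0(pre, "conv2")]] <- init_conv(3, 3, mid, mid)
        add_norm(paste0(pre, "gn2"), mid)
        P[[paste0(pre, "conv3")]] <- init_conv(1, 1, mid, cout)
        add_norm(paste0(pre, "gn3"), cout)
      }
      if (stride != 1L || cin != cout) {
        P[[paste0(pre, "down.conv")]] <- init_conv(1, 1, cin, cout)
        add_norm(paste0(pre, "down.gn"), cout)
      }
      cin <- cout
    }
  }
  for (s in 2:5) {
    P[[sprintf("ffe.lat%d.W", s)]] <- init_conv(1, 1, plan$out[s - 1], cfg$c_fpn)
    P[[sprintf("ffe.lat%d.bias", s)]] <- zeros(cfg$c_fpn)
  }
  for (s in c(2, 3, 5)) {
    P[[sprintf("ffe.smooth%d.W", s)]] <- init_conv(3, 3, cfg$c_fpn, cfg$c_fpn)
    P[[sprintf("ffe.smooth%d.bias", s)]] <- zeros(cfg$c_fpn)
  }
  P
}

nobias <- function(C) zeros(C)

res_block <- function(x, P, pre, kind, stride) {
  gn <- function(h, nm) {
    ad_groupnorm2d(h, P[[paste0(pre, nm, ".g")]], P[[paste0(pre, nm, ".b")]])
  }
  cw <- function(nm) P[[paste0(pre, nm)]]
  if (kind == "basic") {
    h <- ad_conv2d(x, cw("conv1"), nobias(dim(vof(cw("conv1")))[4]),
                   stride = stride, pad = 1L)
    h <- ad_relu(gn(h, "gn1"))
    h <- ad_conv2d(h, cw("conv2"), nobias(dim(vof(cw("conv2")))[4]),
                   stride = 1L, pad = 1L)
    h <- gn(h, "gn2")
  } else {
    h <- ad_conv2d(x, cw("conv1"), nobias(dim(vof(cw("conv1")))[4]),
                   stride = 1L, pad = 0L)
    h <- ad_relu(gn(h, "gn1"))
    h <- ad_conv2d(h, cw("conv2"), nobias(dim(vof(cw("conv2")))[4]),
                   stride = stride, pad = 1L)
    h <- ad_relu(gn(h, "gn2"))
    h <- ad_conv2d(h, cw("conv3"), nobias(dim(vof(cw("conv3")))[4]),
                   stride = 1L, pad = 0L)
    h <- gn(h, "gn3")
  }
  skip <- x
  if (!is.null(P[[paste0(pre, "down.conv")]])) {
    skip <- ad_conv2d(x, cw("down.conv"),
                      nobias(dim(vof(cw("down.conv")))[4]),
                      stride = stride, pad = 0L)
    skip <- gn(skip, "down.gn")
  }
  ad_relu(ad_add(h, skip))
}

#' Run the ResNet+FPN fine-grained feature extractor
#'
#' @param x standardized raster H x W x 3 x N; H and W divisible by 32.
#' @param params model parameters.
#' @param cfg an [ffe_config()].
#' @param ... unused (kept for call compatibility).
#' @return a `feature_pyramid`: `P2`, `P3`, `P5` with `c_fpn` channels at
#'   strides 4, 8, 32. Normalization is per-sample (group norm), so the
#'   result for one image never depends on the rest of the batch.
#' @export
ffe_forward <- function(x, params, cfg, ...) {
  xv <- vof(x)
  if (length(dim(xv)) == 3) {
    if (is_ad(x)) stop("batch axis required for traced input")
    x <- array(xv, c(dim(xv), 1))
  }
  d <- dim(vof(x))
  if (d[1] %% 32 != 0 || d[2] %% 32 != 0)
    stop("input spatial size must be divisible by 32")
  plan <- resnet_plan(cfg)

  h <- ad_conv2d(x, params[["ffe.stem.conv"]], nobias(cfg$base_width),
                 stride = 2L, pad = 3L)
  h <- ad_groupnorm2d(h, params[["ffe.stem.gn.g"]], params[["ffe.stem.gn.b"]])
  h <- ad_relu(h)
  h <- ad_maxpool2d(h, k = 3L, stride = 2L, pad = 1L)

  C <- vector("list", 4)
  for (s in 1:4) {
    for (b in seq_len(plan$blocks[s])) {
      pre <- sprintf("ffe.s%db%d.", s, b)
      stride <- if (s > 1 && b == 1) 2L else 1L
      h <- res_block(h, params, pre, plan$kind, stride)
    }
    C[[s]] <- h
  }

  lat <- function(s, x) {
    ad_conv2d(x, params[[sprintf("ffe.lat%d.W", s)]],
              params[[sprintf("ffe.lat%d.bias", s)]], stride = 1L, pad = 0L)
  }
  M5 <- lat(5, C[[4]])
  M4 <- ad_add(lat(4, C[[3]]), ad_upsample_nearest2(M5))
  M3 <- ad_add(lat(3, C[[2]]), ad_upsample_nearest2(M4))
  M2 <- ad_add(lat(2, C[[1]]), ad_upsample_nearest2(M3))
  smooth <- function(s, x) {
    ad_conv2d(x, params[[sprintf("ffe.smooth%d.W", s)]],
              params[[sprintf("ffe.smooth%d.bias", s)]], stride = 1L, pad = 1L)
  }
  structure(list(P2 = smooth(2, M2), P3 = smooth(3, M3), P5 = smooth(5, M5),
                 c_fpn = cfg$c_fpn),
            class = "feature_pyramid")
}

#' Bring P3 and P5 to the P2 resolution
#'
#' P3 and P5 are bilinearly resized to the P2 spatial size; P2 passes
#' through; channel counts are unchanged.
#'
#' @param pyr a `feature_pyramid` from [ffe_forward()].
#' @return list of three rasters at the P2 resolution.
#' @export
upsample_to_p2 <- function(pyr) {
  stopifnot(inherits(pyr, "feature_pyramid"))
  d2 <- dim(vof(pyr$P2))
  list(P2 = pyr$P2,
       P3 = ad_bilinear_resize(pyr$P3, d2[1], d2[2]),
       P5 = ad_bilinear_resize(pyr$P5, d2[1], d2[2]))
}

fuse_proj_init <- function(embed_dim, c_fpn) {
  list("fuse.W" = init_trunc_normal(c(embed_dim, 3 * c_fpn)),
       "fuse.b" = zeros(3 * c_fpn))
}

#' Fuse fine-grained and global features
#'
#' The three P2-resolution pyramid maps are concatenated along channels
#' (3 c_fpn); the ViT patch tokens (global token excluded) are reshaped to
#' their grid, projected to 3 c_fpn channels with a 1x1 linear map,
#' bilinearly resized to the P2 grid, and combined with the pyramid stack
#' by elementwise addition, channel concatenation or elementwise
#' multiplication.
#'
#' @param ffe_maps list from [upsample_to_p2()].
#' @param gfe a `token_embeddings` from [gfe_forward()].
#' @param params model parameters (the 1x1 projection `fuse.W`/`fuse.b`).
#' @param method `"addition"`, `"concatenation"` or `"multiplication"`.
#' @return a `fused_feature_map` with `values` of channel width 3 c_fpn
#'   (addition/multiplication) or 6 c_fpn (concatenation) at the P2 size.
#' @export
fuse_features <- function(ffe_maps, gfe, params,
                          method = c("addition", "concatenation",
                                     "multiplication")) {
  if (is.character(method) && length(method) == 1 &&
      !method %in% c("addition", "concatenation", "multiplication"))
    stop("unknown fusion method: ", method)
  method <- match.arg(method)
  ffe_stack <- ad_concat_chan(ffe_maps)
  d <- dim(vof(ffe_stack))
  c3 <- d[3]

  toks <- gfe_patch_tokens(gfe)
  proj <- ad_addbias_rows(ad_matmul(toks, params[["fuse.W"]]),
                          params[["fuse.b"]])
  Hp <- gfe$grid[1]; Wp <- gfe$grid[2]; N <- gfe$N
  # token rows are (col fastest, row, sample); recover the spatial grid
  grid <- ad_reshape(proj, c(Wp, Hp, N, c3))
  grid <- ad_aperm(grid, c(2, 1, 4, 3))
  grid <- ad_bilinear_resize(grid, d[1], d[2])

  vals <- switch(method,
                 addition = ad_add(ffe_stack, grid),
                 multiplication = ad_mul(ffe_stack, grid),
                 concatenation = ad_concat_chan(list(ffe_stack, grid)))
  structure(list(values = vals, fusion_method = method, c_fpn = c3 %/% 3),
            class = "fused_feature_map")
}
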