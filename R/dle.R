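# Deep Learner (DLe): staged learned upsampling of the fused features via
# stride-2 transposed convolutions with rectifier nonlinearities (each stage
# exactly doubles the spatial side), optional convolutional block attention
# (CBAM) before the first or after the last stage, and a 1x1 segmentation
# head resized to image resolution for the saliency-segmentation objective.
# Same-resolution Conv2D and flattened-axis Conv1D stage designs are kept as
# ablation paths.

#' DLe configuration
#'
#' @param layer_kind `"transposed2d"` (default), `"conv2d"` or `"conv1d"`
#'   (1-D convolution over the flattened spatial axis; ablation only).
#' @param attention_position `"last"` (default), `"first"` or `"none"`.
#' @param n_stages number of refinement stages (>= 1).
#' @param kernel convolution kernel size (3).
#' @export
dle_config <- function(layer_kind = c("transposed2d", "conv2d", "conv1d"),
                       attention_position = c("last", "first", "none"),
                       n_stages = 2, kernel = 3) {
  if (is.character(layer_kind) && length(layer_kind) == 1 &&
      !layer_kind %in% c("transposed2d", "conv2d", "conv1d"))
    stop("unknown layer_kind: ", layer_kind)
  layer_kind <- match.arg(layer_kind)
  attention_position <- match.arg(attention_position)
  if (n_stages < 1) stop("n_stages must be >= 1")
  if (kernel != 3) stop("kernel must be 3")
  structure(list(layer_kind = layer_kind,
                 attention_position = attention_position,
                 n_stages = as.integer(n_stages), kernel = 3L),
            class = "dle_config")
}

# channel plan: halve per stage, floored at 32 (or at the input width if
# the input is already narrower)
dle_channels <- function(c_in, n_stages) {
  floor_c <- min(32L, c_in)
  ch <- integer(n_stages)
  c <- c_in
  for (s in seq_len(n_stages)) {
    c <- max(floor_c, c %/% 2L)
    ch[s] <- c
  }
  ch
}

cbam_init <- function(C, reduction = 16L, prefix = "cbam.") {
  hidden <- max(1L, C %/% reduction)
  P <- list()
  P[[paste0(prefix, "mlp.W1")]] <- init_linear(C, hidden)
  P[[paste0(prefix, "mlp.b1")]] <- zeros(hidden)
  P[[paste0(prefix, "mlp.W2")]] <- init_linear(hidden, C)
  P[[paste0(prefix, "mlp.b2")]] <- zeros(C)
  P[[paste0(prefix, "spatial.W")]] <- init_conv(7, 7, 2, 1)
  P[[paste0(prefix, "spatial.bias")]] <- zeros(1)
  P
}

dle_init <- function(c_in, cfg, image_channels_out = 1L, prefix = "dle.") {
  ch <- dle_channels(c_in, cfg$n_stages)
  P <- list()
  cin <- c_in
  for (s in seq_len(cfg$n_stages)) {
    nm <- sprintf("%sstage%d.", prefix, s)
    if (cfg$layer_kind == "transposed2d") {
      P[[paste0(nm, "W")]] <- init_deconv(3, 3, ch[s], cin)
    } else if (cfg$layer_kind == "conv2d") {
      P[[paste0(nm, "W")]] <- init_conv(3, 3, cin, ch[s])
    } else {
      P[[paste0(nm, "W")]] <- init_conv(3, 1, cin, ch[s])
    }
    P[[paste0(nm, "bias")]] <- zeros(ch[s])
    cin <- ch[s]
  }
  if (cfg$attention_position == "first") {
    P <- c(P, cbam_init(c_in, prefix = paste0(prefix, "cbam.")))
  } else if (cfg$attention_position == "last") {
    P <- c(P, cbam_init(ch[cfg$n_stages], prefix = paste0(prefix, "cbam.")))
  }
  P[[paste0(prefix, "seg.W")]] <- init_conv(1, 1, ch[cfg$n_stages],
                                            image_channels_out)
  P[[paste0(prefix, "seg.bias")]] <- zeros(image_channels_out)
  P
}

#' Convolutional Block Attention Module
#'
#' Channel attention (spatial average- and max-pooled descriptors through a
#' shared two-layer perceptron, summed and squashed to a (0,1) per-channel
#' gate) followed by spatial attention (channel-wise mean and max maps
#' through a 7x7 convolution squashed to a per-pixel gate).
#'
#' @param x H x W x C x N feature raster (array or tape node).
#' @param params parameters named `<prefix>mlp.W1/b1/W2/b2`,
#'   `<prefix>spatial.W/bias`.
#' @param prefix parameter-name prefix.
#' @param reduction channel-attention reduction ratio; `C >= reduction` is
#'   required.
#' @return raster of the same shape.
#' @export
cbam <- function(x, params, prefix = "cbam.", reduction = 16L) {
  C <- dim(vof(x))[3]
  if (C < reduction) stop("cbam needs at least ", reduction, " channels")
  mlp <- function(desc) { # desc: C x N
    h <- ad_relu(ad_addbias_rows(
      ad_matmul(ad_t(desc), params[[paste0(prefix, "mlp.W1")]]),
      params[[paste0(prefix, "mlp.b1")]]))
    ad_t(ad_addbias_rows(ad_matmul(h, params[[paste0(prefix, "mlp.W2")]]),
                         params[[paste0(prefix, "mlp.b2")]]))
  }
  gate_c <- ad_sigmoid(ad_add(mlp(ad_spatial_meanpool(x)),
                              mlp(ad_spatial_maxpool(x))))
  x1 <- ad_scale_chan(x, gate_c)
  smap <- ad_concat_chan(list(ad_chan_mean(x1), ad_chan_max(x1)))
  gate_s <- ad_sigmoid(ad_conv2d(smap, params[[paste0(prefix, "spatial.W")]],
                                 params[[paste0(prefix, "spatial.bias")]],
                                 stride = 1L, pad = 3L))
  ad_scale_spatial(x1, gate_s)
}

# zero-pad rows of an H x W x C x N raster (used by the conv1d stage)
ad_pad_rows <- function(x, p) {
  xv <- vof(x)
  d <- dim(xv)
  v <- array(0, c(d[1] + 2 * p, d[2], d[3], d[4]))
  v[p + seq_len(d[1]), , , ] <- xv
  if (!is_ad(x)) return(v)
  new_node(v, list(x), function(g) list(g[p + seq_len(d[1]), , , , drop = FALSE]))
}

#' Run the Deep Learner
#'
#' @param fused a `fused_feature_map` from [fuse_features()] (or a bare
#'   raster).
#' @param params model parameters from [init_msssl_model()].
#' @param cfg a [dle_config()].
#' @param image_size side of the full-resolution segmentation logits.
#' @param prefix parameter-name prefix.
#' @return a `deep_learner_output`: `features` (side x 2^n_stages for
#'   transposed2d, unchanged otherwise) and `seg_logits`
#'   (image_size x image_size x 1 x N).
#' @export
dle_forward <- function(fused, params, cfg, image_size, prefix = "dle.") {
  x <- if (inherits(fused, "fused_feature_map")) fused$values else fused
  if (cfg$attention_position == "first")
    x <- cbam(x, params, prefix = paste0(prefix, "cbam."))
  for (s in seq_len(cfg$n_stages)) {
    nm <- sprintf("%sstage%d.", prefix, s)
    W <- params[[paste0(nm, "W")]]
    b <- params[[paste0(nm, "bias")]]
    if (cfg$layer_kind == "transposed2d") {
      x <- ad_convt2d(x, W, b, stride = 2L, pad = 1L, outpad = 1L)
    } else if (cfg$layer_kind == "conv2d") {
      x <- ad_conv2d(x, W, b, stride = 1L, pad = 1L)
    } else if (cfg$layer_kind == "conv1d") {
      d <- dim(vof(x))
      x <- ad_reshape(x, c(d[1] * d[2], 1, d[3], d[4]))
      x <- ad_pad_rows(x, 1L)
      x <- ad_conv2d(x, W, b, stride = 1L, pad = 0L)
      x <- ad_reshape(x, c(d[1], d[2], dim(vof(W))[4], d[4]))
    } else stop("unknown layer_kind: ", cfg$layer_kind)
    x <- ad_relu(x)
  }
  if (cfg$attention_position == "last")
    x <- cbam(x, params, prefix = paste0(prefix, "cbam."))
  seg <- ad_conv2d(x, params[[paste0(prefix, "seg.W")]],
                   params[[paste0(prefix, "seg.bias")]],
                   stride = 1L, pad = 0L)
  seg <- ad_bilinear_resize(seg, image_size, image_size)
  structure(list(features = x, seg_logits = seg),
            class = "deep_learner_output")
}
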