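# SimCLR-style stochastic two-view augmentation. Each view independently
# applies random resized crop, horizontal flip, color jitter and Gaussian
# blur, then standardizes; geometric operations are replayed on the
# segmentation mask with the identical sampled parameters so mask and view
# stay aligned, while photometric operations skip the mask.

#' Augmentation configuration
#'
#' @param crop_size output side in pixels (>= 32).
#' @param flip_prob horizontal-flip probability.
#' @param jitter named strengths for brightness/contrast/saturation/hue
#'   (the SimCLR recipe at strength 1 is 0.4/0.4/0.4/0.1).
#' @param blur_kernels odd kernel sizes (>= 3) to draw from.
#' @param blur_prob per-view probability of applying the blur.
#' @param crop_scale sampled area fraction range. The lower bound is kept
#'   well above zero because fundus discs occupy the frame center and
#'   extreme crops would sample pure background.
#' @param crop_ratio aspect-ratio range.
#' @param mean,std per-channel standardization constants.
#' @param seed default stream seed.
#' @export
augment_config <- function(crop_size = 224,
                           flip_prob = 0.5,
                           jitter = c(brightness = 0.4, contrast = 0.4,
                                      saturation = 0.4, hue = 0.1),
                           blur_kernels = c(3, 5, 7, 9),
                           blur_prob = 0.5,
                           crop_scale = c(0.3, 1.0),
                           crop_ratio = c(3 / 4, 4 / 3),
                           mean = rep(0.5, 3),
                           std = rep(0.5, 3),
                           seed = 1) {
  if (crop_size < 32) stop("crop_size must be >= 32")
  if (flip_prob < 0 || flip_prob > 1) stop("flip_prob must be in [0, 1]")
  if (any(blur_kernels %% 2 != 1 | blur_kernels < 3))
    stop("blur kernels must be odd and >= 3")
  structure(list(crop_size = as.integer(crop_size), flip_prob = flip_prob,
                 jitter = jitter, blur_kernels = as.integer(blur_kernels),
                 blur_prob = blur_prob, crop_scale = crop_scale,
                 crop_ratio = crop_ratio, mean = mean, std = std,
                 seed = as.integer(seed)),
            class = "augment_config")
}

resize_bilinear_hwc <- function(x, oh, ow) {
  d <- dim(x)
  x4 <- array(x, c(d[1], d[2], d[3], 1))
  y <- resize_apply(x4, bilinear_matrix(oh, d[1]), bilinear_matrix(ow, d[2]))
  array(y, c(oh, ow, d[3]))
}

resize_nearest_mat <- function(m, oh, ow) {
  ih <- pmin(pmax(ceiling((seq_len(oh) - 0.5) * nrow(m) / oh), 1), nrow(m))
  iw <- pmin(pmax(ceiling((seq_len(ow) - 0.5) * ncol(m) / ow), 1), ncol(m))
  m[ih, iw, drop = FALSE]
}

gaussian_blur_hwc <- function(x, k, sigma) {
  kern <- gaussian_kernel(k, sigma)
  for (c in seq_len(dim(x)[3])) x[, , c] <- filter_replicate(x[, , c], kern)
  x
}

# sample a random-resized-crop window for an H x W frame
sample_crop <- function(H, W, scale, ratio) {
  for (i in 1:10) {
    area <- stats::runif(1, scale[1], scale[2]) * H * W
    r <- exp(stats::runif(1, log(ratio[1]), log(ratio[2])))
    cw <- round(sqrt(area * r))
    ch <- round(sqrt(area / r))
    if (ch >= 1 && cw >= 1 && ch <= H && cw <= W) {
      y0 <- sample.int(H - ch + 1, 1)
      x0 <- sample.int(W - cw + 1, 1)
      return(c(y0 = y0, x0 = x0, h = ch, w = cw))
    }
  }
  c(y0 = 1, x0 = 1, h = H, w = W) # fallback: full frame
}

# hue rotation as a linear map in YIQ space; x is H x W x 3 in [0, 1]
rotate_hue <- function(x, turns) {
  th <- 2 * pi * turns
  toYIQ <- matrix(c(0.299, 0.587, 0.114,
                    0.596, -0.274, -0.322,
                    0.211, -0.523, 0.312), 3, 3, byrow = TRUE)
  rot <- diag(3)
  rot[2:3, 2:3] <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  M <- solve(toYIQ) %*% rot %*% toYIQ
  d <- dim(x)
  y <- matrix(x, ncol = 3) %*% t(M)
  clamp(array(y, d), 0, 1)
}

apply_jitter <- function(x, js) {
  # js: sampled factors (brightness, contrast, saturation multipliers in
  # [1 - s, 1 + s]; hue shift in turns); applied in a sampled order is the
  # SimCLR recipe, a fixed order keeps replay simple and is noted as such
  x <- clamp(x * js["brightness"], 0, 1)
  mg <- mean(0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3])
  x <- clamp((x - mg) * js["contrast"] + mg, 0, 1)
  gray <- 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
  for (c in 1:3) x[, , c] <- gray + (x[, , c] - gray) * js["saturation"]
  x <- clamp(x, 0, 1)
  if (abs(js["hue"]) > 0) x <- rotate_hue(x, js["hue"])
  x
}

augment_one_view <- function(img, mask, cfg) {
  d <- dim(img)
  crop <- sample_crop(d[1], d[2], cfg$crop_scale, cfg$crop_ratio)
  flip <- stats::runif(1) < cfg$flip_prob
  js <- c(brightness = stats::runif(1, 1 - cfg$jitter["brightness"],
                                    1 + cfg$jitter["brightness"]),
          contrast = stats::runif(1, 1 - cfg$jitter["contrast"],
                                  1 + cfg$jitter["contrast"]),
          saturation = stats::runif(1, 1 - cfg$jitter["saturation"],
                                    1 + cfg$jitter["saturation"]),
          hue = stats::runif(1, -cfg$jitter["hue"], cfg$jitter["hue"]))
  names(js) <- c("brightness", "contrast", "saturation", "hue")
  do_blur <- stats::runif(1) < cfg$blur_prob
  bk <- cfg$blur_kernels[sample.int(length(cfg$blur_kernels), 1)]
  bsig <- stats::runif(1, 0.1, 2)

  ys <- crop["y0"]:(crop["y0"] + crop["h"] - 1)
  xs <- crop["x0"]:(crop["x0"] + crop["w"] - 1)
  v <- img[ys, xs, , drop = FALSE]
  v <- resize_bilinear_hwc(v, cfg$crop_size, cfg$crop_size)
  if (flip) v <- v[, rev(seq_len(dim(v)[2])), , drop = FALSE]
  v <- apply_jitter(v, js)
  if (do_blur) v <- gaussian_blur_hwc(v, bk, bsig)
  for (c in 1:3) v[, , c] <- (v[, , c] - cfg$mean[c]) / cfg$std[c]

  m <- NULL
  if (!is.null(mask)) {
    m <- mask[ys, xs, drop = FALSE]
    m <- resize_nearest_mat(m, cfg$crop_size, cfg$crop_size)
    if (flip) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  }
  list(view = v, mask = m,
       params = list(crop = crop, flip = flip, jitter = js,
                     blur = if (do_blur) c(k = bk, sigma = bsig) else NULL))
}

#' Make a two-view augmented pair
#'
#' @param img H x W x 3 array in [0, 1] (for a green-channel pipeline, the
#'   [0, 1]-scaled replicated green plane; standardization is the final
#'   step of each view).
#' @param mask optional [binary_mask()] (or bare H x W matrix) aligned with
#'   `img`; transformed with each view's geometric parameters.
#' @param cfg an [augment_config()].
#' @param rng optional [msssl_rng()] stream (defaults to `cfg$seed`).
#' @param source_id identifier shared by both views.
#' @return an `augmented_view_pair`: `view_a`/`view_b`
#'   (crop_size x crop_size x 3, standardized), `mask_a`/`mask_b`,
#'   `source_id`, and the sampled `params_a`/`params_b`.
#' @export
make_view_pair <- function(img, mask = NULL, cfg, rng = NULL,
                           source_id = "img") {
  stopifnot(inherits(cfg, "augment_config"))
  if (inherits(mask, "binary_mask")) mask <- mask$values
  if (!is.null(mask) && !identical(dim(mask), dim(img)[1:2]))
    stop("mask shape does not match image")
  rng <- rng %||% msssl_rng(cfg$seed)
  with_rng(rng, {
    a <- augment_one_view(img, mask, cfg)
    b <- augment_one_view(img, mask, cfg)
    structure(list(view_a = a$view, view_b = b$view,
                   mask_a = a$mask, mask_b = b$mask,
                   source_id = source_id,
                   params_a = a$params, params_b = b$params),
              class = "augmented_view_pair")
  })
}
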