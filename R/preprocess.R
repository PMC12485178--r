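# Fundus preprocessing: green-channel extraction (highest lesion/vessel
# contrast in color fundus photographs), black-border cropping, saliency
# detection on the green plane, Otsu binarization of the saliency map (the
# segmentation ground truth used by the pretraining objective), and
# normalization to a model-ready raster.

#' Green-channel image container
#' @param pixels H x W integer raster in 0..255.
#' @param id identifier.
#' @export
green_channel_image <- function(pixels, id = "img") {
  stopifnot(length(dim(pixels)) == 2)
  if (any(pixels < 0 | pixels > 255)) stop("values must be in [0, 255]")
  structure(list(pixels = pixels, id = as.character(id)),
            class = "green_channel_image")
}

#' Saliency map container
#' @param values H x W raster in [0, 1].
#' @param method `"spectral"` or `"fine_grained"`.
#' @export
saliency_map <- function(values, method) {
  stopifnot(length(dim(values)) == 2)
  if (!method %in% c("spectral", "fine_grained")) stop("unknown saliency method")
  if (any(values < 0 | values > 1)) stop("saliency values must be in [0, 1]")
  structure(list(values = values, method = method), class = "saliency_map")
}

#' Binary mask container
#' @param values H x W raster with values in \{0, 1\}.
#' @export
binary_mask <- function(values) {
  stopifnot(length(dim(values)) == 2)
  if (!all(values %in% c(0, 1))) stop("mask values must be 0 or 1")
  structure(list(values = values), class = "binary_mask")
}

#' Extract the green color plane
#'
#' The green channel of an RGB fundus photograph carries the highest
#' contrast for retinal lesions and vessels and is the plane the whole
#' pretraining pipeline operates on.
#'
#' @param img a [fundus_image()] (or bare H x W x 3 array).
#' @return a [green_channel_image()].
#' @export
extract_green_channel <- function(img) {
  px <- if (inherits(img, "fundus_image")) img$pixels else img
  if (length(dim(px)) != 3 || dim(px)[3] != 3)
    stop("input must have exactly 3 color channels")
  green_channel_image(px[, , 2],
                      id = if (inherits(img, "fundus_image")) img$id else "img")
}

#' Crop away dark borders
#'
#' Returns the tight bounding-box crop of all pixels whose maximum channel
#' value exceeds `intensity_threshold`.
#'
#' @param img a [fundus_image()].
#' @param intensity_threshold integer in 0..255 (default 10, robust to
#'   compression noise on nominally black borders).
#' @return a cropped [fundus_image()].
#' @export
crop_black_borders <- function(img, intensity_threshold = 10) {
  stopifnot(inherits(img, "fundus_image"),
            intensity_threshold >= 0, intensity_threshold <= 255)
  mx <- pmax(img$pixels[, , 1], img$pixels[, , 2], img$pixels[, , 3])
  fg <- mx > intensity_threshold
  if (!any(fg)) stop("empty foreground")
  rows <- range(which(apply(fg, 1, any)))
  cols <- range(which(apply(fg, 2, any)))
  fundus_image(img$pixels[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE],
               img$id, img$grade, img$view)
}

# replicate-pad a matrix by p on each side
pad_replicate <- function(m, p) {
  ri <- c(rep(1, p), seq_len(nrow(m)), rep(nrow(m), p))
  ci <- c(rep(1, p), seq_len(ncol(m)), rep(ncol(m), p))
  m[ri, ci]
}

# valid 2-D correlation of a replicate-padded matrix with a small kernel
filter_replicate <- function(m, kern) {
  p <- (nrow(kern) - 1) %/% 2
  mp <- pad_replicate(m, p)
  x <- array(mp, c(dim(mp), 1, 1))
  w <- array(kern, c(dim(kern), 1, 1))
  y <- conv2d_fw_cpp(x, w, 0, 1L, 0L)
  matrix(y, nrow(m), ncol(m))
}

gaussian_kernel <- function(k, sigma) {
  h <- (k - 1) / 2
  g <- exp(-((-h):h)^2 / (2 * sigma^2))
  g <- g / sum(g)
  outer(g, g)
}

minmax_norm <- function(v) {
  r <- range(v)
  if (r[2] - r[1] < 1e-12) return(v * 0)
  (v - r[1]) / (r[2] - r[1])
}

#' Spectral-residual saliency
#'
#' Fourier-domain conspicuity: the log-amplitude spectrum minus its 3x3
#' mean-filtered version (the spectral residual) is recombined with the
#' original phase, inverse-transformed, squared, Gaussian-smoothed and
#' min-max normalized to [0, 1]. Constant inputs map to an all-zero map.
#'
#' @param img a [green_channel_image()].
#' @return a [saliency_map()] with method `"spectral"`.
#' @export
spectral_saliency <- function(img) {
  stopifnot(inherits(img, "green_channel_image"))
  g <- img$pixels / 255
  if (diff(range(g)) < 1e-12)
    return(saliency_map(g * 0, "spectral"))
  F <- stats::fft(g)
  amp <- Mod(F)
  phase <- Arg(F)
  logamp <- log(amp + 1e-12)
  resid <- logamp - filter_replicate(logamp, matrix(1 / 9, 3, 3))
  spec <- matrix(complex(modulus = as.vector(exp(resid)),
                         argument = as.vector(phase)), nrow(g))
  rec <- stats::fft(spec, inverse = TRUE) / length(g)
  sal <- Mod(rec)^2
  sal <- filter_replicate(sal, gaussian_kernel(9, 2.5))
  saliency_map(minmax_norm(sal), "spectral")
}

# clamped-window box mean via integral image (windows shrink at borders)
box_mean <- function(m, r) {
  H <- nrow(m); W <- ncol(m)
  S <- matrix(0, H + 1, W + 1)
  S[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  y0 <- pmax(seq_len(H) - r, 1); y1 <- pmin(seq_len(H) + r, H)
  x0 <- pmax(seq_len(W) - r, 1); x1 <- pmin(seq_len(W) + r, W)
  sums <- S[y1 + 1, x1 + 1, drop = FALSE] - S[y0, x1 + 1, drop = FALSE] -
    S[y1 + 1, x0, drop = FALSE] + S[y0, x0, drop = FALSE]
  counts <- outer(y1 - y0 + 1, x1 - x0 + 1)
  sums / counts
}

#' Fine-grained saliency
#'
#' Center--surround contrast: the absolute difference between each pixel and
#' box-filtered surrounds at several window radii, summed over radii and
#' min-max normalized. This is the default saliency detector.
#'
#' @param img a [green_channel_image()].
#' @param radii surround window radii in pixels.
#' @return a [saliency_map()] with method `"fine_grained"`.
#' @export
fine_grained_saliency <- function(img, radii = c(3, 7, 15)) {
  stopifnot(inherits(img, "green_channel_image"))
  g <- img$pixels / 255
  if (diff(range(g)) < 1e-12)
    return(saliency_map(g * 0, "fine_grained"))
  sal <- matrix(0, nrow(g), ncol(g))
  for (r in radii) sal <- sal + abs(g - box_mean(g, r))
  saliency_map(minmax_norm(sal), "fine_grained")
}

#' Compute saliency by method name
#' @param img a [green_channel_image()].
#' @param method `"fine_grained"` (default) or `"spectral"`.
#' @export
compute_saliency <- function(img, method = c("fine_grained", "spectral")) {
  method <- match.arg(method)
  if (method == "spectral") spectral_saliency(img) else fine_grained_saliency(img)
}

#' Otsu threshold over a 256-bin histogram
#'
#' Scans all 256 bin cut-points of the histogram of a [0, 1] raster and
#' returns the threshold value maximizing the between-class variance.
#'
#' @param values numeric values in [0, 1].
#' @return the threshold in [0, 1]: `(t* + 1)/255` for the best cut bin
#'   `t*`; values `>=` the threshold are foreground.
#' @export
otsu_threshold <- function(values) {
  b <- pmin(floor(as.vector(values) * 255), 255)
  counts <- tabulate(b + 1L, nbins = 256L)
  n <- sum(counts)
  p <- counts / n
  levels <- (0:255) / 255
  w0 <- cumsum(p)
  mu <- cumsum(p * levels)
  mu_t <- mu[256]
  w0c <- w0[1:255]
  between <- (mu_t * w0c - mu[1:255])^2 / (w0c * (1 - w0c))
  between[!is.finite(between)] <- -Inf
  tstar <- which.max(between) - 1L
  (tstar + 1) / 255
}

#' Binarize a saliency map with Otsu's method
#'
#' @param map a [saliency_map()].
#' @return a [binary_mask()]; a constant map yields an all-zero mask.
#' @export
binarize_saliency <- function(map) {
  stopifnot(inherits(map, "saliency_map"))
  v <- map$values
  if (diff(range(v)) < 1e-12)
    return(binary_mask(v * 0))
  thr <- otsu_threshold(v)
  binary_mask((v >= thr) * 1)
}

#' Normalize a green-channel image to a model-ready raster
#'
#' Replicates the green plane to three identical channels (so standard
#' 3-channel backbones apply unchanged), scales to [0, 1] and standardizes
#' each channel with the configured mean and standard deviation.
#'
#' @param img a [green_channel_image()].
#' @param mean,std per-channel standardization constants.
#' @return H x W x 3 numeric array.
#' @export
normalize_for_model <- function(img, mean = 0.5, std = 0.5) {
  stopifnot(inherits(img, "green_channel_image"))
  g <- img$pixels / 255
  x <- array(g, c(dim(g), 3))
  mean <- rep(mean, length.out = 3)
  std <- rep(std, length.out = 3)
  for (c in 1:3) x[, , c] <- (x[, , c] - mean[c]) / std[c]
  x
}
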