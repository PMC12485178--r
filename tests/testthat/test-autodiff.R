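# The reverse-mode engine is validated against central differences: every
# layer type used by the encoder and Deep Learner must reproduce the
# numerical gradient on small random tensors.

test_that("elementwise and matrix ops match numerical gradients", {
  set.seed(1)
  xm <- matrix(rnorm(35), 5, 7)
  mm <- matrix(rnorm(35), 5, 7)
  expect_grad(function(z) ns$ad_sum(ns$ad_mul(ns$ad_softmax_rows(z), mm)), xm)
  expect_grad(function(z) ns$ad_sum(ns$ad_mul(ns$ad_logsoftmax_rows(z), mm)), xm)
  expect_grad(function(z) ns$ad_sum(ns$ad_mul(ns$ad_gelu(z), mm)), xm)
  expect_grad(function(z) ns$ad_sum(ns$ad_mul(ns$ad_softplus(z), mm)), xm)
  expect_grad(function(z) ns$ad_sum(ns$ad_mul(ns$ad_sigmoid(z), mm)), xm)
  gg <- rnorm(7); bb <- rnorm(7)
  expect_grad(function(z)
    ns$ad_sum(ns$ad_mul(ns$ad_layernorm_rows(z, gg, bb), mm)), xm)
  W <- matrix(rnorm(21), 7, 3)
  m2 <- matrix(rnorm(15), 5, 3)
  expect_grad(function(z) ns$ad_sum(ns$ad_mul(ns$ad_matmul(z, W), m2)), xm)
  expect_grad(function(z)
    ns$ad_sum(ns$ad_mul(ns$ad_slice_rows(z, c(2, 4)), mm[c(2, 4), ])), xm)
})

test_that("convolution layers match numerical gradients", {
  set.seed(2)
  x4 <- array(rnorm(6 * 6 * 4 * 2), c(6, 6, 4, 2))
  w <- array(rnorm(3 * 3 * 4 * 5), c(3, 3, 4, 5))
  b <- rnorm(5)
  mA <- array(rnorm(6 * 6 * 5 * 2), c(6, 6, 5, 2))
  expect_grad(function(z)
    ns$ad_sum(ns$ad_mul(ns$ad_conv2d(z, w, b, 1, 1), mA)), x4)
  m3 <- array(rnorm(3 * 3 * 5 * 2), c(3, 3, 5, 2))
  expect_grad(function(z)
    ns$ad_sum(ns$ad_mul(ns$ad_conv2d(z, w, b, 2, 1), m3)), x4)
  # conv weight and bias gradients
  lw <- ns$ad_leaf(w)
  out <- ns$ad_sum(ns$ad_mul(ns$ad_conv2d(x4, lw, b, 1, 1), mA))
  ns$ad_backward(out)
  gn <- num_grad(function(z) sum(ns$vof(ns$ad_conv2d(x4, z, b, 1, 1)) * mA), w)
  expect_lt(max(abs(lw$grad - gn)), 1e-6)
  # transposed conv: gradients and the exact doubling law
  wt <- array(rnorm(3 * 3 * 5 * 4), c(3, 3, 5, 4))
  bt <- rnorm(5)
  y <- ns$ad_convt2d(x4, wt, bt, 2, 1, 1)
  expect_identical(dim(y)[1:2], c(12L, 12L))
  mt <- array(rnorm(12 * 12 * 5 * 2), c(12, 12, 5, 2))
  expect_grad(function(z)
    ns$ad_sum(ns$ad_mul(ns$ad_convt2d(z, wt, bt, 2, 1, 1), mt)), x4)
  lwt <- ns$ad_leaf(wt)
  out <- ns$ad_sum(ns$ad_mul(ns$ad_convt2d(x4, lwt, bt, 2, 1, 1), mt))
  ns$ad_backward(out)
  gnt <- num_grad(function(z)
    sum(ns$vof(ns$ad_convt2d(x4, z, bt, 2, 1, 1)) * mt), wt)
  expect_lt(max(abs(lwt$grad - gnt)), 1e-6)
})

test_that("pooling and normalization layers match numerical gradients", {
  set.seed(3)
  x4 <- array(rnorm(6 * 6 * 8 * 2), c(6, 6, 8, 2))
  mp <- array(rnorm(3 * 3 * 8 * 2), c(3, 3, 8, 2))
  expect_grad(function(z) ns$ad_sum(ns$ad_mul(ns$ad_maxpool2d(z), mp)), x4)
  g8 <- rnorm(8); b8 <- rnorm(8)
  mm <- array(rnorm(6 * 6 * 8 * 2), c(6, 6, 8, 2))
  expect_grad(function(z)
    ns$ad_sum(ns$ad_mul(ns$ad_groupnorm2d(z, g8, b8), mm)), x4, tol = 1e-5)
  expect_grad(function(z) {
    buf <- new.env()
    ns$ad_sum(ns$ad_mul(ns$ad_batchnorm2d(z, g8, b8, buf, "t", TRUE), mm))
  }, x4, tol = 1e-5)
})

test_that("bilinear resize matches the closed-form interpolation weights", {
  # half-pixel centers: output center i maps to source coordinate
  # (i - 0.5) * n_in / n_out - 0.5 (0-based), so upsampling 2 -> 4 uses
  # weights (1,0), (3/4,1/4), (1/4,3/4), (0,1) along each axis
  r <- c(1, 2)
  x <- array(outer(r, r, `+`), c(2, 2, 1, 1)) # ramp 2,3;3,4
  y <- ns$ad_bilinear_resize(x, 4, 4)
  Rh <- rbind(c(1, 0), c(0.75, 0.25), c(0.25, 0.75), c(0, 1))
  expected <- Rh %*% x[, , 1, 1] %*% t(Rh)
  expect_equal(y[, , 1, 1], expected, tolerance = 1e-12)
  # constant field stays constant at any size
  cst <- array(3.7, c(2, 2, 1, 1))
  expect_equal(ns$ad_bilinear_resize(cst, 7, 5)[, , 1, 1],
               matrix(3.7, 7, 5), tolerance = 1e-12)
  # gradient is the transpose of the interpolation operator
  set.seed(4)
  x4 <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  mb <- array(rnorm(7 * 5 * 2 * 2), c(7, 5, 2, 2))
  expect_grad(function(z)
    ns$ad_sum(ns$ad_mul(ns$ad_bilinear_resize(z, 7, 5), mb)), x4)
})

test_that("channel and spatial broadcast ops match numerical gradients", {
  set.seed(5)
  x4 <- array(rnorm(5 * 5 * 6 * 2), c(5, 5, 6, 2))
  s <- matrix(rnorm(12), 6, 2)
  expect_grad(function(z) ns$ad_sum(ns$ad_mul(ns$ad_scale_chan(z, s), x4)), x4)
  expect_grad(function(z) ns$ad_sum(ns$ad_mul(ns$ad_spatial_meanpool(z), s)), x4)
  expect_grad(function(z) ns$ad_sum(ns$ad_mul(ns$ad_spatial_maxpool(z), s)), x4)
  mc <- array(rnorm(5 * 5 * 2), c(5, 5, 1, 2))
  expect_grad(function(z) ns$ad_sum(ns$ad_mul(ns$ad_chan_mean(z), mc)), x4)
  expect_grad(function(z) ns$ad_sum(ns$ad_mul(ns$ad_chan_max(z), mc)), x4)
  ss <- array(rnorm(5 * 5 * 2), c(5, 5, 1, 2))
  expect_grad(function(z) ns$ad_sum(ns$ad_mul(ns$ad_scale_spatial(z, ss), x4)), x4)
  ls <- ns$ad_leaf(ss)
  out <- ns$ad_sum(ns$ad_mul(ns$ad_scale_spatial(x4, ls), x4))
  ns$ad_backward(out)
  gn <- num_grad(function(z) sum(ns$vof(ns$ad_scale_spatial(x4, z)) * x4), ss)
  expect_lt(max(abs(ls$grad - gn)), 1e-6)
})

test_that("gradients accumulate across shared uses of one parameter", {
  set.seed(6)
  W <- matrix(rnorm(9), 3, 3)
  x <- matrix(rnorm(9), 3, 3)
  lw <- ns$ad_leaf(W)
  # W used twice: y = x W + (x W) W
  y1 <- ns$ad_matmul(x, lw)
  out <- ns$ad_sum(ns$ad_add(y1, ns$ad_matmul(y1, lw)))
  ns$ad_backward(out)
  gn <- num_grad(function(z) sum(x %*% z + (x %*% z) %*% z), W)
  expect_lt(max(abs(lw$grad - gn)), 1e-6)
})
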