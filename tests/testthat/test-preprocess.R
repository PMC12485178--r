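# Preprocessing: green extraction, border cropping, both saliency
# detectors, Otsu binarization against a brute-force oracle, and
# model-ready normalization.

test_that("green channel extraction selects exactly the second plane", {
  px <- array(0, c(4, 4, 3))
  px[, , 1] <- 10; px[, , 2] <- 200; px[, , 3] <- 30
  img <- fundus_image(px, "flat")
  expect_true(all(extract_green_channel(img)$pixels == 200))

  expect_true(all(extract_green_channel(fundus_image(array(0, c(3, 3, 3)),
                                                     "z"))$pixels == 0))
  set.seed(1)
  rnd <- array(sample(0:255, 8 * 8 * 3, replace = TRUE), c(8, 8, 3))
  g <- extract_green_channel(fundus_image(rnd, "r"))$pixels
  # brute-force per-pixel slice oracle
  for (i in 1:8) for (j in 1:8) expect_identical(g[i, j], rnd[i, j, 2])
  expect_error(extract_green_channel(array(0, c(4, 4, 2))), "3 color channels")
})

test_that("border cropping returns the tight foreground bounding box", {
  full <- fundus_image(array(200, c(10, 10, 3)), "full")
  expect_identical(dim(crop_black_borders(full, 10)$pixels), c(10L, 10L, 3L))

  frame <- array(0, c(200, 200, 3))
  frame[81:120, 81:120, ] <- 150
  img <- fundus_image(frame, "sq")
  cropped <- crop_black_borders(img, 10)
  expect_lte(abs(dim(cropped$pixels)[1] - 40), 1)
  expect_lte(abs(dim(cropped$pixels)[2] - 40), 1)
  # brute-force bounding-box oracle
  fg <- which(apply(frame, c(1, 2), max) > 10, arr.ind = TRUE)
  expect_identical(dim(cropped$pixels)[1], diff(range(fg[, 1])) + 1L)

  # idempotence
  twice <- crop_black_borders(cropped, 10)
  expect_identical(cropped$pixels, twice$pixels)

  expect_error(crop_black_borders(fundus_image(array(0, c(5, 5, 3)), "b"), 10),
               "empty foreground")
})

test_that("spectral saliency localizes an isolated bright pixel", {
  flat <- green_channel_image(matrix(128, 32, 32))
  expect_true(all(spectral_saliency(flat)$values == 0))

  g <- matrix(0, 64, 64)
  g[20, 45] <- 255
  sal <- spectral_saliency(green_channel_image(g))
  expect_equal(range(sal$values), c(0, 1))
  am <- which(sal$values == max(sal$values), arr.ind = TRUE)[1, ]
  expect_lte(abs(am[1] - 20), 2)
  expect_lte(abs(am[2] - 45), 2)
  expect_identical(sal$method, "spectral")
})

test_that("fine-grained saliency peaks at contrast and normalizes to [0,1]", {
  flat <- green_channel_image(matrix(77, 32, 32))
  expect_true(all(fine_grained_saliency(flat)$values == 0))

  step <- matrix(0, 48, 48)
  step[, 25:48] <- 255
  sal <- fine_grained_saliency(green_channel_image(step))
  expect_equal(range(sal$values), c(0, 1))
  # strongest response in the columns adjacent to the edge, decaying away
  colmax <- apply(sal$values, 2, max)
  expect_true(which.max(colmax) %in% 23:26)
  expect_gt(mean(sal$values[, 23:26]), mean(sal$values[, c(1:8, 41:48)]))
  expect_identical(sal$method, "fine_grained")
})

test_that("both saliency methods are translation-covariant on point sources", {
  base <- matrix(0, 64, 64)
  for (method in c("spectral", "fine_grained")) {
    g1 <- base; g1[25, 30] <- 255
    g2 <- base; g2[28, 35] <- 255 # shifted by (3, 5)
    s1 <- compute_saliency(green_channel_image(g1), method)$values
    s2 <- compute_saliency(green_channel_image(g2), method)$values
    a1 <- which(s1 == max(s1), arr.ind = TRUE)[1, ]
    a2 <- which(s2 == max(s2), arr.ind = TRUE)[1, ]
    expect_lte(abs((a2[1] - a1[1]) - 3), 2)
    expect_lte(abs((a2[2] - a1[2]) - 5), 2)
  }
})

# exhaustive between-class-variance maximization over all 256 bin cuts
otsu_oracle <- function(v) {
  b <- pmin(floor(v * 255), 255)
  counts <- tabulate(b + 1L, nbins = 256L)
  p <- counts / sum(counts)
  lev <- (0:255) / 255
  best <- -Inf; tbest <- 0L
  for (t in 0:254) {
    w0 <- sum(p[1:(t + 1)])
    w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    mu0 <- sum(p[1:(t + 1)] * lev[1:(t + 1)]) / w0
    mu1 <- sum(p[(t + 2):256] * lev[(t + 2):256]) / w1
    bc <- w0 * w1 * (mu0 - mu1)^2
    if (bc > best) { best <- bc; tbest <- t }
  }
  (tbest + 1) / 255
}

test_that("Otsu threshold equals the exhaustive 256-cut oracle", {
  # perfectly bimodal map: the mask is exactly the high set
  v <- matrix(rep(c(0, 1), each = 32), 8, 8)
  mask <- binarize_saliency(saliency_map(v, "spectral"))
  expect_identical(mask$values, (v == 1) * 1)

  # degenerate constant map
  expect_true(all(binarize_saliency(saliency_map(matrix(0.5, 6, 6),
                                                 "spectral"))$values == 0))

  set.seed(42)
  for (i in 1:100) {
    v <- matrix(stats::runif(16 * 16), 16, 16)
    if (i %% 3 == 0) v <- matrix(sample(seq(0, 1, by = 1 / 16), 256,
                                        replace = TRUE), 16, 16)
    expect_equal(otsu_threshold(v), otsu_oracle(v), tolerance = 1e-12)
  }
})

test_that("Otsu mask is invariant under bin-preserving affine rescaling", {
  set.seed(8)
  for (i in 1:20) {
    # coarse 1/16-grid levels so a gentle affine map never merges bins
    v <- matrix(sample(seq(0, 1, by = 1 / 16), 144, replace = TRUE), 12, 12)
    b <- stats::runif(1, 0.85, 1)
    a <- stats::runif(1, 0, 1 - b)
    v2 <- a + b * v
    m1 <- binarize_saliency(saliency_map(v, "spectral"))$values
    m2 <- binarize_saliency(saliency_map(v2, "spectral"))$values
    expect_identical(m1, m2)
  }
})

test_that("model normalization replicates the green plane and standardizes", {
  z <- green_channel_image(matrix(0, 5, 5))
  expect_true(all(normalize_for_model(z, 0.5, 0.5) == -1))
  o <- green_channel_image(matrix(255, 5, 5))
  expect_true(all(normalize_for_model(o, 0.5, 0.5) == 1))
  set.seed(3)
  r <- green_channel_image(matrix(sample(0:255, 25, TRUE), 5, 5))
  out <- normalize_for_model(r)
  expect_identical(out[, , 1], out[, , 2])
  expect_identical(out[, , 2], out[, , 3])
})
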