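# Multi-scale feature extraction encoder: patchify arithmetic, the ViT
# global branch, the ResNet+FPN fine-grained branch, and fusion.

test_that("patchify produces the documented token grids and inverts", {
  x <- array(stats::runif(1024 * 1024 * 3), c(1024, 1024, 3))
  toks <- patchify(x, 16)
  expect_equal(nrow(toks), 4096)
  expect_equal(attr(toks, "grid"), c(64, 64))

  x2 <- array(stats::runif(224 * 224 * 3), c(224, 224, 3))
  expect_equal(nrow(patchify(x2, 32)), 49)

  set.seed(1)
  x3 <- array(stats::runif(32 * 32 * 3), c(32, 32, 3))
  rt <- unpatchify(patchify(x3, 16), 16, 32, 32, 3)
  expect_equal(rt, x3, tolerance = 1e-12)

  expect_error(patchify(array(0, c(30, 30, 3)), 16), "divisible")
})

test_that("ViT forward: attention is row-stochastic with the right shapes", {
  cfg <- vit_config("S", 16, input_size = 224, embed_dim = 32, depth = 1,
                    heads = 2, proj_hidden = 64, proj_dim = 16)
  set_global_determinism(5)
  P <- msssl:::gfe_init(cfg)
  x <- array(stats::rnorm(224 * 224 * 3), c(224, 224, 3, 1))
  emb <- gfe_forward(x, P, cfg, collect_attention = TRUE)
  expect_equal(emb$T, 197) # 196 patches + global token
  expect_identical(dim(emb$attention), c(1L, 2L, 197L, 197L, 1L))
  for (h in 1:2)
    expect_equal(rowSums(emb$attention[1, h, , , 1]), rep(1, 197),
                 tolerance = 1e-5)
  # deterministic: same weights, same input, bitwise-stable output
  emb2 <- gfe_forward(x, P, cfg)
  expect_identical(msssl:::vof(emb$tokens), msssl:::vof(emb2$tokens))
})

test_that("projection head obeys zero, shape and hand-computed oracles", {
  cfg <- vit_config("S", 16, input_size = 64, embed_dim = 2, depth = 1,
                    heads = 1, proj_hidden = 2, proj_dim = 2)
  P <- list("proj.W1" = matrix(0, 2, 2), "proj.b1" = c(0, 0),
            "proj.W2" = matrix(0, 2, 2), "proj.b2" = c(0, 0),
            "proj.W3" = matrix(0, 2, 2), "proj.b3" = c(0, 0))
  expect_true(all(projection_head(matrix(1, 3, 2), P, cfg) == 0))

  cfg256 <- vit_config("S", 16, input_size = 64, embed_dim = 8, depth = 1,
                       heads = 2, proj_hidden = 16, proj_dim = 256)
  set_global_determinism(2)
  P2 <- msssl:::gfe_init(cfg256)
  out <- projection_head(matrix(stats::rnorm(16), 2, 8), P2, cfg256)
  expect_identical(ncol(out), 256L)

  # hand-set 2x2 case followed through the exact layer formulas
  W1 <- matrix(c(1, 2, 3, 4), 2, 2); b1 <- c(0.5, -0.5)
  W2 <- diag(2); b2 <- c(0, 0)
  W3 <- matrix(c(2, 0, 0, 2), 2, 2); b3 <- c(1, 1)
  P3 <- list("proj.W1" = W1, "proj.b1" = b1, "proj.W2" = W2, "proj.b2" = b2,
             "proj.W3" = W3, "proj.b3" = b3)
  xin <- matrix(c(0.3, -0.7), 1, 2)
  gelu <- function(z) z * stats::pnorm(z)
  manual <- gelu(gelu(xin %*% W1 + rep(1, 1) %o% b1) %*% W2) %*% W3 +
    rep(1, 1) %o% b3
  expect_equal(projection_head(xin, P3, cfg), manual, tolerance = 1e-12)
})

test_that("FPN produces strides 4/8/32 with a common channel width", {
  cfg <- ffe_config("resnet18", base_width = 8, c_fpn = 16)
  set_global_determinism(4)
  P <- msssl:::ffe_init(cfg)
  x <- array(stats::rnorm(224 * 224 * 3), c(224, 224, 3, 1))
  pyr <- ffe_forward(x, P, cfg)
  expect_identical(dim(msssl:::vof(pyr$P2))[1:3], c(56L, 56L, 16L))
  expect_identical(dim(msssl:::vof(pyr$P3))[1:3], c(28L, 28L, 16L))
  expect_identical(dim(msssl:::vof(pyr$P5))[1:3], c(7L, 7L, 16L))

  # zero laterals and smoothing weights annihilate the pyramid
  P0 <- P
  for (nm in grep("^ffe\\.(lat|smooth)", names(P0), value = TRUE))
    P0[[nm]] <- P0[[nm]] * 0
  pyr0 <- ffe_forward(x, P0, cfg)
  expect_true(all(msssl:::vof(pyr0$P2) == 0))
  expect_true(all(msssl:::vof(pyr0$P5) == 0))

  expect_error(ffe_forward(array(0, c(50, 50, 3, 1)), P, cfg), "divisible")
})

test_that("FPN shape law holds across input sizes divisible by 32", {
  cfg <- ffe_config("resnet18", base_width = 8, c_fpn = 8)
  set_global_determinism(4)
  P <- msssl:::ffe_init(cfg)
  for (S in c(64, 96, 160, 320, 512)) {
    x <- array(0, c(S, S, 3, 1))
    pyr <- ffe_forward(x, P, cfg)
    expect_identical(dim(msssl:::vof(pyr$P2))[1:2], as.integer(c(S / 4, S / 4)))
    expect_identical(dim(msssl:::vof(pyr$P3))[1:2], as.integer(c(S / 8, S / 8)))
    expect_identical(dim(msssl:::vof(pyr$P5))[1:2], as.integer(c(S / 32, S / 32)))
  }
})

test_that("upsampling to P2 preserves channels and constants", {
  cfg <- ffe_config("resnet18", base_width = 8, c_fpn = 8)
  set_global_determinism(6)
  P <- msssl:::ffe_init(cfg)
  x <- array(stats::rnorm(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  pyr <- ffe_forward(x, P, cfg)
  up <- upsample_to_p2(pyr)
  d2 <- dim(msssl:::vof(pyr$P2))
  for (nm in c("P2", "P3", "P5"))
    expect_identical(dim(msssl:::vof(up[[nm]]))[1:2], d2[1:2])
  # constant-valued P5 resizes to the same constant
  cpy <- pyr
  cpy$P5 <- array(2.5, dim(msssl:::vof(pyr$P5)))
  up2 <- upsample_to_p2(cpy)
  expect_equal(range(msssl:::vof(up2$P5)), c(2.5, 2.5), tolerance = 1e-12)
})

make_fuse_fixture <- function(method = "addition") {
  cfgm <- micro_config(1)
  set_global_determinism(8)
  model <- init_msssl_model(cfgm)
  x <- array(stats::rnorm(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  vit <- msssl:::model_vit_config(cfgm)
  emb <- gfe_forward(x, model$params, vit)
  pyr <- ffe_forward(x, model$params, msssl:::model_ffe_config(cfgm))
  list(model = model, emb = emb, maps = upsample_to_p2(pyr), cfgm = cfgm)
}

test_that("fusion identities, channel laws and the elementwise-sum oracle", {
  fx <- make_fuse_fixture()
  cfpn <- fx$cfgm$encoder$c_fpn

  add <- fuse_features(fx$maps, fx$emb, fx$model$params, "addition")
  mult <- fuse_features(fx$maps, fx$emb, fx$model$params, "multiplication")
  cc <- fuse_features(fx$maps, fx$emb, fx$model$params, "concatenation")
  expect_identical(dim(msssl:::vof(add$values))[3], as.integer(3 * cfpn))
  expect_identical(dim(msssl:::vof(mult$values))[3], as.integer(3 * cfpn))
  expect_identical(dim(msssl:::vof(cc$values))[3], as.integer(6 * cfpn))

  # the concatenation halves are the two fused operands: summing them with
  # explicit loops must reproduce the addition output
  av <- msssl:::vof(add$values)
  cv <- msssl:::vof(cc$values)
  d <- dim(av)
  manual <- array(0, d)
  for (c in seq_len(d[3]))
    manual[, , c, ] <- cv[, , c, ] + cv[, , 3L * cfpn + c, ]
  expect_equal(av, manual, tolerance = 1e-12)
  # and multiplying them reproduces the multiplication output
  manual_m <- array(0, d)
  for (c in seq_len(d[3]))
    manual_m[, , c, ] <- cv[, , c, ] * cv[, , 3L * cfpn + c, ]
  expect_equal(msssl:::vof(mult$values), manual_m, tolerance = 1e-12)

  # additive identity: a zero token projection leaves the pyramid stack
  P0 <- fx$model$params
  P0[["fuse.W"]] <- P0[["fuse.W"]] * 0
  P0[["fuse.b"]] <- P0[["fuse.b"]] * 0
  add0 <- fuse_features(fx$maps, fx$emb, P0, "addition")
  expect_equal(msssl:::vof(add0$values), cv[, , seq_len(3L * cfpn), ,
                                            drop = FALSE],
               tolerance = 1e-12)
  # multiplicative identity: an all-one token projection
  P1 <- P0
  P1[["fuse.b"]] <- rep(1, length(P1[["fuse.b"]]))
  mul1 <- fuse_features(fx$maps, fx$emb, P1, "multiplication")
  expect_equal(msssl:::vof(mul1$values), cv[, , seq_len(3L * cfpn), ,
                                            drop = FALSE],
               tolerance = 1e-12)

  expect_error(fuse_features(fx$maps, fx$emb, fx$model$params, "averaging"),
               "unknown fusion method")
})
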