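# Self-supervised training: EMA teacher updates, both loss terms against
# explicit oracles, the step contract (loss identity, teacher EMA, drift
# bound, per-sample decoupling) and checkpoint round-trips.

test_that("momentum update is the elementwise convex combination", {
  cfgm <- micro_config(1)
  set_global_determinism(1)
  model <- init_msssl_model(cfgm)
  for (m in c(0, 0.5, 0.9, 0.996, 1)) {
    state <- ssl_state(model)
    state$m <- m
    # perturb the student so teacher and student differ
    set.seed(7)
    for (nm in names(model$params))
      model$params[[nm]] <- model$params[[nm]] +
        stats::rnorm(length(model$params[[nm]]), 0, 0.01)
    t_old <- state$teacher
    momentum_update(state)
    for (nm in sample(names(t_old), 8)) {
      oracle <- m * t_old[[nm]] + (1 - m) * model$params[[nm]]
      expect_equal(state$teacher[[nm]], oracle, tolerance = 1e-14)
    }
    if (m == 1) expect_equal(state$teacher, t_old, tolerance = 0)
    if (m == 0) expect_equal(state$teacher, model$params, tolerance = 0)
    model <- init_msssl_model(cfgm) # reset
  }
})

test_that("momentum update rejects structurally incongruent collections", {
  cfgm <- micro_config(1)
  set_global_determinism(1)
  model <- init_msssl_model(cfgm)
  state <- ssl_state(model)
  state$teacher[["gfe.cls"]] <- matrix(0, 2, 2)
  expect_error(momentum_update(state), "congruent")
})

test_that("match loss: uniform case, cross-entropy oracle, optimization", {
  cfgm <- micro_config(1)
  set_global_determinism(1)
  state <- ssl_state(init_msssl_model(cfgm))
  # K = 4 with zero logits and zero center: uniform vs uniform -> ln 4
  z <- matrix(0, 3, 4)
  state$center <- rep(0, 4)
  expect_equal(as.numeric(match_loss(z, z, state)), log(4), tolerance = 1e-6)

  # random logits vs the explicit -sum(p * log q) summation
  set.seed(2)
  sp <- matrix(stats::rnorm(5 * 8), 5, 8)
  tp <- matrix(stats::rnorm(5 * 8), 5, 8)
  state$center <- stats::rnorm(8)
  got <- as.numeric(match_loss(sp, tp, state))
  softmax <- function(v) { e <- exp(v - max(v)); e / sum(e) }
  manual <- mean(vapply(1:5, function(i) {
    p <- softmax((tp[i, ] - state$center) / state$tau_t)
    q <- softmax(sp[i, ] / state$tau_s)
    -sum(p * log(q))
  }, numeric(1)))
  expect_equal(got, manual, tolerance = 1e-10)

  # minimized over student logits when q = p: small gradient descent
  # approaches the entropy of the fixed teacher target
  p_t <- matrix(stats::rnorm(1 * 6), 1, 6)
  state$center <- rep(0, 6)
  target <- softmax((p_t[1, ]) / state$tau_t)
  sl <- matrix(0, 1, 6)
  vel <- 0
  for (it in 1:4000) {
    node <- msssl:::ad_leaf(sl)
    loss <- match_loss(node, p_t, state)
    msssl:::ad_backward(loss)
    vel <- 0.9 * vel - 0.1 * node$grad
    sl <- sl + vel
  }
  final <- as.numeric(match_loss(sl, p_t, state))
  expect_lt(final - (-sum(target * log(target))), 1e-3)
})

test_that("segmentation loss obeys its closed forms and a loop oracle", {
  # perfect prediction with large logits -> loss ~ 0
  mask <- matrix(rbinom(64, 1, 0.4), 8, 8)
  z <- array((2 * mask - 1) * 12, c(8, 8, 1, 1))
  expect_lt(as.numeric(seg_loss(z, mask)), 1e-3)

  # all-zero mask, zero logits: BCE = ln 2 per pixel; Dice = 1 - eps/(HW/2 + eps)
  z0 <- array(0, c(8, 8, 1, 1))
  m0 <- matrix(0, 8, 8)
  expected <- log(2) + (1 - 1 / (32 + 1))
  expect_equal(as.numeric(seg_loss(z0, m0)), expected, tolerance = 1e-10)

  # random case against an explicit per-pixel loop
  set.seed(3)
  zr <- array(stats::rnorm(6 * 6 * 1 * 2), c(6, 6, 1, 2))
  mr <- array(rbinom(72, 1, 0.5), c(6, 6, 2))
  got <- as.numeric(seg_loss(zr, mr))
  per <- numeric(2)
  for (n in 1:2) {
    bce <- 0; inter <- 0; psum <- 0; ysum <- 0
    for (i in 1:6) for (j in 1:6) {
      zz <- zr[i, j, 1, n]; yy <- mr[i, j, n]
      p <- 1 / (1 + exp(-zz))
      bce <- bce - (yy * log(p) + (1 - yy) * log(1 - p)) / 36
      inter <- inter + p * yy; psum <- psum + p; ysum <- ysum + yy
    }
    per[n] <- bce + 1 - (2 * inter + 1) / (psum + ysum + 1)
  }
  expect_equal(got, mean(per), tolerance = 1e-10)

  expect_error(seg_loss(zr, matrix(0, 3, 3)), "mask shape")
})

test_that("a pretraining step honors its loss identity and EMA contracts", {
  cfgm <- micro_config(0)
  set_global_determinism(0)
  model <- init_msssl_model(cfgm)
  state <- ssl_state(model, total_steps = 10)
  batch <- make_fixed_batch(n = 4, size = 64)

  t_old <- state$teacher
  rep1 <- pretrain_step(batch, state)
  s_new <- model$params

  # exact loss identity
  expect_identical(rep1$total, rep1$match_loss +
                     rep1$lambda_seg * rep1$seg_loss)
  # teacher EMA oracle applied post-step
  m <- state$m
  for (nm in sample(names(t_old), 6)) {
    expect_equal(state$teacher[[nm]], m * t_old[[nm]] + (1 - m) * s_new[[nm]],
                 tolerance = 1e-13)
  }
  # drift bound: max |dT| <= (1 - m) * max |T - S| (pre-update)
  for (nm in names(t_old)) {
    dT <- max(abs(state$teacher[[nm]] - t_old[[nm]]))
    gap <- max(abs(t_old[[nm]] - s_new[[nm]]))
    expect_lte(dT, (1 - m) * gap + 1e-12)
  }
  expect_equal(state$step, 1L)
})

test_that("duplicating a batch element leaves other per-sample losses alone", {
  cfgm <- micro_config(0)
  set_global_determinism(0)
  batch <- make_fixed_batch(n = 4, size = 64)
  batch_dup <- batch
  batch_dup[[2]] <- batch[[1]] # duplicate element 1 into slot 2

  model1 <- init_msssl_model(cfgm)
  r1 <- pretrain_step(batch, ssl_state(model1, total_steps = 10))
  set_global_determinism(0)
  model2 <- init_msssl_model(cfgm)
  r2 <- pretrain_step(batch_dup, ssl_state(model2, total_steps = 10))

  expect_equal(r1$per_sample_match[3:4], r2$per_sample_match[3:4],
               tolerance = 1e-10)
  expect_equal(r1$per_sample_seg[3:4], r2$per_sample_seg[3:4],
               tolerance = 1e-10)
})

test_that("center follows the EMA recursion over observed teacher outputs", {
  cfgm <- micro_config(0)
  set_global_determinism(0)
  model <- init_msssl_model(cfgm)
  state <- ssl_state(model, total_steps = 10)
  batch <- make_fixed_batch(n = 2, size = 64)
  cm <- state$center_momentum
  center <- state$center
  for (k in 1:2) {
    # reproduce the teacher projections the step will see
    xa <- msssl:::stack_views(batch, "view_a")
    xb <- msssl:::stack_views(batch, "view_b")
    xall <- array(c(xa, xb), c(64, 64, 3, 4))
    tp <- msssl:::teacher_forward(xall, state$teacher, model$config)
    center <- cm * center + (1 - cm) * colMeans(tp)
    pretrain_step(batch, state)
    expect_equal(state$center, center, tolerance = 1e-10)
  }
})

test_that("zero segmentation weight silences segmentation-head gradients", {
  cfgm <- micro_config(0)
  set_global_determinism(0)
  model <- init_msssl_model(cfgm)
  state <- ssl_state(model, total_steps = 10)
  state$lambda_seg <- 0
  batch <- make_fixed_batch(n = 2, size = 64)

  P <- msssl:::lift_params(model$params)
  cfg <- model$config
  xa <- msssl:::stack_views(batch, "view_a")
  so <- msssl:::student_forward(xa, P, cfg, model$buffers, training = TRUE)
  tb <- msssl:::teacher_forward(xa, state$teacher, cfg)
  loss <- msssl:::ad_add(match_loss(so$proj, tb, state),
                         msssl:::ad_scale(seg_loss(so$seg_logits,
                                                   msssl:::stack_masks(batch, "mask_a")),
                                          state$lambda_seg))
  msssl:::ad_backward(loss)
  gseg <- msssl:::collect_grads(P)[["dle.seg.W"]]
  expect_true(all(gseg == 0))
})

test_that("checkpoints round-trip bit-exactly and bind to the config digest", {
  cfgm <- micro_config(0)
  set_global_determinism(0)
  model <- init_msssl_model(cfgm)
  state <- ssl_state(model, total_steps = 10)
  pretrain_step(make_fixed_batch(n = 2, size = 64), state)
  path <- file.path(tempdir(), "ck_test.rds")
  save_checkpoint(state, NULL, list(epoch = 1L, s = 2L, ord = NULL), path)
  back <- load_checkpoint(path, cfgm)
  expect_identical(back$state$model$params, model$params)
  expect_identical(back$state$teacher, state$teacher)
  expect_identical(back$state$center, state$center)
  expect_identical(back$state$step, state$step)
  expect_true(file.exists(paste0(path, ".json")))

  other <- micro_config(0)
  other$encoder$c_fpn <- 32L
  other <- msssl:::validate_config(other)
  expect_error(load_checkpoint(path, other), "digest")
})
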