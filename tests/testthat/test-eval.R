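# Evaluation protocols: splitting, quadratic weighted kappa and the F1
# family against brute-force oracles, frozen linear evaluation, fine-tuning
# no-op contract, and attention maps.

test_that("splits are disjoint, exhaustive, sized and reproducible", {
  mf <- data.frame(id = sprintf("i%03d", 1:100),
                   grade = rep(0:4, each = 20),
                   view = "single", file = "x.png")
  sp <- split_dataset(mf, split_spec(seed = 3))
  expect_equal(nrow(sp$train), 70)
  expect_equal(nrow(sp$val), 15)
  expect_equal(nrow(sp$test), 15)
  all_ids <- sort(c(sp$train$id, sp$val$id, sp$test$id))
  expect_identical(all_ids, sort(mf$id))
  expect_length(intersect(sp$train$id, sp$test$id), 0)
  expect_length(intersect(sp$train$id, sp$val$id), 0)
  # stratification: each grade contributes proportionally
  expect_equal(as.vector(table(sp$test$grade)), rep(3, 5))

  sp2 <- split_dataset(mf, split_spec(seed = 3))
  expect_identical(sp, sp2)
  sp3 <- split_dataset(mf, split_spec(seed = 4))
  expect_false(identical(sp$test$id, sp3$test$id))

  tiny <- mf[c(1, 2, 21, 41, 61, 81), ]
  expect_error(split_dataset(tiny, split_spec()), "at least 3")
})

# explicit double-sum contingency-table oracle
qwk_oracle <- function(y_true, y_pred, K = 5) {
  O <- matrix(0, K, K)
  for (i in seq_along(y_true))
    O[y_true[i] + 1, y_pred[i] + 1] <- O[y_true[i] + 1, y_pred[i] + 1] + 1
  n <- sum(O)
  E <- outer(rowSums(O), colSums(O)) / n
  num <- 0; den <- 0
  for (i in 1:K) for (j in 1:K) {
    w <- (i - j)^2 / (K - 1)^2
    num <- num + w * O[i, j]
    den <- den + w * E[i, j]
  }
  1 - num / den
}

test_that("quadratic weighted kappa matches the double-sum oracle", {
  expect_equal(quadratic_weighted_kappa(c(0, 1, 2, 3, 4), c(0, 1, 2, 3, 4)), 1)
  # maximal quadratic disagreement case, value from the oracle
  yt <- c(0, 0, 4, 4); yp <- c(4, 4, 0, 0)
  expect_equal(quadratic_weighted_kappa(yt, yp), qwk_oracle(yt, yp),
               tolerance = 1e-12)
  set.seed(5)
  for (i in 1:200) {
    n <- sample(2:200, 1)
    a <- sample(0:4, n, replace = TRUE)
    b <- sample(0:4, n, replace = TRUE)
    if (all(a == b)) next
    expect_equal(quadratic_weighted_kappa(a, b), qwk_oracle(a, b),
                 tolerance = 1e-12)
    # symmetry and order invariance
    expect_equal(quadratic_weighted_kappa(a, b),
                 quadratic_weighted_kappa(b, a), tolerance = 1e-12)
    perm <- sample(n)
    expect_equal(quadratic_weighted_kappa(a[perm], b[perm]),
                 quadratic_weighted_kappa(a, b), tolerance = 1e-12)
  }
  expect_error(quadratic_weighted_kappa(integer(0), integer(0)), "empty")
  expect_error(quadratic_weighted_kappa(c(0, 5), c(0, 1)), "range")
  expect_error(quadratic_weighted_kappa(c(0, 1), c(0)), "length")
})

test_that("classification metrics match brute-force counting", {
  yt <- c(0, 1, 2, 3, 4, 0, 1, 2)
  rep <- classification_metrics(yt, yt)
  expect_equal(rep$accuracy, 100)
  expect_equal(rep$f1_weighted, 100)
  expect_equal(rep$f1_macro, 100)
  expect_equal(rep$f1_micro, 100)

  set.seed(6)
  for (i in 1:30) {
    n <- sample(10:120, 1)
    a <- sample(0:4, n, replace = TRUE)
    b <- sample(0:4, n, replace = TRUE)
    rep <- classification_metrics(a, b)
    # micro-F1 equals accuracy for single-label multiclass
    expect_equal(rep$f1_micro, rep$accuracy, tolerance = 1e-12)
    # confusion conservation and recomputed recalls
    expect_equal(sum(rep$confusion), n)
    expect_equal(as.vector(table(factor(a, levels = 0:4))),
                 unname(rowSums(rep$confusion)))
    acc <- sum(a == b) / n * 100
    expect_equal(rep$accuracy, acc, tolerance = 1e-12)
    f1s <- vapply(0:4, function(k) {
      tp <- sum(a == k & b == k)
      pr <- if (sum(b == k) > 0) tp / sum(b == k) else 0
      rc <- if (sum(a == k) > 0) tp / sum(a == k) else 0
      if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
    }, numeric(1))
    expect_equal(rep$f1_macro, 100 * mean(f1s), tolerance = 1e-12)
    sup <- as.vector(table(factor(a, levels = 0:4)))
    expect_equal(rep$f1_weighted, 100 * sum(f1s * sup) / n, tolerance = 1e-12)
  }
})

test_that("linear evaluation freezes the encoder and fine-tune no-op holds", {
  cfgm <- micro_config(1)
  set_global_determinism(1)
  ds <- local_dataset()
  model <- init_msssl_model(cfgm)
  before <- msssl:::params_checksum(model$params)
  splits <- split_dataset(ds$manifest, split_spec(seed = 2))
  rep <- linear_eval(model, splits, cfgm)
  expect_identical(msssl:::params_checksum(model$params), before)
  expect_true(attr(rep, "frozen_ok"))
  expect_s3_class(rep, "metrics_report")

  # zero-epoch fine-tuning evaluates the initialized head without updates
  r0a <- finetune(model, splits, cfgm, epochs = 0)
  r0b <- finetune(model, splits, cfgm, epochs = 0)
  expect_identical(r0a$confusion, r0b$confusion)
  expect_identical(msssl:::params_checksum(model$params), before)
})

test_that("attention maps have the patch-grid geometry and [0,1] range", {
  cfgm <- micro_config(1)
  set_global_determinism(1)
  model <- init_msssl_model(cfgm)
  scfg <- synthetic_config(image_size = 64, seed = 5)
  img <- generate_fundus(scfg, 4, msssl_rng(4))
  res <- attention_map(model, img, size = 256)
  expect_identical(dim(res$grid), c(16L, 16L)) # 256 / patch 16
  expect_equal(range(res$grid), c(0, 1))
  expect_identical(res$token, "global")

  # head-average equals the explicit mean of per-head global rows
  vit <- msssl:::model_vit_config(cfgm)
  x <- msssl:::resize_bilinear_hwc(
    normalize_for_model(extract_green_channel(img)), 64, 64)
  emb <- gfe_forward(array(x, c(64, 64, 3, 1)), model$params, vit,
                     collect_attention = TRUE)
  A <- emb$attention[vit$depth, , , , 1]
  manual <- colMeans(A[, 1, -1])
  grid <- t(matrix(manual, 4, 4))
  res64 <- attention_map(model, img, size = 64)
  expect_equal(res64$grid, msssl:::minmax_norm(grid), tolerance = 1e-12)

  expect_error(attention_map(model, img, size = 100), "divisible")
})
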