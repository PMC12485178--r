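# Downstream evaluation: reproducible 70/15/15 splitting (stratified by
# grade), quadratic weighted kappa and the F1 family for 5-class ordinal
# grading, linear evaluation on frozen features, full fine-tuning, and
# global-token attention-map visualization.

#' Split specification
#'
#' @param fractions train/val/test fractions, positive, summing to 1.
#' @param seed shuffle seed.
#' @param stratified stratify by grade (default on; stabilizes small
#'   benchmarks).
#' @export
split_spec <- function(fractions = c(0.70, 0.15, 0.15), seed = 1,
                       stratified = TRUE) {
  if (length(fractions) != 3 || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be 3 positive numbers summing to 1")
  structure(list(fractions = fractions, seed = as.integer(seed),
                 stratified = isTRUE(stratified)),
            class = "split_spec")
}

split_counts <- function(n, fractions) {
  n_val <- round(fractions[2] * n)
  n_test <- round(fractions[3] * n)
  n_train <- n - n_val - n_test # remainder goes to train
  c(train = n_train, val = n_val, test = n_test)
}

#' Split a manifest into disjoint train/val/test manifests
#'
#' Splitting operates on unique image ids (dual views of one eye always
#' land in the same split). Sizes are the rounded fractions with the
#' remainder assigned to train; the partition is exhaustive and disjoint
#' and reproducible under `spec$seed`.
#'
#' @param manifest data frame with `id` and `grade` columns.
#' @param spec a [split_spec()].
#' @return list of three manifests `train`, `val`, `test`.
#' @export
split_dataset <- function(manifest, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"), nrow(manifest) > 0)
  ids <- unique(manifest[, c("id", "grade")])
  rng <- msssl_rng(spec$seed)
  assign_one <- function(sub) {
    n <- nrow(sub)
    cnt <- split_counts(n, spec$fractions)
    ord <- with_rng(rng, sample.int(n))
    lab <- rep(c("train", "val", "test"), times = cnt)
    out <- character(n)
    out[ord] <- lab
    out
  }
  if (spec$stratified) {
    small <- table(factor(ids$grade, levels = sort(unique(ids$grade))))
    if (any(small < 3))
      stop("stratified split needs at least 3 samples per grade")
    ids$split <- NA_character_
    for (g in sort(unique(ids$grade))) {
      sel <- ids$grade == g
      ids$split[sel] <- assign_one(ids[sel, , drop = FALSE])
    }
  } else {
    ids$split <- assign_one(ids)
  }
  take <- function(which) {
    manifest[manifest$id %in% ids$id[ids$split == which], , drop = FALSE]
  }
  list(train = take("train"), val = take("val"), test = take("test"))
}

#' Quadratic weighted kappa
#'
#' Chance-corrected agreement with disagreement weights
#' `w_ij = (i - j)^2 / (K - 1)^2`:
#' `kappa = 1 - sum(w * O) / sum(w * E)` where `O` is the observed K x K
#' contingency table and `E` the outer product of its marginals scaled to
#' the total count.
#'
#' @param y_true,y_pred integer labels in `0..K-1`.
#' @param K number of ordinal classes.
#' @return kappa in [-1, 1]; 1 for identical vectors.
#' @export
quadratic_weighted_kappa <- function(y_true, y_pred, K = 5) {
  if (length(y_true) == 0) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (any(!(y_true %in% 0:(K - 1))) || any(!(y_pred %in% 0:(K - 1))))
    stop("labels out of range 0..K-1")
  if (all(y_true == y_pred)) return(1)
  O <- table(factor(y_true, levels = 0:(K - 1)),
             factor(y_pred, levels = 0:(K - 1)))
  O <- matrix(as.numeric(O), K, K)
  n <- sum(O)
  E <- outer(rowSums(O), colSums(O)) / n
  W <- outer(0:(K - 1), 0:(K - 1), function(i, j) (i - j)^2 / (K - 1)^2)
  1 - sum(W * O) / sum(W * E)
}

#' Classification metrics for 5-class grading
#'
#' @param y_true,y_pred integer labels in 0..K-1.
#' @param K number of classes.
#' @return a `metrics_report`: quadratic weighted `kappa`, `accuracy` (%),
#'   `f1_weighted`/`f1_macro`/`f1_micro` (%), the K x K `confusion` matrix
#'   (rows = truth) and a per-class table.
#' @export
classification_metrics <- function(y_true, y_pred, K = 5) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) == 0) stop("empty input")
  if (any(!(y_true %in% 0:(K - 1))) || any(!(y_pred %in% 0:(K - 1))))
    stop("labels out of range 0..K-1")
  conf <- table(factor(y_true, levels = 0:(K - 1)),
                factor(y_pred, levels = 0:(K - 1)))
  conf <- matrix(as.numeric(conf), K, K,
                 dimnames = list(truth = 0:(K - 1), pred = 0:(K - 1)))
  n <- length(y_true)
  tp <- diag(conf)
  support <- rowSums(conf)
  predn <- colSums(conf)
  prec <- ifelse(predn > 0, tp / predn, 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  acc <- sum(tp) / n
  micro_p <- sum(tp) / sum(predn)
  micro_r <- sum(tp) / sum(support)
  f1_micro <- if (micro_p + micro_r > 0)
    2 * micro_p * micro_r / (micro_p + micro_r) else 0
  structure(list(
    kappa = quadratic_weighted_kappa(y_true, y_pred, K),
    accuracy = 100 * acc,
    f1_weighted = 100 * sum(f1 * support) / n,
    f1_macro = 100 * mean(f1),
    f1_micro = 100 * f1_micro,
    confusion = conf,
    per_class = data.frame(class = 0:(K - 1), precision = prec,
                           recall = rec, f1 = f1, support = support)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report  kappa=%.4f  acc=%.2f%%  F1w=%.2f%%  F1M=%.2f%%  F1m=%.2f%%>\n",
    x$kappa, x$accuracy, x$f1_weighted, x$f1_macro, x$f1_micro))
  invisible(x)
}

# ---- feature extraction and heads -------------------------------------------

as_model <- function(checkpoint, cfg = NULL) {
  if (inherits(checkpoint, "msssl_model")) return(checkpoint)
  if (inherits(checkpoint, "ssl_state")) return(checkpoint$model)
  load_checkpoint(checkpoint, cfg)$model
}

# pooled representation per image: the ViT global token (default) or the
# spatially averaged Deep-Learner features ("full" path)
extract_features <- function(model, manifest, batch = 16L) {
  cfg <- model$config
  vit <- model_vit_config(cfg)
  n <- nrow(manifest)
  idx <- split(seq_len(n), ceiling(seq_len(n) / batch))
  feats <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    rows <- idx[[k]]
    S <- cfg$encoder$input_size
    x <- array(0, c(S, S, 3, length(rows)))
    for (i in seq_along(rows)) {
      pi <- prepare_image(manifest$file[rows[i]], cfg)
      x[, , , i] <- (pi$raster - 0.5) / 0.5
    }
    if (identical(cfg$eval$head, "full")) {
      P <- model$params
      out <- student_forward(x, P, cfg, model$buffers, training = FALSE)
      f <- vof(ad_spatial_meanpool(out$features))
      feats[[k]] <- t(f)
    } else {
      emb <- gfe_forward(x, model$params, vit)
      feats[[k]] <- vof(gfe_cls_token(emb))
    }
  }
  do.call(rbind, feats)
}

softmax_head_train <- function(Xtr, ytr, Xval, yval, K = 5, epochs = 200,
                               lr = 0.01, weight_decay = 1e-4, seed = 1) {
  d <- ncol(Xtr)
  rng <- msssl_rng(seed)
  W <- with_rng(rng, matrix(stats::rnorm(d * K, 0, 0.01), d, K))
  b <- rep(0, K)
  Yt <- diag(K)[ytr + 1, , drop = FALSE]
  opt <- adamw_state(list(W = W, b = b), lr = lr,
                     weight_decay = weight_decay)
  best <- list(kappa = -Inf, W = W, b = b)
  n <- nrow(Xtr)
  for (e in seq_len(epochs)) {
    Z <- sweep(Xtr %*% W, 2L, b, "+")
    Pm <- softmax_rows_val(Z)
    G <- (Pm - Yt) / n
    gr <- list(W = crossprod(Xtr, G), b = colSums(G))
    ps <- adamw_step(opt, list(W = W, b = b), gr)
    W <- ps$W; b <- ps$b
    if (e %% 5 == 0 || e == epochs) {
      pv <- max.col(sweep(Xval %*% W, 2L, b, "+"), ties.method = "first") - 1
      kap <- tryCatch(quadratic_weighted_kappa(yval, pv),
                      error = function(e2) -Inf)
      if (kap > best$kappa) best <- list(kappa = kap, W = W, b = b)
    }
  }
  best
}

head_predict <- function(head, X) {
  max.col(sweep(X %*% head$W, 2L, head$b, "+"), ties.method = "first") - 1
}

# crude but order-sensitive checksum of a parameter collection, used to
# verify the frozen-encoder contract
params_checksum <- function(params) {
  s <- 0
  for (nm in names(params)) {
    p <- as.vector(params[[nm]])
    s <- s + sum(p * (seq_along(p) %% 97 + 1)) + length(p) * 1e-7
  }
  sprintf("%.10e", s)
}

manifest_labels <- function(manifest) {
  lab <- manifest$grade[!duplicated(manifest$id)]
  ids <- manifest$id[!duplicated(manifest$id)]
  stats::setNames(as.integer(lab), ids)
}

# one row per id (first view) for feature extraction
dedup_manifest <- function(manifest) manifest[!duplicated(manifest$id), ,
                                              drop = FALSE]

#' Linear evaluation of frozen pretrained features
#'
#' The encoder stays frozen (verified by checksum); a single linear layer
#' on the pooled representation is trained on the train split, selected on
#' the validation split by quadratic weighted kappa, and reported on the
#' test split.
#'
#' @param checkpoint checkpoint path, `ssl_state` or `msssl_model`.
#' @param splits list with `train`, `val`, `test` manifests (see
#'   [split_dataset()]).
#' @param cfg optional configuration for digest checking.
#' @param train_labels optional override of the training labels (same
#'   order as the deduplicated train manifest) for custom controls.
#' @param null_permutations if > 0, additionally run this many
#'   label-permutation controls: train and validation labels are jointly
#'   shuffled (so that neither fitting nor kappa-based model selection sees
#'   a true label) and the resulting test kappas are returned in attribute
#'   `null_kappas`. Their mean estimates the no-information baseline.
#' @return a `metrics_report` on the test split, with attributes `head`,
#'   `val_kappa` and (optionally) `null_kappas`.
#' @export
linear_eval <- function(checkpoint, splits, cfg = NULL, train_labels = NULL,
                        null_permutations = 0L) {
  model <- as_model(checkpoint, cfg)
  before <- params_checksum(model$params)
  tr <- dedup_manifest(splits$train)
  va <- dedup_manifest(splits$val)
  te <- dedup_manifest(splits$test)
  Xtr <- extract_features(model, tr)
  Xva <- extract_features(model, va)
  Xte <- extract_features(model, te)
  mu <- colMeans(Xtr)
  sd <- pmax(apply(Xtr, 2, stats::sd), 1e-8)
  std <- function(X) sweep(sweep(X, 2L, mu, "-"), 2L, sd, "/")
  ytr <- train_labels %||% as.integer(tr$grade)
  fit_and_score <- function(y_train, y_val) {
    head <- softmax_head_train(std(Xtr), y_train, std(Xva), y_val,
                               epochs = model$config$eval$epochs,
                               lr = model$config$eval$lr,
                               seed = model$config$eval$seed)
    list(head = head, pred = head_predict(head, std(Xte)))
  }
  fit <- fit_and_score(ytr, as.integer(va$grade))
  null_kappas <- NULL
  if (null_permutations > 0) {
    rng <- msssl_rng(substream_seed(model$config$eval$seed, "null"))
    null_kappas <- vapply(seq_len(null_permutations), function(k) {
      ysh_tr <- with_rng(rng, sample(as.integer(tr$grade)))
      ysh_va <- with_rng(rng, sample(as.integer(va$grade)))
      quadratic_weighted_kappa(as.integer(te$grade),
                               fit_and_score(ysh_tr, ysh_va)$pred)
    }, numeric(1))
  }
  after <- params_checksum(model$params)
  if (!identical(before, after)) stop("encoder was modified during linear evaluation")
  rep <- classification_metrics(as.integer(te$grade), fit$pred)
  attr(rep, "head") <- fit$head
  attr(rep, "val_kappa") <- fit$head$kappa
  attr(rep, "null_kappas") <- null_kappas
  attr(rep, "frozen_ok") <- TRUE
  rep
}

#' Fine-tune the pretrained encoder on labeled grades
#'
#' All global-branch parameters and a linear classification head on the
#' pooled representation are trainable (no additional modules downstream).
#' With `epochs = 0` the initialized head is evaluated without any update.
#'
#' @param checkpoint checkpoint path, `ssl_state` or `msssl_model`.
#' @param splits list with `train`, `val`, `test` manifests.
#' @param cfg optional configuration for digest checking.
#' @param epochs fine-tuning epochs.
#' @param lr learning rate.
#' @param batch_size minibatch size.
#' @return a `metrics_report` on the test split.
#' @export
finetune <- function(checkpoint, splits, cfg = NULL, epochs = 3, lr = 1e-4,
                     batch_size = 8L) {
  model <- as_model(checkpoint, cfg)
  cfgm <- model$config
  vit <- model_vit_config(cfgm)
  K <- 5L
  D <- vit$embed_dim
  rng <- msssl_rng(substream_seed(cfgm$runtime$seed, "finetune"))
  params <- model$params[grep("^gfe\\.", names(model$params), value = TRUE)]
  params$head.W <- with_rng(rng, matrix(stats::rnorm(D * K, 0, 0.01), D, K))
  params$head.b <- rep(0, K)

  tr <- dedup_manifest(splits$train)
  va <- dedup_manifest(splits$val)
  te <- dedup_manifest(splits$test)
  S <- cfgm$encoder$input_size
  load_raster <- function(mf) {
    x <- array(0, c(S, S, 3, nrow(mf)))
    for (i in seq_len(nrow(mf)))
      x[, , , i] <- (prepare_image(mf$file[i], cfgm)$raster - 0.5) / 0.5
    x
  }
  xtr <- load_raster(tr)
  ytr <- as.integer(tr$grade)
  eval_split <- function(mf, x = NULL) {
    x <- x %||% load_raster(mf)
    emb <- gfe_forward(x, params, vit)
    cls <- vof(gfe_cls_token(emb))
    logits <- sweep(cls %*% params$head.W, 2L, params$head.b, "+")
    max.col(logits, ties.method = "first") - 1
  }

  if (epochs > 0) {
    opt <- adamw_state(params, lr = lr, weight_decay = 1e-4)
    best <- list(kappa = -Inf, params = params)
    n <- nrow(tr)
    for (e in seq_len(epochs)) {
      ord <- with_rng(rng, sample.int(n))
      nb <- n %/% batch_size
      for (bI in seq_len(max(nb, 1))) {
        rows <- ord[((bI - 1) * batch_size + 1):min(bI * batch_size, n)]
        P <- lift_params(params)
        emb <- gfe_forward(xtr[, , , rows, drop = FALSE], P, vit)
        cls <- gfe_cls_token(emb)
        logits <- ad_addbias_rows(ad_matmul(cls, P$head.W), P$head.b)
        onehot <- diag(K)[ytr[rows] + 1, , drop = FALSE]
        loss <- ad_scale(ad_sum(ad_mul(ad_logsoftmax_rows(logits), onehot)),
                         -1 / length(rows))
        ad_backward(loss)
        params <- adamw_step(opt, params, collect_grads(P))
      }
      pv <- eval_split(va)
      kap <- tryCatch(quadratic_weighted_kappa(as.integer(va$grade), pv),
                      error = function(e2) -Inf)
      if (kap > best$kappa) best <- list(kappa = kap, params = params)
    }
    params <- best$params
  }
  pred <- eval_split(te)
  rep <- classification_metrics(as.integer(te$grade), pred)
  attr(rep, "val_kappa") <- if (epochs > 0) best$kappa else NA_real_
  rep
}

# ---- attention visualization ------------------------------------------------

# bilinear interpolation of the learned position embedding to a new grid
interp_pos_embed <- function(pos, old_grid, new_grid, D) {
  cls <- pos[1, , drop = FALSE]
  grid <- pos[-1, , drop = FALSE]
  a <- array(grid, c(old_grid[2], old_grid[1], D, 1)) # col fastest ordering
  a <- aperm(a, c(2, 1, 3, 4))
  a <- resize_apply(a, bilinear_matrix(new_grid[1], old_grid[1]),
                    bilinear_matrix(new_grid[2], old_grid[2]))
  a <- aperm(a, c(2, 1, 3, 4))
  rbind(cls, matrix(a, new_grid[1] * new_grid[2], D))
}

#' Global-token attention map of the ViT branch
#'
#' The image is resized to `size` (1024 by default, for detailed maps), run
#' through the ViT; the final layer's global-token attention row (its self
#' entry dropped) is averaged across heads, reshaped to the patch grid and
#' min-max normalized.
#'
#' @param checkpoint checkpoint path, `ssl_state` or `msssl_model`.
#' @param img a [fundus_image()] (or H x W x 3 array in 0..255).
#' @param size square working resolution; must be a multiple of the patch
#'   size.
#' @return an `attention_map_result`: `grid` ((size/p) x (size/p), in
#'   [0, 1]), `layer = "last"`, `aggregation = "mean_heads"`,
#'   `token = "global"`.
#' @export
attention_map <- function(checkpoint, img, size = 1024) {
  model <- as_model(checkpoint)
  cfg <- model$config
  p <- cfg$encoder$patch_size
  if (size %% p != 0) stop("size must be divisible by the patch size")
  if (inherits(img, "fundus_image")) img <- img$pixels
  green <- extract_green_channel(img)
  raster <- normalize_for_model(green)
  x <- resize_bilinear_hwc(raster, size, size)

  vit <- model_vit_config(cfg)
  old_hp <- vit$input_size %/% p
  new_hp <- size %/% p
  params <- model$params
  if (new_hp != old_hp) {
    params[["gfe.pos"]] <- interp_pos_embed(params[["gfe.pos"]],
                                            c(old_hp, old_hp),
                                            c(new_hp, new_hp), vit$embed_dim)
    vit$input_size <- as.integer(size)
  }
  emb <- gfe_forward(x, params, vit, collect_attention = TRUE)
  A <- emb$attention[vit$depth, , , , 1, drop = FALSE] # last layer
  heads <- dim(A)[2]
  row <- apply(array(A[1, , 1, -1, 1], c(heads, emb$T - 1)), 2, mean)
  # token order is col-fastest, so fill the grid accordingly
  grid <- t(matrix(row, new_hp, new_hp))
  structure(list(grid = minmax_norm(grid), layer = "last",
                 aggregation = "mean_heads", token = "global"),
            class = "attention_map_result")
}
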