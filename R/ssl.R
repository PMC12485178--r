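# Momentum-encoder self-supervised pretraining with two objectives:
# (1) representation matching -- cross-entropy between the centered,
#     temperature-sharpened teacher distribution and the student
#     distribution (self-distillation; no negative pairs), symmetrized over
#     the two augmented views;
# (2) saliency segmentation -- binary cross-entropy plus soft-Dice between
#     the Deep Learner's segmentation logits and the Otsu-binarized
#     saliency mask of each view.
# The teacher is an exponential-moving-average copy of the student and
# receives no gradient at any point.

#' Create the self-supervised training state
#'
#' @param model an `msssl_model` from [init_msssl_model()] (the student).
#' @param total_steps planned optimizer steps (for the cosine schedule).
#' @return `ssl_state` environment: teacher parameter copy, centering
#'   vector, EMA momentum `m`, temperatures `tau_s` > `tau_t`, center
#'   momentum, optimizer state and step counter.
#' @export
ssl_state <- function(model, total_steps = 1000L) {
  cfg <- model$config$ssl
  st <- new.env(parent = emptyenv())
  st$model <- model
  st$teacher <- model$params
  st$center <- rep(0, model$config$encoder$proj_dim)
  st$m <- cfg$m
  st$tau_s <- cfg$tau_s
  st$tau_t <- cfg$tau_t
  st$center_momentum <- cfg$center_momentum
  st$lambda_seg <- cfg$lambda_seg
  st$step <- 0L
  st$total_steps <- as.integer(total_steps)
  st$opt <- adamw_state(model$params, lr = cfg$lr,
                        weight_decay = cfg$weight_decay)
  st$history <- list()
  class(st) <- "ssl_state"
  st
}

params_congruent <- function(a, b) {
  identical(names(a), names(b)) &&
    all(vapply(names(a), function(nm)
      identical(dim(a[[nm]]), dim(b[[nm]])) &&
        length(a[[nm]]) == length(b[[nm]]), logical(1)))
}

#' Exponential-moving-average teacher update
#'
#' Every teacher parameter moves to `m * teacher + (1 - m) * student`; the
#' student is untouched and no gradient ever flows into the teacher.
#'
#' @param state an [ssl_state()].
#' @return the state, invisibly.
#' @export
momentum_update <- function(state) {
  stopifnot(inherits(state, "ssl_state"))
  s <- state$model$params
  t <- state$teacher
  if (!params_congruent(t, s))
    stop("teacher and student parameter collections are not congruent")
  m <- state$m
  for (nm in names(t)) t[[nm]] <- m * t[[nm]] + (1 - m) * s[[nm]]
  state$teacher <- t
  invisible(state)
}

#' Representation-matching loss (one view pairing)
#'
#' Cross-entropy between the teacher distribution
#' `softmax((teacher_proj - center) / tau_t)` (a constant target) and the
#' student distribution `softmax(student_proj / tau_s)`.
#'
#' @param student_proj N x K student projections (tape node during
#'   training, or plain matrix).
#' @param teacher_proj N x K teacher projections (plain matrix).
#' @param state an [ssl_state()] (temperatures and center).
#' @return scalar loss (node or numeric) with attribute `per_sample`.
#' @export
match_loss <- function(student_proj, teacher_proj, state) {
  tp <- vof(teacher_proj)
  sp <- vof(student_proj)
  if (ncol(tp) != ncol(sp)) stop("projection dimensions differ")
  if (any(!is.finite(tp)) || any(!is.finite(sp)))
    stop("non-finite projections; step aborted")
  p <- softmax_rows_val(sweep(tp, 2L, state$center, "-") / state$tau_t)
  q <- ad_logsoftmax_rows(ad_scale(student_proj, 1 / state$tau_s))
  N <- nrow(tp); K <- ncol(tp)
  per <- ad_scale(ad_matmul(ad_mul(q, p), matrix(1, K, 1)), -1)
  loss <- ad_scale(ad_matmul(ad_t(per), matrix(1 / N, N, 1)), 1)
  loss <- if (is_ad(loss)) loss else as.numeric(loss)
  attr(loss, "per_sample") <- as.vector(vof(per))
  loss
}

#' Segmentation loss: binary cross-entropy plus soft Dice
#'
#' Per-sample mean pixelwise BCE (computed in the numerically stable
#' logits form) plus `1 - (2 |P∩Y| + eps) / (|P| + |Y| + eps)` with
#' smoothing `eps = 1`, averaged over the batch.
#'
#' @param seg_logits H x W x 1 x N logits (node or array).
#' @param mask matching binary mask (H x W x N or H x W x 1 x N array, or a
#'   [binary_mask()] for a single sample).
#' @param eps Dice smoothing term.
#' @return scalar loss with attribute `per_sample`.
#' @export
seg_loss <- function(seg_logits, mask, eps = 1) {
  if (inherits(mask, "binary_mask")) mask <- mask$values
  d <- dim(vof(seg_logits))
  if (length(d) == 2) {
    seg_logits <- ad_reshape(seg_logits, c(d, 1, 1))
    d <- c(d, 1, 1)
  }
  y <- array(mask, d)
  if (length(mask) != prod(d)) stop("mask shape does not match logits")
  HW <- d[1] * d[2]
  N <- d[4]
  z <- ad_reshape(seg_logits, c(HW, N))
  ym <- matrix(y, HW, N)
  ones <- matrix(1, 1, HW)
  bce_px <- ad_add(ad_sub(ad_relu(z), ad_mul(z, ym)),
                   ad_softplus(ad_scale(ad_abs(z), -1)))
  bce_n <- ad_matmul(ones / HW, bce_px)                       # 1 x N
  p <- ad_sigmoid(z)
  inter <- ad_matmul(ones, ad_mul(p, ym))
  psum <- ad_matmul(ones, p)
  ysum <- matrix(colSums(ym), 1, N)
  dice_n <- ad_sub(matrix(1, 1, N),
                   ad_div(ad_addc(ad_scale(inter, 2), eps),
                          ad_addc(ad_add(psum, ysum), eps)))
  per <- ad_add(bce_n, dice_n)
  loss <- ad_matmul(per, matrix(1 / N, N, 1))
  loss <- if (is_ad(loss)) loss else as.numeric(loss)
  attr(loss, "per_sample") <- as.vector(vof(per))
  loss
}

stack_views <- function(batch, field) {
  d <- dim(batch[[1]][[field]])
  out <- array(0, c(d[1], d[2], 3, length(batch)))
  for (i in seq_along(batch)) out[, , , i] <- batch[[i]][[field]]
  out
}

stack_masks <- function(batch, field) {
  d <- dim(batch[[1]][[field]])
  out <- array(0, c(d[1], d[2], 1, length(batch)))
  for (i in seq_along(batch)) out[, , 1, i] <- batch[[i]][[field]]
  out
}

#' One pretraining step
#'
#' The student processes both augmented views through the full
#' encoder/Deep-Learner path; the momentum teacher processes the opposite
#' views (projection output only). The total loss is
#' `match + lambda_seg * seg` (exact identity), one optimizer step is taken
#' on the student only, then the teacher EMA and the center EMA advance.
#'
#' @param batch list of `augmented_view_pair`s with masks present.
#' @param state an [ssl_state()].
#' @return a `loss_report`: `total`, `match_loss`, `seg_loss`,
#'   `lambda_seg`, `lr`, and per-sample components.
#' @export
pretrain_step <- function(batch, state) {
  stopifnot(inherits(state, "ssl_state"), length(batch) >= 1)
  if (any(vapply(batch, function(p) is.null(p$mask_a) || is.null(p$mask_b),
                 logical(1))))
    stop("all view pairs must carry masks")
  model <- state$model
  cfg <- model$config
  va <- stack_views(batch, "view_a")
  vb <- stack_views(batch, "view_b")
  ma <- stack_masks(batch, "mask_a")
  mb <- stack_masks(batch, "mask_b")

  N <- length(batch)
  d <- dim(va)
  xall <- array(0, c(d[1], d[2], 3, 2 * N))
  xall[, , , seq_len(N)] <- va
  xall[, , , N + seq_len(N)] <- vb
  mall <- array(0, c(d[1], d[2], 1, 2 * N))
  mall[, , , seq_len(N)] <- ma
  mall[, , , N + seq_len(N)] <- mb

  # both views in one batched pass (batch statistics span the 2N views)
  P <- lift_params(model$params)
  so <- student_forward(xall, P, cfg, model$buffers, training = TRUE)
  tproj <- teacher_forward(xall, state$teacher, cfg)
  sA <- ad_slice_rows(so$proj, seq_len(N))
  sB <- ad_slice_rows(so$proj, N + seq_len(N))
  ta <- tproj[seq_len(N), , drop = FALSE]
  tb <- tproj[N + seq_len(N), , drop = FALSE]

  la <- match_loss(sA, tb, state)
  lb <- match_loss(sB, ta, state)
  match <- ad_scale(ad_add(la, lb), 0.5)
  seg <- seg_loss(so$seg_logits, mall)
  total <- ad_add(match, ad_scale(seg, state$lambda_seg))

  if (!is.finite(vof(total)[1])) stop("non-finite loss; step aborted")
  ad_backward(total)
  grads <- collect_grads(P)
  lr <- cosine_lr(state$step + 1L, state$total_steps, cfg$ssl$lr)
  model$params <- adamw_step(state$opt, model$params, grads, lr)
  momentum_update(state)
  tc <- rbind(ta, tb)
  state$center <- state$center_momentum * state$center +
    (1 - state$center_momentum) * colMeans(tc)
  state$step <- state$step + 1L

  ps_seg <- attr(seg, "per_sample")
  rep <- structure(list(
    total = vof(total)[1], match_loss = vof(match)[1], seg_loss = vof(seg)[1],
    lambda_seg = state$lambda_seg, lr = lr, step = state$step,
    per_sample_match = 0.5 * (attr(la, "per_sample") + attr(lb, "per_sample")),
    per_sample_seg = 0.5 * (ps_seg[seq_len(N)] + ps_seg[N + seq_len(N)])),
    class = "loss_report")
  state$history[[length(state$history) + 1L]] <-
    rep[c("step", "total", "match_loss", "seg_loss", "lr")]
  rep
}

# ---- data pipeline ----------------------------------------------------------

# Per-image preparation: border crop, green extraction, resize to the model
# input size, saliency + Otsu mask. Deterministic, so the cache can be
# rebuilt identically when resuming.
prepare_image <- function(file, cfg) {
  img <- load_fundus(file)
  img <- tryCatch(crop_black_borders(img, cfg$preprocess$crop_threshold),
                  error = function(e) img)
  S <- cfg$encoder$input_size
  raster <- resize_bilinear_hwc(img$pixels / 255, S, S)
  green <- green_channel_image(round(raster[, , 2] * 255), img$id)
  sal <- compute_saliency(green, cfg$preprocess$saliency)
  mask <- binarize_saliency(sal)
  # the raster fed to augmentation is the replicated green plane in [0, 1]
  g01 <- raster[, , 2]
  list(raster = array(g01, c(S, S, 3)), mask = mask$values)
}

build_cache <- function(manifest, cfg) {
  items <- split(seq_len(nrow(manifest)), manifest$id)
  cache <- lapply(seq_len(nrow(manifest)), function(i)
    prepare_image(manifest$file[i], cfg))
  list(cache = cache, items = items)
}

# assemble one batch of augmented pairs from item ids
make_batch <- function(ids, prep, manifest, acfg, cfg, rng) {
  lapply(ids, function(it) {
    rows <- prep$items[[it]]
    use_dual <- length(rows) == 2 &&
      with_rng(rng, stats::runif(1)) < cfg$ssl$dual_pair_prob
    if (use_dual) {
      a <- prep$cache[[rows[1]]]
      b <- prep$cache[[rows[2]]]
      pa <- with_rng(rng, augment_one_view(a$raster, a$mask, acfg))
      pb <- with_rng(rng, augment_one_view(b$raster, b$mask, acfg))
      structure(list(view_a = pa$view, view_b = pb$view,
                     mask_a = pa$mask, mask_b = pb$mask,
                     source_id = it, params_a = pa$params,
                     params_b = pb$params),
                class = "augmented_view_pair")
    } else {
      r <- if (length(rows) > 1)
        rows[with_rng(rng, sample.int(length(rows), 1))] else rows[1]
      a <- prep$cache[[r]]
      make_view_pair(a$raster, a$mask, acfg, rng, source_id = it)
    }
  })
}

pretrain_augment_config <- function(cfg) {
  augment_config(crop_size = cfg$encoder$input_size,
                 flip_prob = cfg$augment$flip_prob,
                 jitter = c(brightness = cfg$augment$brightness,
                            contrast = cfg$augment$contrast,
                            saturation = cfg$augment$saturation,
                            hue = cfg$augment$hue),
                 blur_kernels = cfg$augment$blur_kernels,
                 blur_prob = cfg$augment$blur_prob,
                 crop_scale = cfg$augment$crop_scale,
                 seed = cfg$runtime$seed)
}

#' Self-supervised pretraining loop
#'
#' Runs epochs of [pretrain_step()] over a manifest of fundus images,
#' logging line-delimited JSON and writing resumable checkpoints. With a
#' fixed seed the run is bit-exactly reproducible, and resuming from a
#' checkpoint reproduces the uninterrupted loss stream.
#'
#' @param manifest data frame with columns `id`, `grade`, `view`, `file`
#'   (see [generate_dataset()]).
#' @param cfg validated configuration.
#' @param out_dir output directory for checkpoints and logs.
#' @param resume optional checkpoint path to continue from.
#' @param max_steps optional hard cap on optimizer steps (useful for
#'   smoke tests); default runs `cfg$ssl$epochs` full epochs.
#' @param checkpoint_every write a checkpoint every this many steps in
#'   addition to the end-of-run checkpoint.
#' @return path of the final checkpoint, with the `ssl_state` attached as
#'   attribute `state`.
#' @export
pretrain <- function(manifest, cfg, out_dir, resume = NULL, max_steps = NULL,
                     checkpoint_every = NULL) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  log_file <- file.path(out_dir, "train_log.jsonl")
  prep <- build_cache(manifest, cfg)
  n_items <- length(prep$items)
  bs <- cfg$ssl$batch_size
  steps_per_epoch <- n_items %/% bs
  if (steps_per_epoch < 1) stop("batch size exceeds dataset size")
  total_steps <- cfg$ssl$epochs * steps_per_epoch

  if (is.null(resume)) {
    model <- init_msssl_model(cfg)
    state <- ssl_state(model, total_steps = total_steps)
    data_rng <- msssl_rng(substream_seed(cfg$runtime$seed, "data"))
    cursor <- list(epoch = 1L, s = 1L, ord = NULL)
    if (file.exists(log_file)) unlink(log_file)
  } else {
    ck <- load_checkpoint(resume, cfg)
    state <- ck$state
    model <- state$model
    data_rng <- ck$data_rng
    cursor <- ck$cursor
  }

  acfg <- pretrain_augment_config(cfg)
  ids <- names(prep$items)
  done <- FALSE
  epoch <- cursor$epoch
  while (epoch <= cfg$ssl$epochs && !done) {
    # the shuffled order is part of the checkpoint so that an interrupted
    # epoch resumes exactly where it stopped
    ord <- if (epoch == cursor$epoch && !is.null(cursor$ord)) cursor$ord
           else with_rng(data_rng, sample(ids))
    s0 <- if (epoch == cursor$epoch) cursor$s else 1L
    for (s in seq(s0, length.out = max(steps_per_epoch - s0 + 1L, 0L))) {
      take <- ord[(s - 1) * bs + seq_len(bs)]
      batch <- make_batch(take, prep, manifest, acfg, cfg, data_rng)
      rep <- pretrain_step(batch, state)
      line <- jsonlite::toJSON(list(step = rep$step, epoch = epoch,
                                    total = rep$total, match = rep$match_loss,
                                    seg = rep$seg_loss, lr = rep$lr,
                                    m = state$m),
                               auto_unbox = TRUE, digits = NA)
      cat(line, "\n", sep = "", file = log_file, append = TRUE)
      cur <- if (s < steps_per_epoch) list(epoch = epoch, s = s + 1L, ord = ord)
             else list(epoch = epoch + 1L, s = 1L, ord = NULL)
      if (!is.null(checkpoint_every) && rep$step %% checkpoint_every == 0)
        save_checkpoint(state, data_rng, cur,
                        file.path(out_dir, sprintf("ckpt_step%05d.rds",
                                                   rep$step)))
      if (!is.null(max_steps) && state$step >= max_steps) {
        done <- TRUE
        cursor <- cur
        break
      }
    }
    if (!done) cursor <- list(epoch = epoch + 1L, s = 1L, ord = NULL)
    epoch <- epoch + 1L
  }
  path <- file.path(out_dir, "checkpoint_final.rds")
  save_checkpoint(state, data_rng, cursor, path)
  attr(path, "state") <- state
  path
}

# ---- checkpointing ----------------------------------------------------------

#' Save a training checkpoint
#'
#' Binary archive (student, teacher, center, optimizer moments, step, RNG
#' stream states, configuration) plus a JSON sidecar carrying the config
#' digest, step and seed.
#'
#' @param state an [ssl_state()].
#' @param data_rng the data-order RNG stream (or `NULL`).
#' @param cursor data-loop position (epoch, step-in-epoch, epoch order).
#' @param path output `.rds` path; the sidecar is `<path>.json`.
#' @export
save_checkpoint <- function(state, data_rng = NULL,
                            cursor = list(epoch = 1L, s = 1L, ord = NULL),
                            path) {
  model <- state$model
  obj <- list(params = model$params,
              buffers = as.list(model$buffers),
              teacher = state$teacher,
              center = state$center,
              opt = list(m = state$opt$m, v = state$opt$v, t = state$opt$t,
                         lr = state$opt$lr,
                         weight_decay = state$opt$weight_decay),
              m = state$m, tau_s = state$tau_s, tau_t = state$tau_t,
              center_momentum = state$center_momentum,
              lambda_seg = state$lambda_seg,
              step = state$step, total_steps = state$total_steps,
              history = state$history,
              cursor = cursor,
              data_rng_state = if (!is.null(data_rng)) data_rng$state else NULL,
              config = local({
                cfg <- model$config
                attributes(cfg) <- attributes(cfg)["names"]
                cfg
              }),
              digest = model$digest)
  saveRDS(obj, path)
  side <- list(digest = model$digest, step = state$step,
               seed = model$config$runtime$seed, epoch = cursor$epoch,
               n_history = length(state$history))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load a training checkpoint
#'
#' @param path `.rds` checkpoint path.
#' @param cfg optional configuration; its structural digest must match the
#'   checkpoint's (no silent shape coercion).
#' @return list with the rebuilt `state`, `model`, `data_rng`, `cursor`.
#' @export
load_checkpoint <- function(path, cfg = NULL) {
  obj <- readRDS(path)
  if (!is.null(cfg) && config_digest(cfg) != obj$digest)
    stop("checkpoint digest ", obj$digest,
         " does not match the configuration digest ", config_digest(cfg))
  cfg_full <- obj$config
  cfg_full <- validate_config(cfg_full)
  attr(cfg_full, "digest") <- obj$digest
  model <- new.env(parent = emptyenv())
  model$params <- obj$params
  model$buffers <- list2env(obj$buffers, new.env(parent = emptyenv()))
  model$config <- cfg_full
  model$digest <- obj$digest
  class(model) <- "msssl_model"
  state <- new.env(parent = emptyenv())
  state$model <- model
  state$teacher <- obj$teacher
  state$center <- obj$center
  state$m <- obj$m
  state$tau_s <- obj$tau_s
  state$tau_t <- obj$tau_t
  state$center_momentum <- obj$center_momentum
  state$lambda_seg <- obj$lambda_seg
  state$step <- obj$step
  state$total_steps <- obj$total_steps
  state$history <- obj$history
  state$opt <- adamw_state(obj$params, lr = obj$opt$lr,
                           weight_decay = obj$opt$weight_decay)
  state$opt$m <- obj$opt$m
  state$opt$v <- obj$opt$v
  state$opt$t <- obj$opt$t
  class(state) <- "ssl_state"
  data_rng <- NULL
  if (!is.null(obj$data_rng_state)) {
    data_rng <- msssl_rng(1)
    data_rng$state <- obj$data_rng_state
  }
  list(state = state, model = model, data_rng = data_rng,
       cursor = obj$cursor %||% list(epoch = 1L, s = 1L, ord = NULL))
}
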