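# Model assembly: one parameter list covering the GFE (ViT + projection
# head), the FFE (ResNet+FPN), the fusion projection and the Deep Learner
# with its segmentation head, plus the full student forward pass.

model_vit_config <- function(cfg) {
  vit_config(variant = cfg$encoder$vit_variant,
             patch_size = cfg$encoder$patch_size,
             input_size = cfg$encoder$input_size,
             embed_dim = cfg$encoder$vit_dim,
             depth = cfg$encoder$vit_depth,
             heads = cfg$encoder$vit_heads,
             proj_hidden = cfg$encoder$proj_hidden,
             proj_dim = cfg$encoder$proj_dim)
}

model_ffe_config <- function(cfg) {
  ffe_config(backbone = cfg$encoder$fpn_backbone,
             base_width = cfg$encoder$fpn_base_width,
             c_fpn = cfg$encoder$c_fpn)
}

model_dle_config <- function(cfg) {
  dle_config(layer_kind = cfg$dle$layer_kind,
             attention_position = cfg$dle$attention_position,
             n_stages = cfg$dle$n_stages)
}

#' Initialize an MsSSL model
#'
#' Builds all parameters for the configured encoder and Deep Learner. The
#' result is an environment so training updates in place.
#'
#' @param cfg validated configuration from [load_config()].
#' @param rng optional [msssl_rng()] stream for initialization.
#' @return `msssl_model` environment with `$params`, `$buffers`, `$config`.
#' @export
init_msssl_model <- function(cfg, rng = NULL) {
  rng <- rng %||% msssl_rng(substream_seed(cfg$runtime$seed, "init"))
  vit <- model_vit_config(cfg)
  ffe <- model_ffe_config(cfg)
  dle <- model_dle_config(cfg)
  c_fuse <- if (cfg$encoder$fusion == "concatenation")
    6L * ffe$c_fpn else 3L * ffe$c_fpn
  params <- with_rng(rng, {
    c(gfe_init(vit),
      ffe_init(ffe),
      fuse_proj_init(vit$embed_dim, ffe$c_fpn),
      dle_init(c_fuse, dle, prefix = "dle."))
  })
  m <- new.env(parent = emptyenv())
  m$params <- params
  m$buffers <- new.env(parent = emptyenv())
  m$config <- cfg
  m$digest <- config_digest(cfg)
  class(m) <- "msssl_model"
  m
}

#' @export
print.msssl_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<msssl_model  %d parameter tensors, %.2fM values, digest %s>\n",
              length(x$params), np / 1e6, x$digest))
  invisible(x)
}

# Full student pass: GFE -> projection, FFE -> pyramid, fusion -> DLe ->
# segmentation logits. `params` may be plain arrays (gradient-free) or
# lifted tape nodes.
student_forward <- function(x, params, cfg, buffers, training = FALSE,
                            collect_attention = FALSE) {
  vit <- model_vit_config(cfg)
  emb <- gfe_forward(x, params, vit, collect_attention = collect_attention)
  cls <- gfe_cls_token(emb)
  proj <- projection_head(cls, params, vit)
  pyr <- ffe_forward(x, params, model_ffe_config(cfg), buffers, training)
  fused <- fuse_features(upsample_to_p2(pyr), emb, params,
                         method = cfg$encoder$fusion)
  out <- dle_forward(fused, params, model_dle_config(cfg),
                     image_size = cfg$encoder$input_size)
  list(proj = proj, seg_logits = out$seg_logits, features = out$features,
       cls = cls, emb = emb)
}

# Teacher pass: only the projection output is consumed downstream, so just
# the ViT trunk and projection head are evaluated (the teacher mirrors the
# full student structure; its FFE/DLe parameters exist but are not run).
teacher_forward <- function(x, params, cfg) {
  vit <- model_vit_config(cfg)
  emb <- gfe_forward(x, params, vit)
  projection_head(gfe_cls_token(emb), params, vit)
}
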