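# Run configuration: nested defaults (the best ablation settings:
# fine-grained saliency, ResNet50 FPN, ViT-S-p16, addition fusion,
# transposed-conv DLe with CBAM at the end), YAML loading with strict
# validation, and a canonical digest that binds checkpoints to the encoder
# structure they were trained with.

config_enums <- list(
  "preprocess.saliency" = c("fine_grained", "spectral"),
  "encoder.vit_variant" = c("S", "B"),
  "encoder.fpn_backbone" = c("resnet50", "resnet18"),
  "encoder.fusion" = c("addition", "concatenation", "multiplication"),
  "dle.layer_kind" = c("transposed2d", "conv2d", "conv1d"),
  "dle.attention_position" = c("last", "first", "none"),
  "eval.head" = c("full", "gfe")
)

#' Default run configuration
#'
#' @return nested list with blocks `data`, `preprocess`, `augment`,
#'   `encoder`, `dle`, `ssl`, `eval`, `runtime`.
#' @export
msssl_default_config <- function() {
  list(
    data = list(dir = ".", manifest = "manifest.csv"),
    preprocess = list(saliency = "fine_grained", crop_threshold = 10),
    augment = list(crop_size = 224, flip_prob = 0.5,
                   brightness = 0.4, contrast = 0.4, saturation = 0.4,
                   hue = 0.1, blur_kernels = c(3, 5, 7, 9), blur_prob = 0.5,
                   crop_scale = c(0.3, 1.0)),
    encoder = list(input_size = 224, vit_variant = "S", patch_size = 16,
                   vit_depth = NULL, vit_dim = NULL, vit_heads = NULL,
                   proj_hidden = 2048, proj_dim = 256,
                   fpn_backbone = "resnet50", fpn_base_width = 64,
                   c_fpn = 256, fusion = "addition"),
    dle = list(layer_kind = "transposed2d", attention_position = "last",
               n_stages = 2),
    ssl = list(m = 0.996, tau_s = 0.1, tau_t = 0.04, center_momentum = 0.9,
               lambda_seg = 1.0, lr = 5e-4, weight_decay = 0.04,
               epochs = 5, batch_size = 8, warmup_steps = 10,
               dual_pair_prob = 0.5),
    eval = list(fractions = c(0.70, 0.15, 0.15), seed = 1, stratified = TRUE,
                head = "full", epochs = 200, lr = 0.01),
    runtime = list(seed = 1, deterministic = TRUE, out_dir = "msssl_out")
  )
}

merge_config <- function(defaults, user, path = character()) {
  if (is.null(user)) return(defaults)
  if (!is.list(user))
    stop("config block is not a mapping at: ",
         paste(path, collapse = "."), call. = FALSE)
  bad <- setdiff(names(user), names(defaults))
  if (length(bad))
    stop("unknown config key: ",
         paste(c(path, bad[1]), collapse = "."), call. = FALSE)
  out <- defaults
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      out[[nm]] <- merge_config(defaults[[nm]], user[[nm]], c(path, nm))
    } else {
      val <- user[[nm]]
      if (is.list(val)) val <- unlist(val)
      out[nm] <- list(val) # NULL-safe: keep the key when the value is NULL
    }
  }
  out
}

validate_config <- function(cfg) {
  for (key in names(config_enums)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    val <- cfg[[parts[1]]][[parts[2]]]
    if (!is.character(val) || length(val) != 1 ||
        !val %in% config_enums[[key]])
      stop("invalid value for ", key, ": ",
           paste(val, collapse = "/"), " (allowed: ",
           paste(config_enums[[key]], collapse = ", "), ")", call. = FALSE)
  }
  fr <- cfg$eval$fractions
  if (length(fr) != 3 || any(fr <= 0) || abs(sum(fr) - 1) > 1e-9)
    stop("eval.fractions must be 3 positive numbers summing to 1",
         call. = FALSE)
  if (cfg$ssl$m < 0 || cfg$ssl$m > 1)
    stop("ssl.m must be in [0, 1]", call. = FALSE)
  if (cfg$ssl$tau_t >= cfg$ssl$tau_s)
    stop("teacher temperature must be below student temperature (sharpening)",
         call. = FALSE)
  if (cfg$ssl$lambda_seg < 0) stop("ssl.lambda_seg must be >= 0", call. = FALSE)
  if (cfg$encoder$input_size %% cfg$encoder$patch_size != 0)
    stop("encoder.input_size must be divisible by encoder.patch_size",
         call. = FALSE)
  if (cfg$encoder$input_size %% 32 != 0)
    stop("encoder.input_size must be divisible by 32", call. = FALSE)
  cfg
}

#' Load and validate a YAML run configuration
#'
#' Unknown keys and invalid enum values are rejected with the offending
#' path; an empty file yields the full default configuration.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides optional nested list merged over the file.
#' @return validated config with attribute `digest`.
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  cfg <- msssl_default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user)
  }
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  cfg <- validate_config(cfg)
  attr(cfg, "digest") <- config_digest(cfg)
  cfg
}

#' Serialize a configuration back to YAML
#' @param cfg configuration list.
#' @param path output file.
#' @export
save_config <- function(cfg, path) {
  attributes(cfg) <- attributes(cfg)["names"]
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# canonical serialized form: sorted keys, fixed precision
canonical_json <- function(x) {
  if (is.list(x)) {
    nms <- sort(names(x))
    inner <- vapply(nms, function(nm) {
      paste0("\"", nm, "\":", canonical_json(x[[nm]]))
    }, character(1))
    paste0("{", paste(inner, collapse = ","), "}")
  } else if (is.null(x)) {
    "null"
  } else if (is.character(x)) {
    paste0("[", paste0("\"", x, "\"", collapse = ","), "]")
  } else {
    paste0("[", paste(format(x, digits = 12), collapse = ","), "]")
  }
}

#' Digest of the structural part of a configuration
#'
#' Only blocks that change parameter shapes or semantics (encoder, dle,
#' preprocess) enter the digest; a checkpoint evaluated under a structurally
#' different configuration is rejected rather than silently coerced.
#'
#' @param cfg configuration list.
#' @return 8-hex-digit string.
#' @export
config_digest <- function(cfg) {
  fnv1a32(canonical_json(cfg[c("encoder", "dle", "preprocess")]))
}
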