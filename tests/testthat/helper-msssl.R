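# Shared fixtures: a reduced encoder configuration, a cached synthetic
# dataset, and a central-difference gradient checker. Everything is built
# in code at test time; nothing is stored on disk beyond tempdir().

ns <- asNamespace("msssl")

# central-difference gradient of a scalar-valued function
num_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

expect_grad <- function(f_node, x, tol = 1e-6, eps = 1e-5) {
  lx <- ns$ad_leaf(x)
  out <- f_node(lx)
  ns$ad_backward(out)
  gn <- num_grad(function(z) ns$vof(f_node(z)), x, eps)
  expect_lt(max(abs(lx$grad - gn)) / max(1, max(abs(gn))), tol)
}

# reduced encoder: 64 px input, depth-2/64-d ViT, narrow resnet18 trunk
# with a 64-channel pyramid
tiny_overrides <- function(seed = 0) {
  list(
    encoder = list(input_size = 64, vit_depth = 2, vit_dim = 64,
                   vit_heads = 4, proj_hidden = 128, proj_dim = 32,
                   fpn_backbone = "resnet18", fpn_base_width = 16,
                   c_fpn = 64),
    augment = list(crop_size = 64),
    ssl = list(batch_size = 8, epochs = 5),
    runtime = list(seed = seed))
}

tiny_config <- function(seed = 0) load_config(overrides = tiny_overrides(seed))

# an even smaller encoder for shape/gradient tests
micro_config <- function(seed = 0) {
  load_config(overrides = list(
    encoder = list(input_size = 64, vit_depth = 1, vit_dim = 32,
                   vit_heads = 2, proj_hidden = 64, proj_dim = 16,
                   fpn_backbone = "resnet18", fpn_base_width = 8,
                   c_fpn = 16),
    augment = list(crop_size = 64),
    ssl = list(batch_size = 4, epochs = 1),
    runtime = list(seed = seed)))
}

# cached small synthetic dataset (20 eyes, 64 px) shared across test files
local_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "msssl_testdata")
      cfg <- synthetic_config(image_size = 64, seed = 2,
                              lesion_rate_per_grade = c(0, 4, 10, 18, 30))
      cache <<- list(manifest = generate_dataset(cfg, 4, dir), cfg = cfg,
                     dir = dir)
    }
    cache
  }
})

# a fixed augmented batch for training-step tests
make_fixed_batch <- function(n = 8, size = 64, seed = 11) {
  scfg <- synthetic_config(image_size = 96, seed = 5)
  rng <- msssl_rng(seed)
  acfg <- augment_config(crop_size = size, seed = 3)
  lapply(seq_len(n), function(i) {
    img <- generate_fundus(scfg, (i - 1) %% 5, rng, id = paste0("im", i))
    g <- extract_green_channel(img)
    mask <- binarize_saliency(fine_grained_saliency(g))
    raster <- array(g$pixels / 255, c(dim(g$pixels), 3))
    make_view_pair(raster, mask, acfg, rng, source_id = paste0("im", i))
  })
}
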