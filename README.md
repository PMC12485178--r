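# msssl — multi-scale self-supervised pretraining for diabetic-retinopathy grading

Grading diabetic retinopathy (DR) means placing a color fundus photograph on
a 5-step ordinal severity scale (0 = no disease … 4 = proliferative).
Labeled fundus data are scarce, and features transferred from natural-image
corpora miss the lesion-scale detail grading depends on. `msssl` implements
a momentum-encoder self-supervised framework specialized for fundus
photographs, for researchers who want to study or extend this family of
methods in R at desk scale, with every component testable offline.

The core pieces:

- **Multi-scale encoder** — a vision-transformer global branch (GFE) fused
  with a ResNet + feature-pyramid fine-grained branch (FFE; levels P2/P3/P5
  at strides 4/8/32, upsampled to the P2 grid), combined by elementwise
  addition (concatenation and multiplication are configurable
  alternatives).
- **Deep Learner (DLe)** — staged stride-2 transposed convolutions with
  ReLU, ending in a convolutional block attention module (CBAM), plus a
  segmentation head at image resolution.
- **Two pretraining objectives** — self-distillation against an
  exponential-moving-average teacher (no negative pairs):
  cross-entropy between the student distribution `softmax(s/τ_s)` and the
  centered, sharpened teacher target `softmax((t − center)/τ_t)`,
  symmetrized over two SimCLR-style augmented views; plus a saliency
  segmentation loss (BCE + soft Dice) against Otsu-binarized green-channel
  saliency masks. `total = match + λ_seg · seg`.
- **Fundus preprocessing** — green-channel extraction, black-border
  cropping, spectral-residual and fine-grained (center–surround) saliency.
- **Evaluation protocols** — stratified 70/15/15 splits, frozen linear
  evaluation and fine-tuning, quadratic weighted kappa
  (`κ = 1 − Σ w_ij O_ij / Σ w_ij E_ij`, `w_ij = (i−j)²/(K−1)²`),
  weighted/macro/micro F1, confusion matrices, and global-token
  attention-map visualization.
- **Synthetic fundus generator** — green-dominant retina disc, optic-disc
  highlight, vessel tree, and Poisson lesion counts increasing with grade,
  in single- and dual-view variants, so the whole pipeline runs with no
  download.

The networks, reverse-mode autodiff and AdamW optimizer are implemented in
the package itself (R with C++/Armadillo convolution kernels); every layer's
gradient is validated against finite differences in the test suite.

## Worked example

Generate a labeled synthetic dataset, pretrain briefly, linear-probe a
held-out split, and look at an attention map:

```r
library(msssl)

cfg_data <- synthetic_config(image_size = 64, seed = 7,
                             lesion_rate_per_grade = c(0, 4, 10, 18, 30))
manifest <- generate_dataset(cfg_data, 20, file.path(tempdir(), "fundus_demo"))

cfg <- load_config(overrides = list(
  encoder = list(input_size = 64, vit_depth = 2, vit_dim = 64, vit_heads = 4,
                 proj_hidden = 128, proj_dim = 32,
                 fpn_backbone = "resnet18", fpn_base_width = 16, c_fpn = 64),
  augment = list(crop_size = 64),
  ssl = list(batch_size = 8, epochs = 3),
  runtime = list(seed = 1)))
set_global_determinism(1)
ckpt <- pretrain(manifest, cfg, file.path(tempdir(), "demo_run"))

splits <- split_dataset(manifest, split_spec(seed = 1))
report <- linear_eval(ckpt, splits, cfg)
report
#> <metrics_report  kappa=0.5161  acc=33.33%  F1w=27.27%  F1M=27.27%  F1m=33.33%>
report$confusion
#>      pred
#> truth 0 1 2 3 4
#>     0 1 2 0 0 0
#>     1 0 2 1 0 0
#>     2 2 1 0 0 0
#>     3 0 2 0 0 1
#>     4 0 1 0 0 2

att <- attention_map(ckpt, generate_fundus(cfg_data, 3, msssl_rng(3)),
                     size = 256)
dim(att$grid)
#> [1] 16 16
```

After only three epochs on 100 tiny images the frozen features already
order the grades far better than chance (quadratic weighted κ = 0.52 on 15
held-out eyes, against κ ≈ 0 for shuffled labels; micro-F1 equals accuracy
by construction in this single-label setting). The confusion matrix shows
the errors concentrating near the diagonal, which is what the quadratic
kappa rewards; accuracy itself is noisy at this demo size. The attention grid is the final-layer
global-token attention averaged over heads — at 256 px with 16-px patches,
a 16×16 map.

A thin command-line wrapper ships in `inst/cli/msssl`
(`synth | preprocess | pretrain | linear-eval | finetune | evaluate |
visualize-attention`), each command a direct call into the functions above.

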