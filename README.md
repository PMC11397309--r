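# leafpad

Diffusion-augmented, parallel-attention Transformer pipeline for
plant-leaf disease classification, implemented end to end in base R.

Plant pathologists and agricultural remote-sensing groups increasingly
classify foliar disease from RGB photographs with Transformer
classifiers, augmented by generative models when field data are scarce.
leafpad is a reference implementation of that full pipeline at desk
scale: classical image enhancement, CutOut/CutMix/Mosaic augmentation
with soft-label bookkeeping, a denoising-diffusion generator, a
parallel-attention Transformer classifier with a reconstruction head, a
composite classification/reconstruction/adversarial objective, and the
splitting/cross-validation/metrics machinery around it. Because the kind
of field dataset such studies use (six jujube-disease classes) is rarely
deposited, the package also ships a seeded class-conditional synthetic
leaf generator so every stage is testable without external data.

## The model

An image is cut into `p × p` patches, embedded to width
`d_model = heads × head_dim` (default 512 = 8 × 64), and passed through
12 pre-norm encoder blocks. Each block runs N parallel attention branches
on the same input,

    Attention_i(Q, K, V) = softmax(Q_i K_i' / sqrt(d_k)) V_i ,   i = 1..N

whose outputs are fused by weighted summation (heads within a branch are
concatenated to 512; branches across are weighted-summed), followed by a
512→2048→ReLU→512 feed-forward net. Mean-pooled tokens give K class
logits; a linear head maps the same tokens back to patches as a
reconstruction. Training minimizes

    L = λ_cls · L_cls + λ_recon · L_recon + λ_adv · L_adv

(soft-label cross-entropy, reconstruction MSE, and a non-saturating
adversarial term against a small strided-conv discriminator), with
defaults (1.0, 0.5, 0.1), learning rate 0.001 decayed 10% every 10
epochs, dropout 0.1 and L2 1e-4.

The diffusion generator runs a 64-step noising chain
`q(x_t | x_{t-1}) = N(α_t x_{t-1}, (1−α_t) I)` and a convolutional
ε-prediction denoiser (128 internal channels, 3×3 kernels), trained on a
variational-lower-bound objective and used for label-preserving
augmentation round trips. All network forward *and* backward passes are
hand-written vectorized base R, validated by finite-difference gradient
checks.

## Worked example

Generate a synthetic two-class dataset, train a tiny parallel-attention
model, and evaluate it:

```r
library(leafpad)

specs <- default_leaf_specs()[c("black_spot", "rust")]
dsd <- generate_dataset(specs, n_per_class = 100, size = 32, seed = 1,
                        out_dir = "leaves")
m <- split_manifest(dsd$manifest, c(0.7, 0.15, 0.15), seed = 1)

cfg <- leafpad_config(
  model = list(layers = 2L, heads = 2L, head_dim = 16L, ffn_hidden = 64L,
               image_size = 32L, n_classes = 2L),
  train = list(batch = 16L),
  loss  = list(mode = "parallel"),
  augment = list(p = 0))

fit <- train_classifier(m, cfg, epochs = 30, seed = 0, images = dsd$images)
fit
#> <leafpad_model: 2-layer parallel-attention Transformer, 3 branches, parallel loss>
#>   d_model 32 (2 heads x 16), 16 tokens of 8x8 patches, 2 classes
#>   47144 parameters; trained 30 epochs; best val accuracy 1.0000

evaluate_model(fit, m, split = "test", images = dsd$images)
#> <metrics_report: n = 30, accuracy = 1.0000>
#> macro P = 1.0000, R = 1.0000, F1 = 1.0000
#>             pred
#> true         black_spot rust
#>   black_spot         15    0
#>   rust                0   15
```

The model separates the two lesion-color classes perfectly: the
confusion matrix is diagonal, so precision, recall, F1 and accuracy are
all 1 on the held-out test split. On harder settings (six classes with
lesion colors pulled toward the leaf color via
`default_leaf_specs(difficulty = 0.6)`), accuracies drop and the
composite loss's advantage over plain cross-entropy becomes visible.

The enhancement, augmentation and diffusion stages are exposed directly
(`equalize_hist()`, `cutmix()`, `make_schedule()`, `sample_diffusion()`,
…), and `inst/cli/leafpad.R` wraps the pipeline for shell use
(`synth`, `enhance`, `augment`, `train`, `evaluate`, `sample`).

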