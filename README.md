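# octvae

Predicting 6-month postoperative macular OCT B-scans from preoperative
volume scans after full-thickness macular hole (FTMH) surgery, with a
conditional variational autoencoder — plus everything around it: synthetic
retinal phantoms with known ground truth, RPE-based rigid volume
registration, conditioned preprocessing/augmentation, and a quantitative
agreement suite.

## Who this is for

Researchers in retinal image analysis who want a fully reproducible,
self-contained reference implementation of an OCT image-to-image
prediction pipeline. No patient data is included or required: a phantom
module generates paired pre/postoperative volumes (ten retinal bands,
foveal pit, FTMH crater, optional ELM/EZ defects, known rigid
misalignment, noise) so every stage runs and is tested end to end.

## The core model

The generator is a conditional VAE. The encoder maps a preoperative
224 x 224 slice `x` and a one-hot condition `c` (its distance band from
the fovea) to a Gaussian posterior `q(z | x, c) = N(mu, diag(exp(logvar)))`
through four conv blocks (3x3, stride 1, pad 1, channels doubling, each
with batch norm, leaky ReLU, dropout, 2x max pooling) and five fully
connected layers. The sampler draws `z = mu + exp(logvar/2) * eps`; the
decoder mirrors the encoder with nearest-neighbour unpooling and a sigmoid
output. Training minimises

    L(epoch) = Recon(epoch) + beta(epoch) * KL(q(z|x,c) || N(0, I))

with `Recon = BCE + lambda_s (1 - MS-SSIM)` up to the switch epoch
(400/600 at full scale) and a perceptual feature distance afterwards, and
`beta` ramping linearly from 0 to 1 over the warm-up. Inference is
deterministic (`z = mu`). Registration is closed-form orthogonal
Procrustes on the RPE surface point clouds in physical micrometres;
agreement is quantified by neurosensory-area accuracy/precision/recall/F1,
FH/MFT/MNPT/MTPT thickness profiles, percentage Bland–Altman 95% limits of
agreement with the ±30% rule, and ELM/EZ continuity. There is no deep
learning framework dependency — the package carries its own small
reverse-mode autodiff tape, validated against finite differences.

## Worked example

```r
library(octvae)

# one miniature phantom case with a known 1.2-degree / 60 um misalignment
spec <- phantom_spec(n_slices = 24, n_axial = 480, n_lateral = 64,
                     scan_width = 3000, axial_pitch = 2.6, noise_sd = 0,
                     misalignment = rt_from_angles(c(1.2, -2, 1.8),
                                                   c(60, -40, 90),
                                                   center = c(1500, 623, 1500)))
case <- make_phantom_case(spec)

reg <- register_volumes(case$pre, case$post)
cat(sprintf("RPE residual: %.1f -> %.2f um RMS (%.2f axial px)\n",
            reg$rms_before_um, reg$rms_after_um, reg$rms_after_px))
#> RPE residual: 53.9 -> 0.63 um RMS (0.24 axial px)
```

The residual drops from tens of micrometres to a fraction of an axial
pixel: the preoperative volume now sits on the postoperative RPE surface,
which surgery does not alter, so the pair is anatomically comparable.

Training and evaluating the reduced cVAE study (20 phantom cases, 64 px):

```r
cohort <- make_cohort(20, phantom_spec(n_slices = 16, n_axial = 192,
                                       n_lateral = 96, scan_width = 2400,
                                       axial_pitch = 3.2), seed = 3,
                      rot_max_deg = 0, trans_max_um = 0)
split <- split_cases(sprintf("c%03d", 1:20), seed = 4)   # 14 / 3 / 3
manifest <- build_dataset(cohort, split, out_dir = "ds", window = 4,
                          crop_size = 128, out_size = 64)
model <- octvae(load_slice_pairs(manifest),
                octvae_config(image_size = 64, base_channels = 8,
                              latent_dim = 32,
                              fc_hidden = c(256, 128, 64, 64),
                              batch_size = 32, max_epochs = 12,
                              recon_switch_epoch = 12, kld_warmup = 8,
                              lr = 1e-3, seed = 11))
print(model)
#> Conditional VAE (64x64, C=8, d=32)
#>   trained 12 epochs; best epoch 11 (val loss 0.8081)
```

Validation loss falls from 0.92 (epoch 1) to 0.81; the trained predictor
reaches a mean neurosensory-area F1 of 0.93 on held-out phantoms versus
0.56 for untrained weights — the model has learned the pre-to-post
mapping, not just an intensity prior.

At full scale the bookkeeping reproduces the modelled study exactly:

```r
cohort <- make_cohort(150, phantom_spec(), seed = 1, render = FALSE)
split <- split_cases(sprintf("case%03d", 1:150), seed = 2)  # 100 / 25 / 25
m <- build_dataset(cohort, split, window = 200, write_images = FALSE)
table(m$split)        # 120000 train / 5000 validation / 5000 test pairs
table(m$condition[m$split == "train"])
#>     0     1     2     3
#> 25800 25200 25800 43200
```

A thin CLI over these functions lives in `inst/cli/octvae-cli.R`
(`simulate`, `register`, `pipeline`, `infer` subcommands).

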