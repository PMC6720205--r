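---
title: "Methods: a dense GAN for embryo-like images and its evaluation suite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a dense GAN for embryo-like images and its evaluation suite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryogan)
```

## The problem and the model

Early-cleavage embryo microscopy frames are grayscale, low-contrast scenes:
a bright-rimmed circular culture well on a dark field, containing one, two
or four translucent cells whose membranes are slightly darker than their
interiors. `embryogan` trains a generative adversarial pair to synthesize
such frames and provides a battery of statistics for judging the result.

The discriminator is a six-layer fully connected classifier (flatten →
dense → LeakyReLU(0.2) → dense → LeakyReLU(0.2) → dense(1, sigmoid)); the
generator is an eleven-layer map from a 100-dimensional standard-normal
latent vector through three dense → LeakyReLU(0.2) → batch-norm(momentum
0.8) stages to a dense tanh layer reshaped into the output image. Both are
plain matrix code: `net_forward()` / `net_backward()` implement the forward
passes and reverse-mode gradients, and the test suite checks the analytic
gradients against central finite differences at 1e-4 relative error.

Training is the standard alternating scheme: per iteration the
discriminator takes one Adam step on a combined batch of `batch_size` real
images labeled 1 and `batch_size` generated images labeled 0 under binary
cross-entropy, then the generator takes one Adam step through the frozen
discriminator. The generator's default objective is the non-saturating
surrogate — the cross-entropy of `D(G(z))` against label 1 — because the
literal `log(1 - D(G(z)))` form starves the generator of gradient early in
training when the discriminator wins easily; the literal form remains
available (`g_loss = "saturating"`) for comparison.

## Tunable parameters

* `lr = 2e-5`, `beta1 = 0.7` — the reference Adam settings for full-scale
  runs (200,000 iterations, batch 256, 200×200 images). `beta2 = 0.999`
  and `eps = 1e-8` are the conventional defaults; the same settings drive
  both networks.
* `momentum = 0.8` — batch-norm running-average weight
  (`running <- 0.8 * running + 0.2 * batch`); biased (1/N) batch variance
  is used both for normalization and for the running average.
* LeakyReLU `alpha = 0.2` throughout.
* Dense widths default to 512/256 (discriminator) and 256/512/1024
  (generator). Widths are not dictated by the architecture's published
  layer counts, so they are config-overridable; the defaults are the
  canonical dense-GAN configuration consistent with every stated layer
  detail.
* Images are stored in `[0, 255]` and mapped affinely to `[-1, 1]` for the
  networks, pairing with the tanh output; `denormalize_image()` inverts
  and clamps.
* Predicted probabilities are clipped to `[1e-7, 1 - 1e-7]` inside the
  cross-entropy, which bounds the loss and its gradient on confident
  mistakes.

## Desk-scale study conditions

Full-scale training is a multi-hour GPU-class workload, so the package's
own experiments (tests and `scripts/acceptance.R`) run a scaled-down
configuration chosen once: 64×64 one-cell phantoms (120 training images),
batch 32, 2500 iterations, widths 128/64 and 64/128/256, and `lr = 2e-4`.
The learning rate is raised from the full-scale 2e-5 because that value is
matched to a 200,000-iteration schedule; shortening the schedule by two
orders of magnitude calls for the standard dense-GAN rate of 2e-4. Under
these conditions the run finishes in a few minutes on one CPU and exhibits
the qualitative signatures of a coupled adversarial pair: finite losses
throughout, a positive pairwise-diversity (mode-collapse) score, and a
generated-vs-real average-histogram correlation exceeding the
generated-vs-noise correlation.

## The phantom generator

`generate_phantom()` draws, in order: a uniform background (intensity 45),
the well interior (95) and its bright rim (225, width 1% of the frame),
then each cell as a translucent disc (+24 over the well medium) with a
darker membrane annulus (interior minus `rim_contrast = 60`, width 12% of
the cell radius), a zero-mean horizontal illumination ramp (amplitude 8),
additive Gaussian noise (`noise_sigma = 6`) and salt-and-pepper corruption
(`salt_pepper_frac = 0.002`). Cell radii are drawn from 18–32% of the well
radius, centers uniformly in the well with the whole disc kept inside;
overlapping cells are permitted by default because overlap is a realistic
stage of cell division, and `allow_overlap = FALSE` rejection-samples
disjoint placements. Every image carries its ground-truth mask and
geometry as attributes, and each dataset image derives its seed from
`(base_seed, class, index)`, so any subset regenerates independently.

The phantom emulates first- and second-order image statistics — the
intensity layers the histogram metrics see and the local texture the GLCM
sees — not biology: there is no optics model, no chromatin texture, no
focal drift, and the background is untextured (real dish background is
undocumented, so it is left unconstrained). Passing tests therefore
demonstrate that the pipeline's mechanics are correct on data of this
structure, not that the GAN reaches clinical realism on real footage.

## Evaluation suite: numerical choices

* **Histograms** — 256 bins over the declared range (native 8-bit
  resolution); per-image histograms are probability-normalized and then
  averaged, so the set histogram sums to 1. The intersection of two
  probability histograms is bounded by 1; a `sum2` compatibility mode
  reproduces pipelines that normalize over the pair (where identical
  histograms intersect at 2).
* **Chi-square** — bins with zero reference mass are skipped rather than
  divided by; this is the common implementation convention and is the one
  asymmetry the identity-padding invariant documents.
* **Bhattacharyya** — `sqrt(1 - sum(sqrt(H1 H2)) / sqrt(mean(H1) mean(H2)
  N^2))`, with the inner term clamped to `[0, 1]` against floating-point
  drift; for probability histograms the normalizer is exactly 1.
* **GLCM** — quantization to 64 levels (configurable), distance 1, angles
  {0°, 45°, 90°, 135°}, symmetric counting, per-angle normalization, and
  angle averaging: Haralick's original protocol. Entropies use natural
  logarithms with `0 log 0 = 0`.
* **Sum variance** — computed about the sum average. The original listing
  of the 14 statistics references the sum entropy at this spot, which is
  widely treated as a typographical slip; the sum-average convention is
  used and stated here.
* **Degenerate textures** — a single-cell GLCM (constant image) has zero
  marginal variance: energy is 1 and the entropies 0, while correlation
  and the maximal correlation coefficient are undefined and returned as
  `NA` with a warning rather than silently zeroed.
* **t-tests** — Welch's unequal-variance test, two-sided, per feature,
  flagged at `alpha = 0.01`; the pooled-variance variant is available.
  Features that are constant within both groups are reported explicitly
  (`t = 0, p = 1` when equal; significant when unequal) instead of
  erroring.
* **PCA** — covariance-form `prcomp` fitted separately per set; the
  comparison statistic is the absolute Pearson correlation of the two PC1
  loading vectors, since per-image score vectors from different sets have
  no pairing and an eigenvector's sign is arbitrary. Features undefined
  (`NA`) in either set are dropped from both before fitting.
* **Expert tally** — TRR is `100 * accepted / generated` per class and the
  overall misclassification pools classes; reported percentages use
  half-up rounding to one decimal. Judgment CSVs with several judges per
  image aggregate by strict per-image majority before tallying.
* **Rotation augmentation** — exact 90° grid rotations (pixel
  permutations, hence lossless), applied after any resizing since grid
  rotations and block means commute.
* **Resizing** — 3×3 block mean for the 600 → 200 path (any exact integer
  factor), bilinear for other ratios; upscaling is refused unless
  requested. The block mean was chosen because it is deterministic and
  directly checkable against brute-force averaging.

## Determinism and checkpointing

A single seed drives phantom generation, weight initialization, latent
draws and batch shuffling through derived streams. Training is bit-for-bit
reproducible single-threaded, and a `train_gan()` result can be resumed:
the returned state carries the RNG state, so training i₁ iterations,
stopping, and training i₂ more reproduces the uninterrupted (i₁+i₂) loss
history exactly — the test suite asserts identity, not tolerance.
Generator checkpoints serialize to a versioned JSON container (spec header
plus flat parameter arrays at full double precision).

## Known limitations

* Dense (fully connected) networks only; no convolutional variant, so
  full-resolution training is compute-hungry and the generated texture is
  less spatially coherent than a DCGAN's.
* The 2500-iteration desk-scale run demonstrates adversarial coupling, not
  convergence: its histogram correlation is far below what a full run
  reaches, and Haralick features still separate real from generated.
* One unconditional network serves all classes (per-class runs are a
  one-line loop over configs); there is no conditional label input.
* The trainer is single-threaded R; at 200×200 full scale a long schedule
  is a matter of hours-to-days on CPU.
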