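---
title: "Methods: multimodal pain assessment from facial video and heart rate"
author: "PainFusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal pain assessment from facial video and heart rate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PainFusion)
```

# The problem and the model

Automatic acute-pain assessment scores short stimulation sessions --- here
5.5 s of facial video at 25 FPS paired with single-lead ECG at 512 Hz ---
into five calibrated intensity classes (NP, P1--P4) or the binary contrast
NP vs P4. PainFusion implements a four-module transformer framework for this
task, plus everything needed to exercise it end to end on synthetic data:

1. **Heart-rate extraction.** Pan-Tompkins QRS detection (5--15 Hz
   band-pass, derivative, squaring, 150 ms moving-window integration,
   adaptive signal/noise thresholds with search-back and T-wave
   discrimination) yields R-peak times; the mean inter-beat interval
   $\mu = \frac{1}{n}\sum_i (RR_{i+1} - RR_i)$ (in samples) gives the heart
   rate $HR = 60\,FS/\mu$, computed per one-second segment to produce a
   $\theta$-point BPM vector ($\theta = 5$ for 5.5 s records).
2. **Spatial encoder.** Each 448x448 face crop becomes five 224x224 images
   (the resized full frame and the four quadrant tiles). A
   transformer-in-transformer encoder --- 196 patches of 16x16 pixels, each
   split into 16 sub-patches of 4x4, inner/outer encoders with 4 and 10
   heads, 12 blocks, width $d = 100$ --- embeds each image; the frame
   embedding is $D = d_{full} + c\,(d_{t1}+d_{t2}+d_{t3}+d_{t4})$ with
   $c = 0.1$, and frame embeddings concatenate into the session embedding
   $VD$ of length $N = d \cdot f$.
3. **Heart-rate encoder.** The BPM vector, with Fourier position features,
   is projected to width 512; a 4-vector learned latent array cross-attends
   once (1 head, depth 1) and flattens to a 2048-d embedding, which bicubic
   interpolation expands to length $N$ for fusion by element-wise addition.
4. **Temporal classifier.** The fused embedding is sliced into 100-wide
   tokens (restoring the per-frame structure); a 32-vector latent array
   cross-attends once (1 head) and is refined by three 8-head
   self-attention blocks (width 128), each followed by a GELU FCN;
   mean-pooled latents feed the linear class head.

During training only, latent-space augmentations perturb the embedding: the
learned **AugmNet** bottleneck (encoder/decoder of two fully connected
layers each, ELU after every layer; exact passthrough at inference),
**Basic** (polarity inversion + relative-scale Gaussian noise) and
**Masking** (zeroing one contiguous span of 10--20% of the embedding).

# Parameter budgets and the free hyperparameters

The published architecture fixes widths, head counts and depths but leaves
the inner token width, FCN hidden widths, latent counts and Fourier band
counts open. We fixed them once against the published per-module parameter
budgets, which the instantiated modules reproduce exactly
(`modelSummary()`):

| module | fixed by the architecture | chosen here | parameters |
|---|---|---|---|
| Spatial | p=16, s=4, d=100, 4/10 heads, depth 12 | inner width 24, FCN hidden 96 / 586 | 2.57 M |
| HR encoder | width 512, 1 cross head, depth 1, 2048-d out | 4 latents, 16 bands, FCN hidden 3245 | 4.40 M |
| AugmNet | 2+2 FC layers, ELU | widths N→36→172→36→N at N=13,800 | 1.02 M |
| Temporal | width 128, 1+3 blocks, 1/8 heads | 32 latents, 16 bands, FCN hidden 1304 | 1.63 M |

Totals: 9.62 M, and 8.60 M at inference (AugmNet is training-only). Two
of these choices deserve comment: an FCN hidden width near the conventional
4x multiple (2048) would leave the heart-rate encoder at 3.17 M, so the
hidden width is 3245 (about 6.3x); and a symmetric 36/36 AugmNet bottleneck
gives 1.01 M, so the central code is widened to 172. FLOP figures from the
analytic counter (2mnk per matrix product, one forward pass at the default
session shape) are reported alongside but depend on the counting
convention; they are informational, not calibrated.

A handful of printed statements are internally tense, resolved as follows:

* The video embedding length is taken as $N = d \cdot f = 13{,}800$ from
  the explicit concatenation over $f = 138$ frames, not the alternative
  phrase "$d \times FPS$" (2,500), which is inconsistent with per-frame
  concatenation.
* The attention scaling is the standard
  $\mathrm{softmax}(QK^\top/\sqrt{d_k})V$; the printed formula places
  $d_k$ ambiguously but cites the standard dot-product attention.
* The uncertainty-weighted multi-task objective is implemented as
  $\sum_i [e^{-w_i} L_i + w_i]$. The printed sign ($e^{+w}L + w$) is
  unbounded below in $w$ and contradicts the cited homoscedastic
  uncertainty method; with the corrected sign the per-task optimum is
  $w_i^* = \log L_i$, which the tests verify analytically.
* "1 cross-attention block with a total depth of 1, followed by 3
  self-attention blocks" is read as a single pass of the 1+3 stack.
* The class token provides the d-dimensional readout of the spatial
  encoder (the cited architecture uses one; the text is silent), and one
  shared encoder processes all five images of a frame --- separate towers
  would multiply the parameter count far past its budget.

# Numerical conventions

* **Zero-phase filtering.** The band-pass and derivative stages are
  zero-phase (forward-backward Butterworth; symmetric derivative kernel) so
  detected R indices stay on the raw sample axis, which the mean-IBI
  formula requires.
* **Segment attribution.** An inter-beat interval belongs to the 1-s
  segment its earlier peak falls in (half-open `[k*fs, (k+1)*fs)`).
  A segment with no attributable interval --- the "fewer than two usable
  beats" case in which the mean-IBI formula is undefined --- is filled with
  the mean of the nearest computed neighbours (single nearest at the
  boundaries); a record with no computable segment raises an error rather
  than fabricating a rate.
* **Detector constants** follow the classical description: 0.125/0.875
  threshold updates, search-back at half threshold after 1.66x the running
  RR average, 360 ms T-wave window with the half-slope rule, 200 ms
  refractory period. Candidate peaks additionally pass a non-maximum
  suppression at the refractory distance so noise bumps riding a QRS flank
  cannot pre-empt the true beat.
* **Bicubic resampling** uses the Keys kernel ($a = -0.5$), half-pixel
  centres and edge replication, normalised so constants are preserved
  exactly and same-size resampling is the identity. The 1-D embedding is
  arranged row-major on a 32x64 grid before expansion (bicubic
  interpolation is inherently 2-D; the grid shape is a recorded
  convention).
* **Tiles and patches** use half-open pixel ranges, origin top-left, raster
  order (TL, TR, BL, BR); tiling is lossless by construction.
* **Face cropping** applies no rotation or landmark alignment --- head
  movement is treated as part of the expression signal --- and reuses the
  previous detection box when a frame's detection fails. The detector is a
  pluggable box-plus-confidence interface; a passthrough detector serves
  pre-cropped input. The box-to-square expansion takes the bounding square
  about the box centre, clamped to the frame.
* **Gradients.** The temporal classifier and AugmNet are trained by
  hand-written reverse-mode differentiation through every layer (layer
  norm, attention, GELU/ELU, pooling), verified in the tests against
  numerical differentiation to ~1e-5 relative error. AdamW uses decoupled
  weight decay on matrices only, with linear warmup and cosine decay.
  Training embeddings are standardised per feature.

# The synthetic-data generator

Real recordings of this protocol are registration-gated, so the package
ships a generator that emulates the *structure* the framework assumes, with
ground truth for every recoverable quantity:

* **Protocol layout.** 87 subjects x (20 baseline + 4 levels x 20
  stimulations) = 8,700 sessions of 5.5 s at the default specification,
  with the stimulation order shuffled per subject from a subject-derived
  seed. The manifest is generated eagerly; frames and ECG are materialised
  lazily per session, deterministically from `(seed, subject, label, rep)`.
* **ECG.** A Ricker-wavelet QRS train at spacings `round(60*fs/BPM)`, a
  smaller T bump 240 ms after each beat, slow baseline wander and optional
  white noise; true R indices and the per-second BPM profile are stored.
* **Faces.** A purely geometric surrogate (ellipse head, eyes, brow and
  mouth strokes) drawn at 448x448. Pain level scales a deformation
  amplitude (brow curvature, mouth opening) that also ramps toward the
  session's end, mimicking the late manifestation of pain within a
  session; level NP draws zero deformation.
* **Effect sizes.** Neither the protocol nor the source reports per-class
  physiological effect sizes, so the defaults are conventions chosen once:
  +3 BPM per pain level on a subject baseline of 70 +/- 8 BPM, with 4 BPM
  between-session and 1 BPM within-session jitter --- separable NP vs P4
  but deliberately not trivially so --- and 0.15 deformation amplitude per
  level.

What passing tests on this generator do show: the geometry, counts and
label-dependent signal paths of the pipeline are correct, heart-rate ground
truth is recovered through the full detection chain, and the trained fused
classifier extracts genuinely label-correlated structure. What they do not
show: performance on real faces or real cardiac dynamics (no appearance
variation, occlusion, arrhythmia or artefact structure), so no accuracy
number here estimates the published real-data accuracies.

# Training and evaluation harness

Training follows the published recipe (AdamW, lr 1e-4, cosine decay,
weight decay 0.1, 50 warmup epochs, batch 32, 500--800 epochs) as the
`trainConfig()` defaults. The spatial and heart-rate encoders act as fixed
feature extractors: their published pretraining corpora are out of scope,
and every in-scope property concerns the architecture, not transferred
weights. Evaluation is leave-one-subject-out: one fold per subject, fold
confusion matrices pooled before computing accuracy and macro
precision/recall/F1 (pooling is invariant to fold size; the source does not
state its averaging convention). The binary task filters sessions to NP and
P4 before splitting.

# Problem sizes used in the shipped checks

The package's own checks run at sizes chosen to keep the full suite
desk-scale while exercising every code path: full-size modules are
instantiated for parameter counting and single-image/single-embedding
forwards; learning checks use a reduced classifier (width 16, 8 latents) on
40 two-cluster embeddings; the end-to-end fused run uses 3 subjects x 170
sessions of 2 s at 2 FPS/256 Hz with a depth-1 spatial encoder (width 20,
56-pixel patches), 50 training epochs per fold, and tests the binary task
on its 204 NP/P4 sessions against a one-sided binomial null at chance 0.5.

# Known limitations

* Forward passes are plain-R matrix algebra: correct and deterministic,
  but not fast enough to train the full-size spatial encoder; the training
  path covers the temporal classifier and AugmNet.
* AugmNet's own objective is not recoverable from the source (its defining
  equations are illegible there); it is trained end-to-end by the
  downstream classification loss alone, its bottleneck forcing the learned
  corruption. Reconstruction or adversarial variants would be drop-in
  replacements.
* The attention-map utilities implement the described weight-contribution
  visualisations with one concrete back-projection convention each;
  qualitative claims about real attention patterns are not testable here.
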