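---
title: "DysDiTect: models, synthetic cohorts, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DysDiTect: models, synthetic cohorts, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The screening problem

Chinese developmental dyslexia (DD) shows up strongly in handwriting:
dictation of two-character words produces substitution, insertion and
deletion errors at the radical and stroke level, and — because testing
stops after eight consecutive incorrect words — long blank runs late in
the response sheet. DysDiTect treats a participant's whole dictation
record as one *ordered sequence* of 96 character images and predicts the
participant's diagnostic status (DD vs. typically developing, TD) from
that sequence. The positive class is DD throughout: sensitivity is the
correct rate among DD children, specificity among TD children.

The package implements the full pipeline: scanned-page preprocessing,
a calibrated synthetic-cohort generator (the study's own data are private),
the model family with its 16-variant ablation grid, training, evaluation
with grade banding, and the attention-map analyses.

## Model family

Every variant shares a CNN encoder applied independently to each of the
96 images (weight sharing makes the encoder permutation-equivariant).
Four switches generate the family, named `DysDiTect_` plus the enabled
letters in P, L, A, G order:

* **P** — fixed sinusoidal positional encoding added to the 32-dimensional
  per-character features, `PE[pos, 2i] = sin(pos / 10000^(2i/D))` and the
  cosine counterpart;
* **L** — a 2-layer bidirectional LSTM, 128 hidden units per direction,
  per-timestep outputs concatenated to 256 features;
* **A** — 4-head scaled dot-product self-attention with no causal mask;
  the output dimensionality is unchanged and the per-head row-stochastic
  96 × 96 weight matrices are retained for analysis;
* **G** — the school grade (2–6), scaled to grade/6 so it lives on the
  scale of the condensed features, appended as a 97th input to the final
  classifier.

After the enabled stages, a linear map shared across timesteps condenses
each character embedding to one neuron; the 96 (or 97) values feed a
final linear layer and a sigmoid that outputs the DD probability.
Dropout 0.2 is applied to the LSTM (between layers and on the output),
the attention output, and the condensed vector during training. When L
is off, attention runs at the raw CNN width (32 = 4 heads × 8); the
published description never states that width, so this is our choice.
No residual connection or layer normalization surrounds the attention
block by default (`attn_residual` exposes the residual as an option).

### Backbones

The published system fine-tunes an ImageNet-pretrained ResNet-50 with
only stage 4 and the heads unfrozen. Pretrained weight bundles are large
binaries that this package does not distribute, so
`backbone = "resnet50_transfer"` fails with an explanatory error; the
generic freeze policy (`finetune_policy = "frozen"`: all CNN blocks
except the last one and the heads held fixed) is implemented and tested
on the compact backbone.

The default `small_cnn` backbone is designed so the whole 16-variant
family trains on a single CPU: a parameter-free 4 × 4 average-pool stem
(128 → 32 pixels) followed by three 3 × 3 conv / 2 × 2 average-pool
blocks with 8, 16 and 32 channels, global average pooling, and a linear
projection to 32 features. At roughly 0.8M multiply–accumulates per
image this is ~70× cheaper than a four-block encoder on the full
128 × 128 raster while preserving the per-item feature contract
(32 features per character). The stem's density map keeps stroke
topology at the scale the renderer produces; it would be too coarse for
genuine stroke-level orthographic detail, which is one reason desk-scale
results are not comparable to the published ones.

### Initialization

Conv and linear weights use He-style uniform fan-in scaling; **all biases
start at zero**. The zero biases matter: character images are sparse
binary rasters, and with nonzero bias initialization the CNN features of
every item share a constant offset two orders of magnitude larger than
the across-item variation, which stalls from-scratch training at the
trivial constant prediction. With zero biases an all-blank character maps
to an exactly-zero feature vector, so response-type differences dominate
the feature geometry from the first step. LSTM weights and biases follow
the usual uniform ±1/sqrt(hidden) convention.

## Synthetic cohorts

The generator reproduces the statistical structure the classifier
exploits, not Chinese glyphs:

* **Composition.** Cell counts default to the full study composition
  (1064 children, DD 172/110/101/72/28 and TD 174/158/143/62/44 across
  grades 2–6); `desk_cohort_config()` scales it proportionally (largest
  remainder) to a desk-sized cohort, 120 participants by default.
* **Ability.** Each participant draws a per-character success
  probability from a Beta distribution moment-matched to the published
  per-cell score means and SDs (score/96), clipped to (0.01, 0.99).
* **Item difficulty.** Word difficulties rise linearly from −slope to
  +slope logits (slope 4) across the 48 words, mirroring the task's
  incremental-difficulty design, and each participant's latent location
  is solved (by root-finding against an exact dynamic program over the
  consecutive-incorrect run length) so that the *expected score under
  the stop rule* equals 96 × ability. This is on by default for a
  reason: with i.i.d. responses a low-ability participant (p ≈ 0.22)
  fails eight words in a row almost immediately, and mean scores land
  tens of points below the calibration targets; with the gradient and
  the truncation-aware solve, every cell's mean score lands within
  ~1 point of its target (the suite checks ±1.5 at n = 1000 per cell).
* **Responses and discontinuation.** Characters are Bernoulli given the
  word-level probability; a word is incorrect iff either character is
  wrong; after 8 consecutive incorrect words everything remaining is
  blank. Blanks count as wrong in accuracy, and blank runs are always a
  suffix.
* **Rendering.** Each of the 96 items has a fixed pseudo-character
  template (4–9 random polyline strokes in a unit box, frozen under a
  template seed — the same materials go to every participant). Correct
  responses render the template with small endpoint jitter; wrong
  responses perturb it (a stroke removed, added, or displaced); blanks
  are empty. Line width is 3 px at 128 px and scales with resolution.
  Optional extras emulate scanner-era artifacts: a cross-out scribble on
  blanks and scoring tick/cross overlays (both off by default).

What the generator does **not** emulate: real glyph structure, writing
quality differences between groups on *correct* characters, motor
variability, or grade-specific materials. Consequently a passing desk
benchmark shows that the pipeline can recover group structure carried by
error patterns and discontinuation; it says nothing about recognizing
dyslexic handwriting quality in real scans, and desk-scale accuracies
are not comparable to the published test-set results.

## Splitting

The 8:1:1 split is stratified over the ten grade × status cells with
largest-remainder allocation and surplus preference test > val > train;
this reproduces the published totals (within one participant of
851:106:107 on the full composition — the original allocation rule is
not printed, so per-stratum placement may differ). Shuffling within each
stratum derives from the split seed; counts are seed-invariant.

## Training

Adam with binary cross-entropy, minibatches of 6 participants reshuffled
every epoch, weight decay 5e-5, dropout 0.2, learning rate halved every
three epochs, at most 50 epochs, early stop when the best validation
loss fails to improve by 1e-4 across three consecutive epochs ("improve"
reads as *running-best* decrease, the standard patience semantics), and
evaluation from the checkpoint with the lowest validation loss. The
published initial rate 5e-6 is kept as the `train_config()` default: it
is a fine-tuning rate for a pretrained backbone. `desk_train_config()`
raises it to 3e-3 for from-scratch training of the compact backbone —
across {1e-3, 3e-3, 5e-3}, 1e-3 under-converges within the 10-epoch desk
cap, 5e-3 destabilizes the validation loss, and 3e-3 descends fastest
while early stopping still selects a sensible checkpoint — and caps
training at 10 epochs. A single master seed (42, the published setting)
derives per-component seeds for weight initialization, shuffling and
dropout, making runs bit-reproducible on one machine.

Validation loss is the mean per-participant binary cross-entropy. The
decision threshold on the DD probability is 0.5 wherever predictions are
thresholded (the publication never states one; it is exposed as an
argument), and AUC uses the Mann–Whitney pair formulation on the
predicted probabilities, with ties counted one half.

## Desk-scale problem sizes

The suite and the acceptance script run everything at sizes a single CPU
handles comfortably, as the package's own reference conditions: the
label-recovery benchmark trains `DysDiTect_L` (compact backbone, full
128 px renders) on a 120-participant norm-calibrated cohort for at most
10 epochs; the 16-variant smoke grid trains two epochs each on a
32-participant, 32 px cohort with reduced widths; the full-composition
structure check renders all 102,144 images at 32 px thumbnail size.

## Attention analyses

For a variant with attention, heads are averaged into one row-stochastic
matrix (head handling is unstated in the publication; averaging is our
choice). The *attained weights* of character j are column j — the
attention assigned to it by all tokens — renormalized to sum to one
(`renorm = FALSE` divides by 96 instead; the publication does not say
which was used). Entropy is Shannon entropy in base 2, forced by the
published values clustering just below log2 96 ≈ 6.585 bits; it is
summarized per group × response cell as K / mean / SD, with singleton
cells reporting an undefined SD and empty cells K = 0.

ICC(3,k) follows the two-way mixed-effects, consistency,
average-measures definition: ICC = (MS_rows − MS_error)/MS_rows, F =
MS_rows/MS_error on (N−1, N−1) degrees of freedom for k = 2, with
F-quantile confidence bounds; identical columns give ICC = 1 exactly.
The published pairing of "character entropy and accuracy measures"
(N = 92) is ambiguous, so `entropy_accuracy_ratings()` implements our
best reading — per-participant mean attained-weight entropy against
per-participant proportion correct, both z-scored (consistency ICC is
location/scale-free, so standardization only removes the arbitrary
units) — and the generic N × 2 `icc3k()` accepts any other pairing.
Reproducing the published entropy table and ICC = 0.418 would require
the study's data and trained weights and is out of scope.

## Numerical and degenerate-input conventions

* Binarization: Otsu's threshold on Rec. 601 luminance; the minority
  class is ink, so scans (sparse dark ink) and already-binary images
  (white strokes on black) both come out with strokes = 1, and
  re-binarization is idempotent. Constant images become all-zero.
* Box detection: Sobel edge-magnitude projection profiles; each printed
  border yields edge responses on both sides, merged within 4 px. A page
  that does not yield exactly 2 × rows and 2 × cols line centers raises
  a structured grid-not-found error naming the page, or falls back to
  the declared layout when `fallback = TRUE` (the pipeline driver's
  default — the declared layout plays the role of manual checking).
* Rescaling: bilinear to the target size ignoring aspect ratio (boxes
  are near-square), then re-thresholded at 0.5. Blank means a stroke
  fraction below 0.005.
* Metrics with zero denominators are undefined (`NA`), never 0.
* A Beta cell with sd² ≥ mean(1−mean) is infeasible and rejected.
* `binarize`, the LSTM, attention softmax and BCE all use numerically
  stable forms; gradients of every layer are finite-difference-checked
  in the test suite.

## Known limitations

* Desk-scale training recovers group structure from response patterns;
  it cannot learn stroke-level orthographic features of real
  handwriting, and the compact backbone would need replacing (plus a
  pretrained bundle) for real scans at published fidelity.
* The synthetic ability model is one-dimensional; a 13-participant test
  split therefore carries real sampling variance, and held-out metrics
  at other seeds scatter around the population separability of the
  calibrated cohort.
* The per-stratum split allocation reproduces published totals, not
  necessarily the original per-stratum memberships.
* ICC confidence intervals assume the standard two-way ANOVA normality
  conditions, which per-character entropies only approximate.
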