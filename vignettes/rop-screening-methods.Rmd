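---
title: "Methods: smartphone fundus-video screening for ROP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smartphone fundus-video screening for ROP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The screening problem

Retinopathy of prematurity (ROP) is an abnormal vascular development of
the retina in preterm infants; untreated late-stage disease detaches the
retina and blinds. Screening requires indirect ophthalmoscopy by a
pediatric ophthalmologist — a scarce specialist, especially in
low-resource settings. The process this package implements replaces the
specialist at the *screening* step: a lightly trained videographer films
the dilated eye with a smartphone through a +20/+28/+40 D condensing
lens, and software reduces the video to a patient-level ROP-positive /
ROP-negative call that routes only likely positives to the specialist.

The pipeline has three stages:

1. **Magnifier localization.** The condensing lens appears in every frame
   as a bright circle on a dark surround. Each extracted grayscale frame
   is searched with a circular Hough transform over a lens-derived radius
   window; the fundus field is cropped at the selected circle and resized
   to 256×256.
2. **Frame quality selection.** A trainable classifier scores each crop
   as a clear fundus view vs an artifact (blur, glare, partial circle,
   empty frame); the top-3 crops per video go forward. Videos with no
   usable frame are *indeterminate* — the cue to record another video.
3. **ROP classification and aggregation.** A sensitivity-weighted binary
   classifier scores each selected crop; scores are calibrated by
   temperature scaling and thresholded at 0.5. The patient is called
   ROP-positive iff **any** selected frame is positive (the any-positive
   rule), which trades specificity for the sensitivity that matters in
   screening: with per-frame sensitivity $s$ and $k$ roughly independent
   frames, patient-level sensitivity approaches $1-(1-s)^k \ge s$.

## The circular Hough search

A circle of radius $R$ centered at $(a,b)$ satisfies
$x = a + R\cos\theta$, $y = b + R\sin\theta$. Edge pixels are extracted
by central-difference gradient magnitude thresholding (default threshold
0.08 on [0,1] intensities; the capture literature does not prescribe a
detector, so it is a config knob). The accumulator value at integer
$(a,b,R)$ is defined as the number of edge pixels whose Euclidean
distance to $(a,b)$ rounds to $R$; the implementation stamps, for each
edge pixel and radius, the rasterized annulus $[R-\tfrac12, R+\tfrac12)$
of centers it votes for (compiled code), which is mathematically
identical to direct per-center counting — the test suite verifies
equality against an exhaustive brute-force accumulator.

Numerical choices:

* **Vote threshold** — a candidate must collect at least half the
  theoretical full-circle vote count $2\pi R$ (the annulus area). Tying
  the threshold to $2\pi R$ makes it scale-free across radii. Partial
  circles cut by the frame border usually fall below it, which is the
  desired behavior (those frames are invalid anyway).
* **Radius window** — `expected_radius ± radius_tolerance` (defaults
  96/80/64 px for +20/+28/+40 D at the 256 px frame scale, tolerance
  10 px). `learn_radius_range()` optionally refines the window from the
  mode of selected radii over a calibration video, realizing a
  data-driven "learned range".
* **Candidate selection** — the frame is disregarded when no candidate
  passes; among candidates the one minimizing $|R-\text{expected}|$ wins
  (size, not position, defines "expected magnifier dimensions"), ties
  broken by higher votes, then lexicographically by center for full
  determinism.
* **Crop** — square of side $2R$, zero-padded at frame borders, bilinear
  resize to 256×256.

## The two classifiers

No deep-learning framework is part of this package's dependency set; the
classifiers are compact single-hidden-layer (tanh) neural networks over a
fixed 27-dimensional crop descriptor: a 12-bin radial intensity profile,
16-sector statistics of the 0.7–0.9 R annulus (a demarcation-ridge arc
appears as one bright sector, summarized as max − median), sharpness
(Laplacian variance), saturation and darkness fractions, and channel
statistics. The descriptor is computed after downscaling crops to the
configured input size (default 64×64).

Training uses full-batch Adam on the **weighted binary cross-entropy**

$$\ell(p, y) = -\big[w^{+}\, y \log p + (1-y)\log(1-p)\big],$$

where $w^{+} \ge 1$ multiplies only the positive (ROP) term: false
negatives are the costly error in screening. The default
$w^{+} = (\#\text{neg}/\#\text{pos}) \times 1.5$ balances the classes
and then leans further toward sensitivity; the grid test verifies that
validation sensitivity at threshold 0.5 is non-decreasing in $w^{+}$.
"Training until convergence" is realized as early stopping on validation
loss (patience 150 epochs at learning rate $10^{-4}$ for the ROP model;
the quality model uses $10^{-2}$/patience 100 since nothing anchors its
rate), restoring the best weights. Full-batch training plus seeded
initialization makes every fit bit-reproducible.

Augmentation (ROP training only, one augmented copy per crop by
default): rotation up to ±15°, horizontal/vertical flips, photometric
jitter (brightness/contrast/saturation half-width 0.05). Jitter is
interpreted photometrically; the rotation/flip group covers geometric
variation. All operators preserve the crop size, and the all-off spec is
the exact identity.

**Calibration.** Raw confidence outputs need not match outcome
frequencies, so a single temperature $T$ is fitted on validation logits
by minimizing the NLL of $\sigma(z/T)$ (scalar search on $\log T \in
[\log 0.05, \log 20]$). Scaling by $T$ preserves ranking, hence AUROC;
the tests verify recovery of $T \approx 1$ on generatively calibrated
logits and $T \approx 2$ when those logits are doubled, and that NLL and
10-bin expected calibration error do not worsen on held-out data.

**Hard-negative mining** is exposed as a utility: the highest-scoring
crops whose ground truth marks them invalid (confident false positives)
are returned for relabeling and retraining; iterative human review is
out of scope, with frame truth standing in for the expert.

## The synthetic cohort generator

No clinical videos ship with the package, so every stage is exercised on
a ground-truthed phantom cohort designed to emulate the *statistical and
optical structure* the pipeline assumes — not retinal photorealism:

* a bright fundus disk (configurable contrast 0.35 over a 0.04
  background, radial vignetting) on a dark surround, radius 80 ± 5 px
  jitter on 256×256 frames;
* a recursive binary-branching vessel tree from an optic-disc analog,
  with sinusoidal tortuosity whose amplitude scales with a tortuosity
  gain and stroke width with a dilation gain;
* for ROP-positive eyes only: a bright circumferential ridge arc at
  0.7–0.9 of the fundus radius plus tortuosity/dilation gains
  $1 + 0.30\,e$ and $1 + 0.25\,e$, where $e$ is `effect_strength`
  (default 1; $e = 0$ makes the classes statistically identical, and a
  fixed pixel statistic's AUROC rises monotonically with $e$);
* artifact frames at rate `1 - valid_frame_rate` (default 30%), split
  evenly among blur (Gaussian σ 5 px), glare (1–3 saturated blobs),
  partial circles crossing the border, and empty frames;
* patient-level prevalence 0.295 and a 2.5% chance of a second video per
  patient, matching the study-scale accounting of ~524 videos per 512
  neonates;
* additive Gaussian pixel noise (σ 0.02) truncated at ±3σ — truncation
  keeps artifact-free background strictly bounded, which gives the empty
  frame its clean contract; all output is 8-bit quantized so in-memory
  frames and PNG round trips are bit-identical.

Because videos are PNG frame stacks (`frame_%06d.png`), decoding is
lossless and deterministic; `.mp4`/`.mov` paths raise an explicit decode
error rather than silently skipping, since no decoder is bundled. The
frame sampling default is a stride of 5 (every fifth frame), the
protocol's sampling rate; stride is a knob because yield-vs-cost trades
differ by deployment.

What passing synthetic tests does **not** show: robustness to real
optics (specular reflexes, motion blur continua, uneven illumination),
to true vascular morphology, or to inter-grader label noise. The
generator gives *construction-separable* classes; classifier bars
(quality AUROC ≥ 0.9, ROP AUROC ≥ 0.85) validate the pipeline's
plumbing and learning machinery, not clinical performance.

## Evaluation statistics

* Confusion metrics are percentages with zero-denominator cases returned
  as `NA`, never silent zeros.
* AUROC is the all-pairs concordance (ties one half), computed from
  midranks and tested exhaustively against a brute-force pairwise oracle
  at small n.
* Confidence intervals use the normal approximation
  $100\,(\hat p \pm z\sqrt{\hat p(1-\hat p)/n})$ with $z = 1.96$
  exactly (not 1.959964 — the reporting convention this reproduces), capped
  into [0, 100] and reported to one decimal, half-up. The CI `n` follows
  the reader-study convention of the *full evaluation-set size* (all 148
  frames or all 50 patients) even for subgroup metrics; a per-denominator
  mode is available (`ci_n_mode = "denominator"`) for the statistically
  conventional choice. Fidelity first; correctness as an option.
* Stratified splits round the train and validation counts half-up per
  stratum and assign the remainder to test — the convention that
  reproduces a 2227-item split at 74.7/12.2/13.1% into exactly
  1664/272/291. A grouped variant keeps all of a patient's frames in one
  split; training rejects patient overlap with a `patient_leakage` error.
* Indeterminate screening decisions are excluded from metric denominators
  and reported separately.

## Decisions on genuinely open points

* Multi-video patients are aggregated by the any-positive rule across
  videos, the natural extension of the frame rule; eyes are not modeled
  separately.
* The quality "ranking" score is the classifier's positive-class
  probability.
* The decision threshold after calibration defaults to 0.5; a
  validation-picked threshold under a sensitivity floor can be supplied
  via the `threshold` argument.
* Frame indexing is 0-based everywhere; grayscale uses fixed BT.601 luma
  weights (0.299, 0.587, 0.114).

## Problem sizes used by the test and acceptance runs

Chosen as desk-scale defaults: quality training on a ~400-frame balanced
cohort (20 patients × 20 frames at 50% valid rate); ROP training on a
30-patient × 20-frame default cohort with a patient-disjoint 80/20
split; Hough oracle equivalence on 50 frames ≤160×160; localization on
200 valid frames; the any-positive amplification on 500 positive
patients at 128 px frame scale with 3 frames per video, screened with
models trained at that same scale. The acceptance script uses slightly
smaller cohorts of the same structure, screens a 60-patient mixed cohort
at the default 256 px scale, and reseeds everything from its `--seed`.

A practical note surfaced by the synthetic experiments: the sharpness
terms of the crop descriptor are resolution-sensitive, so a model
trained at one frame scale does not transfer to videos captured at a
very different scale. Screening models should be trained at (or
resampled to) the deployment capture geometry; the tests and the
acceptance script train and screen scale-matched.

## Known limitations

* Phantom realism is a stand-in; no claim transfers to clinical data.
* The descriptor-based classifiers cannot learn signatures outside their
  descriptor span; on real data a convolutional architecture trained at
  256×256 would replace them behind the same training surface (weighted
  BCE, early stopping, calibration are architecture-agnostic).
* The Hough accumulator assumes a single dominant circle per frame;
  multi-magnifier frames and ellipse distortion are out of scope.
* Wald intervals are poor near 0/1 at small n; they are kept because
  interval *fidelity* to the reporting convention is the goal.
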