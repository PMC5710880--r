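---
title: "glandscreen: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{glandscreen: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models each
stage implements, the assumptions they make, the parameters that matter,
and the choices we made where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The screening problem

Colorectal biopsies are graded by pathologists on the Japanese Group
Classification (Group 1 non-neoplastic … Group 5 carcinoma, Group X
inadequate). A screening assistant does not need to reproduce the full
grading: it needs to (a) almost never call a carcinoma or adenoma
*Negative*, while (b) keeping the fraction of tissues flagged for a second
human read (the over-detected proportion) tolerable. The three indices in
`screening_indices()` formalize exactly this. Their denominators are the
Group 5 row (carcinoma), the Group 3 row (adenoma) and all tissues
respectively; the non-epithelial lymphoma and carcinoid rows count in the
overall total but in neither group-specific denominator — the packaged
two-hospital fixtures only reproduce the published totals and percentages
under this reading, which fixes the interpretation.

Rounding of the indices is half-up to one decimal (`round_half_up()`),
matching how such tables are conventionally printed; base R's
round-half-to-even would turn 12.25 into 12.2 rather than 12.3.

## Stain model and rendering

All colour handling sits on the Beer–Lambert relation: a pixel's optical
density `OD = -log(I / I0)` is a non-negative combination of a hematoxylin
and an eosin unit vector (`stain_profile()`, Ruifrok-style defaults). The
synthetic renderer composes per-pixel H and E *concentrations* (nuclei
≈ 0.9–1.1 H; epithelial cytoplasm ≈ 0.33–0.44 E; stroma ≈ 0.18 E with a
smooth spatial field; lumina and background ≈ 0) and exponentiates. Because
rendering and estimation share this physics, `estimate_stains()` can be
tested against vectors the generator actually used — the reason we chose a
Macenko-style SVD estimator over histogram matching, whose target is not
expressible as ground truth.

Batch effects are modelled in concentration space (`apply_batch_effect()`):
`intensity_scale` multiplies concentrations (overall stain uptake);
`contrast_scale < 1` compresses concentrations towards their 25th-percentile
(stromal) baseline, so nuclear and background colour distributions slide
into each other — the washed-out, low-contrast failure mode. The component
of OD orthogonal to the stain plane (sensor noise, quantization) is carried
through unchanged, which makes the identity batch effect exactly the
identity.

Two numerical guards in `estimate_stains()` matter in practice:

* a second-singular-value ratio below 0.1 raises a *degenerate
  single-stain* error (measured: stroma-only renders ≈ 0.05, any real
  two-stain render ≈ 0.19 — the gap is wide);
* `normalize_stains()` caps the per-stain concentration rescaling factor at
  4: a stain essentially absent from the source must not have its noise
  amplified to the target's range. The low-contrast recovery (factor ≈ 2.5)
  sits comfortably under the cap.

## Quality control

The focus score is the variance of the Laplacian of luminance (0–255
scale) per tile (default 64 px). We chose it over FFT band energy for
determinism and speed. The decision threshold (`quality$blur_threshold`,
default 10) was calibrated once on generator output and frozen
(`data-raw/make_reference.R`): sharp foreground tiles score ≥ ~25 across
classes and seeds, σ=3-blurred tiles ≤ ~4, so any threshold in the gap
separates perfectly; 10 sits near its geometric middle.

Pen ink is detected by fixed colour rules (saturation > 0.55 with hue in
the green-to-blue band 70–235°, or near-black value < 0.2) rather than
image-adaptive ones — marker ink is an absolute colour, and adaptive
thresholds would fail exactly on heavily inked slides. Shadows are drops of
the low-frequency illumination field more than 20% below the white point,
outside the (saturation-defined) tissue foreground; the field is estimated
by normalized convolution over background pixels only, so tissue darkness
cannot masquerade as shadow.

Status mapping (fractions over foreground tiles): unusable at blurred
≥ 0.5, pen ≥ 0.2, shadow ≥ 0.3; partially degraded above 0.05. These
fractions are our convention — the motivating system documents only
qualitative examples — and all are config-exposed. Partially degraded
tissues continue with degraded tiles painted to background so neither
atypia analysis sees them; fully unusable tissues short-circuit to
Unclassifiable without running the atypia stages.

## Structural atypia

Rim thickness is `2 x median` of the Euclidean distance transform sampled
on the component's skeleton (Zhang–Suen thinning, implemented in-package
since no installed library provides 2-D thinning). The median is robust to
branch points of the medial axis, where a mean or maximum inflates.
Thickness maps to gland level 1–10 through fixed, absolute 5 µm bins
spanning 5–55 µm: per-image quantile bins would make levels incomparable
across tissues, defeating the cool-to-warm visualization's purpose.

The arrangement (polarity) score operationalizes "arrangement of nuclei
and cytoplasm": the gland band (nuclei + eosin-dominant cytoplasm within
one nuclear width of the component) is swept in 24 angular sectors around
its lumen; a sector violates basal polarity when the median radius of its
nuclear pixels lies luminal of 60% of the band's radial extent, and the
score is the violated fraction of assessable sectors (those showing both
compartments). On generator glands the score tracks the stratification
parameter: polarized single-layer glands average ≤ 0.2, fully stratified
ones ≥ 0.6.

The two-pass economy: high-magnification segmentation runs only for
components at or above `trigger_level` (default 5). When no finer pyramid
level is available the pass runs on the input image — the measure depends
on radial geometry more than on resolution.

Cutpoints `low_max = 3` / `high_min = 8` / arrangement ≥ 0.5 are shipped
defaults; `calibrate_thresholds()` re-places `low_max` just below the 5th
percentile of adenoma maximum levels and the trigger at the 10th percentile
of glandular-carcinoma levels on a validation cohort. On this generator's
scale calibration typically lands `low_max = 1`: synthetic adenomas
(rims of 2–2.8 nuclear widths of 7–8.2 µm) measure 12–20 µm, i.e. levels
2–4. Running the classifier without calibration therefore under-calls
adenoma — as any screening system tuned for one site does on another.

## Cytological atypia and MIL

Nuclei are pixels above an *absolute* hematoxylin-concentration cutoff
(0.5), split by watershed on the distance transform; the absolute cutoff is
deliberate — it is what makes the low-contrast batch failure reproducible
(detection collapses to ~0 of truth) and what colour normalization then
rescues (back to within ±20%).

ROIs are non-overlapping `roi_size_px` grid tiles (default 128 px at
0.92 µm/px) keeping only tiles with ≥ 10 nuclei; each carries an 8-feature
morphometric vector (density, mean/sd nuclear area, eccentricity, mean/sd
hematoxylin, mean nearest-neighbour distance, fraction of nuclei over
55 µm²). The MIL model is a one-hidden-layer (8 tanh units) network scoring
instances in [0,1], pooled over a bag by log-sum-exp of logits (sharpness
4), trained full-batch with Adam on bag-level cross-entropy — labels exist
only per tissue, never per ROI. A feature-based MIL was chosen over
raw-pixel deep learning: the reference architecture and weights of the
original system are unavailable, and desk-scale CPU training must be
feasible; the bag/instance structure and the [0,1] instance-score contract
are preserved.

The tissue aggregate is the mean of the squares of the three largest ROI
scores ("mean-square of top three" read as mean-of-squares: monotone,
bounded in [0,1], and equal to the score itself under saturation; the
square-of-mean reading would not be monotone in the same sense). Fewer than
three ROIs zero-pad — small tissues should not be advantaged. The decision
boundary maps *equality to high*, favouring sensitivity.

The packaged default model (`default_mil_model()`, trained by
`data-raw/make_default_model.R` on a fixed-seed 60-tissue synthetic cohort)
separates sharply on held-out synthetic data: carcinoma aggregates ≥ 0.84,
benign ≤ 0.21. The default threshold 0.6 follows the calibration rule —
midway between the highest benign and the lowest poorly-differentiated
carcinoma aggregate on a fixed-seed validation cohort, never above the
point that would miss a validation carcinoma.

## Overall classification

`combine_results()` is a total pure function on the 3 × 2 × 3 lattice,
formalizing "the higher atypia level is adopted preferentially" as a
maximum over Negative < Adenoma < Positive; cytology has no middle level,
so Adenoma can only come from structure — consistent with attributing the
adenoma/carcinoma distinction to structural atypia. Two corners are not
dictated by the motivating description and were decided here: quality
precedence (an unusable image's scores are untrustworthy by definition,
so rule 1 fires before everything) and structural-unclassifiable with
cytological high, which we resolve to Positive (sensitivity bias; the
explanation trail records the firing rule).

## The synthetic generator: what it does and does not emulate

Emulated: tubular gland geometry (lumen, apical cytoplasm band, nuclear
rim of controllable thickness in nuclear widths), loss of basal polarity
via the stratification parameter, dissociated-large-cell (poorly
differentiated / signet-ring) carcinoma, stain batches (vector rotation,
intensity, contrast compression), blur (global and focal), pen marks,
shadows, and a wavy tissue blob on a bright background. Determinism: every
operation draws from an RNG stream keyed by (seed, operation name), so
outputs are pure functions of their seeds and insensitive to call order.

Not emulated: photorealistic chromatin/stromal texture, inflammatory
infiltrates, mucin pools, sectioning folds and tears, cautery artifact, or
true 40× detail — nuclei are smooth ellipses. Consequently, passing tests
demonstrate that each algorithm implements its stated contract on
geometrically faithful inputs with exactly known ground truth; they do not
certify clinical performance on real slides, whose published hospital-level
accuracies require the original scanned cohorts.

Class-conditional phenotype defaults (`sample_phenotype()`): negative —
rims 1.0–1.3 nuclear widths, nuclei 6–7 µm, no stratification; adenoma —
rims 2.0–2.8, nuclei 7–8.2 µm, stratification 0.15–0.45; carcinoma — 70%
glandular (rims 3.4–5.0, nuclei 8.5–10 µm, stratification ≥ 0.55) and 30%
dissociated (1.5–3.5 cells /1000 µm², nuclei 9–11 µm). These are one-time
choices of morphometrically plausible ranges for the three classes;
inter-gland spacing keeps a lamina-propria gap wide enough that
morphological closing at one nuclear width never merges neighbours.

## Problem sizes

Unit fixtures render at 512 × 512 px and the canonical single-tissue
default at 1024 × 1024 px, both at 0.92 µm/px (a 4× downsample of a 40×,
0.23 µm/px scan). The end-to-end screening experiment uses 384 × 384 px
tissues — 150 validation and 300 held-out (100 per class) — a scale at
which the full pipeline (about 0.7 s/tissue on one CPU) keeps the whole
experiment desk-sized while every stage still operates well above its
minimum geometry (glands of 25–60 px radius, 64 px QC tiles, 128 px ROIs).

## Known limitations

* The generator's benign/malignant separation is cleaner than real
  histology's; calibrated thresholds transfer to the generator's scale
  only.
* `reapply_thresholds()` (used to report validation indices inside
  `calibrate_thresholds()`) cannot retroactively compute arrangement
  scores for components that were below the old trigger; held-out
  evaluation re-runs the full pipeline and does not inherit this
  approximation.
* Label masks are written as 16-bit TIFF (the installed PNG writer is
  8-bit); images remain 8-bit RGB PNG.
* `detect_tissues()` merges fragments within the closing radius (250 µm);
  genuinely distinct fragments closer than that are returned as one
  region.
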