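---
title: "Automated HEp-2 IIF ANA evaluation: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated HEp-2 IIF ANA evaluation: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`anapattern` re-creates the evaluation chain of an automated HEp-2
indirect-immunofluorescence (IIF) reader for antinuclear antibodies (ANA):
two-channel field simulation, counterstain segmentation, intensity-based
positive/negative calling, per-cell k-NN pattern recognition, rule-based
synthesis into per-dilution and per-patient results with endpoint titers,
and the agreement statistics used to validate automated against visual
reading. This vignette documents the models behind each stage, the
parameters that matter, and the choices made where the design was genuinely
open. No clinical serum data ship with the package: everything quantitative
about the pipeline is established on synthetic, ground-truthed fields.

## The synthetic field model

A field is specified by `field_spec()`: a pattern mixture with relative
strengths, an endpoint titer `t` (reciprocal), the imaged dilution `d`
(reciprocal), cell count, mitotic fraction, image shape and a seed.
`render_field()` draws non-overlapping elliptical nuclei (semi-major axis
14–20 px, axis ratio 0.7–1.0, random orientation) by rejection sampling,
with defaults of 60 cells on a 1024×1024 16-bit frame — desk-scale sizes
that keep a full dilution series interactive.

**Counterstain channel.** Every nucleus receives dye at base level 0.45
(of full scale) with ±6% per-cell variation and a smooth chromatin texture.
Mitotic figures — a configurable fraction, default 8% — are rendered at
0.75× linear size and 2× brightness, emulating condensed chromatin. These
two factors are what the downstream mitosis rule keys on.

**FITC channel.** Per cell, the pattern is painted at amplitude
`s × strength` where

$$s(d) = \min(1, t/d) \cdot \frac{1}{1 + d/(20\,t)}.$$

The saturating factor makes the last clearly positive dilution coincide
with the titer (endpoint reading); the weak mass-action shoulder makes the
signal *strictly* decreasing in dilution — real serial dilutions visibly
fade before they extinguish, and a flat-then-cliff law would make
"fades with dilution" untestable. `dilution_amplitude()` exposes the law.

Pattern morphologies follow classical IIF reading rules: homogeneous is a
near-uniform nuclear fill (relief ~8%) that also stains mitotic chromatin;
speckled is a fine granular texture sparing two nucleolar holes and the
mitotic plate; nucleolar adds 2–5 large bright blobs (radius 4.5–6.5 px)
over a faint nucleoplasmic floor; centromeres are 30–50 small dots
(1.2–1.8 px) that persist on mitotic figures; nuclear dots are 4–10
intermediate dots (2.5–3.5 px); cytoplasmic stains a perinuclear annulus
and leaves the nucleus dark. The faint diffuse floor (amplitude 0.25)
under the dotted patterns mirrors the nucleoplasmic background seen in
real dotted-pattern sera and keeps such samples above the positive/negative
cutoff even though the dots themselves cover little area.

**Mixed patterns.** A field with several patterns assigns each cell a
*dominant* pattern drawn from the mixture strengths (multinomial), rather
than superimposing every pattern on every cell. Real mixed sera superimpose
reactivities within single cells; the multinomial simplification is what
makes per-cell voting followed by a cell-fraction rule a meaningful test of
mixed-pattern reporting. This is the main respect in which passing tests on
synthetic mixtures understates the difficulty of real ones.

**Acquisition noise.** Constant background 0.05, a linear illumination
plane of amplitude 0.002 (LED illumination of slide scanners is nearly
flat), Poisson photon noise at 800 photons per full-scale unit, Gaussian
read noise of sd 0.005, then quantization to the 16-bit grid. Identical
specs render bit-identical images; a dilution series reuses the geometry
sub-seed and re-draws only acquisition noise per dilution, so the same
cells are imaged at every dilution.

## Calibration and segmentation

`calibrate()` estimates each channel's background as the 5th percentile of
a 9×9 box-smoothed copy — the smoothing suppresses the shot/read-noise tail
that biases a pixelwise low quantile — subtracts it, and divides by a fixed
reference level (0.75), *not* by the image's own maximum: a dim image must
stay dim for an intensity cutoff to mean anything. Outputs are clipped to
[0, 1]; an all-zero channel calibrates to all zeros rather than failing.

`segment_nuclei()` is the standard counterstained-nucleus recipe: global
Otsu threshold, hole filling, watershed on the distance transform
(tolerance 3 px) to split touching nuclei, then an area filter of
[200, 8000] px² at the default scale — wide enough for the smaller mitotic
figures, tight enough to drop debris. Segmentation consumes only the
counterstain channel, so no antibody-channel artefact (including a failed
FITC focus) can lose cells; this is asserted structurally in the tests.
The cytoplasmic measurement region is a 6 px dilation annulus minus all
nuclei. Mitoses are flagged when mean in-nucleus counterstain is ≥ 1.5× the
median over nuclei *and* area is ≤ 0.8× the median; under the generator's
2×-brightness/0.75×-size rendering both margins are comfortable, and with
fewer than 3 cells the statistics are meaningless so nothing is flagged.

## Features and classification

The positive/negative decision precedes pattern analysis:
`normalized_image_intensity()` takes the median over non-mitotic cells of
mean calibrated FITC over nucleus ∪ cytoplasm, and `classify_pos_neg()`
compares it (inclusive boundary) to a configurable cutoff. The default
0.15 is the package's recommended basic setup; laboratories tune this
sensitivity/specificity trade-off, which is why it is a parameter and not
a constant.

Each cell yields 62 features (`feature_names()`): 7 intensity statistics
each for nucleus and cytoplasm plus their mean ratio; 16 grey-level
co-occurrence features (contrast/correlation/energy/homogeneity at 4
offsets, 16 grey levels); two 10-bin uniform LBP histograms (radius 1
and 2); a 6-scale granulometry spectrum; Laplacian-of-Gaussian blob count,
mean scale and mean prominence (σ ∈ {1.5, 2.5, 4, 6}); Sobel edge density;
and the fraction of nuclear area above half the nuclear maximum. Texture
features are computed on a per-cell min-max normalized crop so pattern
identity survives titer/dilution amplitude changes, while the intensity
statistics deliberately keep the calibrated scale. Blob detection alone
uses the unstretched crop: min-max normalization amplifies the residual
relief of a near-uniform fill, and a homogeneous nucleus must not sprout
blobs on account of its own normalization. The feature list is
version-stamped into saved databases so a database/query mismatch fails
loudly instead of silently misclassifying.

`build_reference_db()` assembles the labelled database from single-pattern
fields at full amplitude — interphase cells only, classes balanced — and
stores per-feature mean/sd for z-scoring. `knn_classify_cell()` uses
Euclidean distance on z-scored features with k = 9 by default; vote ties
break by the smaller total distance of the tied class's voters, then by
fixed class order, so classification is fully deterministic. Confidence is
winning votes / k. Negativity is never decided by k-NN — the database
contains no negative class by construction.

## Reporting rules

`aggregate_cell_results()` reports a pattern when ≥ 25% of voting cells
carry it (`min_fraction`), so a 3:1 two-pattern mixture is still called
mixed; the plurality pattern is always reported. Per-pattern confidence is
the mean over supporting cells; ties in confidence order break by support.
A positive image with zero classifiable cells becomes a `manual_review`
status rather than an error or a silent negative, matching the
computer-aided-diagnosis principle that automated results are validated by
a human. `merge_patient()` reads each pattern's titer as the highest
dilution at which it is still reported — plain endpoint reading, no
interpolation, since nothing firmer than "estimated" is established for
commercial readers — with right-censoring (">= max dilution") when a
pattern persists at the highest tested dilution. `negative_worklist()`
orders negatives by ascending intensity with sample-id tie-breaks, the
batch-validation list of routine workflows.

## Agreement statistics

`agreement_stats()` computes concordance `100·(a+d)/n`, unweighted Cohen's
kappa `(p_o − p_e)/(1 − p_e)` with
`p_e = ((a+b)(a+c) + (c+d)(b+d))/n²`, and analytical
sensitivity/specificity/PPV/NPV. Rates with empty denominators are `NA`
(undefined, not zero). Percentages round half-up to one decimal and kappa
to three — half-up, not banker's rounding, is what reproduces published
validation tables (26/32 prints as 81.3, not 81.2); the unrounded kappa is
kept alongside. The Altman bands (≤ 0.20 poor, 0.21–0.40 fair, 0.41–0.60
moderate, 0.61–0.80 good, 0.81–1.00 very good) are attached to the rounded
value. Multi-class pattern agreement is reported as per-class recognition
rates via `pattern_table()` rather than a multi-class kappa, matching how
such validations are published. The implementation is cross-checked in the
tests against an exhaustive brute-force pair-expansion oracle over all 2×2
tables up to n = 30.

## Numerical and testing choices

- **Determinism.** All randomness flows through named sub-seed streams of
  the field seed (geometry, pattern painting, per-dilution noise); images
  are quantized to the 16-bit grid at render time, so "same seed" means
  byte-identical files, which the CLI tests assert end to end.
- **Degenerate inputs.** Zero cells, blank channels, empty dilution lists,
  sub-window nuclei and constant tables all have defined behaviour (empty
  results, explicit errors naming the offender, or documented fallbacks)
  rather than incidental behaviour.
- **Problem sizes.** The test suite and the acceptance script run the
  pipeline on 512×512 fields of 14–24 cells, a 360-record reference
  database (60 per class), 70 single-pattern evaluation fields, 10
  three-dilution series and three 50-cell 768×768 segmentation fields —
  sizes chosen so the full evidence chain re-runs in a few minutes on one
  core while every gate (per-image accuracy, titer recovery, segmentation
  recall) still has enough trials to be meaningful. Package defaults for
  interactive use stay at 1024×1024 / 60 cells.
- **Evaluation seeds are disjoint from database seeds** by construction
  (the database derives its seeds in a private stream), so classifier
  gates are honest held-out measurements.

## Limitations

The generator is a minimal sufficient model, not photorealism: no optics,
fixation artefacts, bleaching, focus drift, overlapping or confluent
growth, and no cell-to-cell superposition of mixed reactivities. Passing
its gates therefore demonstrates that the evaluation chain is correct and
internally consistent — segmentation finds what is there, the classifier
separates the canonical morphologies, titers are recovered from the
amplitude law, statistics reproduce published tables — but says nothing
about performance on clinical sera, where pattern boundaries (dense fine
speckled vs homogeneous, superimposed cytoplasmic staining) are the real
difficulty. The 62-feature set is a documented stand-in for the much
larger proprietary feature sets of commercial readers, and k-NN parameters
(k = 9, Euclidean, z-scoring) were fixed a priori rather than tuned.
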