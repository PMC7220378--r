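---
title: "Methods: locomotion pharmacology with planted ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locomotion pharmacology with planted ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlipharm)
```

This vignette documents the quantitative model behind the package's
forced-locomotion drug-effect pipeline, the synthetic generator used to
verify it, and the numerical decisions made along the way.

## The measurement chain

An awake-locomotion pharmacology session consists of repeated 40 s
treadmill recordings: several pre-drug recordings, then drug application,
then post-drug recordings. Each recording yields, per ROI, a somatic and a
neuropil fluorescence trace plus a treadmill encoder trace. The pipeline
reduces this to one number per ROI per recording and then to one
classification and one regression:

1. **Neuropil correction.** `neuropil_correct()` computes
   F = F_soma − 0.7·F_neuropil. The factor 0.7 is the standard
   two-photon somatic decontamination coefficient; it is a parameter
   (`r` in `normalize_to_rest()`), not a constant.
2. **Rest normalization.** `select_least_active()` picks the recording
   with the smallest encoder distance over [0, 5) s (ties go to the lowest
   recording index). Per ROI, F_rest is the mean corrected fluorescence of
   that recording over the same window; `normalize_to_rest()` then forms
   ΔF/F_rest = (F − F_rest)/F_rest for every recording with the single
   per-ROI F_rest. Using one shared reference makes recordings
   comparable across the session; a per-recording baseline would absorb
   the very drug effects and photodynamic trends under study.
3. **Locomotion fluorescence.** `locomotion_fluorescence()` takes the
   75th percentile (R quantile type 7) of ΔF/F_rest over the motorized
   maximal-speed window [10, 25) s. A high percentile tracks transient
   locomotion-evoked activity while being robust to single-frame
   artifacts; windows are half-open, frames `floor(start·rate)` to
   `floor(end·rate) − 1`.
4. **Detrending.** Fluorescence declines slowly over a session
   (bleaching, expression run-down). `fit_decay()` fits
   f(j) = A + B·e^(−j/C) to the *pre-drug* locomotion-fluorescence values
   against the acquisition index j (1-based), via `minpack.lm::nlsLM`.
   `detrend_values()` subtracts the fitted curve from **all** recordings,
   so any post-drug change is measured against the extrapolated no-drug
   trend. If the exponential fit fails to converge, a linear fit is used
   and the result is flagged `"linear_fallback"`; constant input is
   flagged `"degenerate_constant"`.
5. **Classification.** `classify_drug_effect()` excludes the first three
   post-drug recordings (drug wash-in; with a wash-in time constant of a
   few minutes the early post-drug recordings are mixtures of the two
   states) and applies a two-sample t-test at α = 0.01, labelling each
   ROI `increase`, `decrease`, or `none`. Welch's unequal-variance form
   is the default (`drug_test_params(test_kind = "welch")`): pre- and
   post-drug samples have different sizes and, after a real drug effect,
   no reason to share a variance. A pooled-variance option is provided.
   A paired test is *not* applicable because the numbers of pre- and
   post-drug recordings differ and recordings are not paired in time.
6. **Regression.** `regress_change_vs_baseline()` regresses the per-ROI
   post-drug change (mean detrended post-drug value, wash-in excluded)
   on the pre-drug baseline (mean raw pre-drug value). The *change* is
   taken from detrended values — otherwise the session-wide decay would
   masquerade as a uniform drug effect — while the *baseline* is the raw
   pre-drug level, since "how active was this ROI before the drug" is a
   raw quantity. The report is a Pearson r, R², slope, intercept, p, and n.

Cross-session ROI identity is established first:
`estimate_translation()` searches integer shifts exhaustively (zero-mean
cross-correlation; ties resolved by smallest |dx| + |dy|, then
lexicographically) and `match_rois()` matches label masks one-to-one,
greedily by descending intersection-over-union, with an inclusive
threshold of 0.3 — permissive enough for soma outlines re-drawn days
apart, strict enough to reject neighbors.

## The synthetic generator

`gen_locomotion_block()` emulates a session with a *planted* effect model
so the full pipeline can be validated end to end:

- Per-ROI baseline locomotion fluorescence b ~ Normal(μ_b = 1.28,
  σ_b = 0.60) in ΔF/F_rest units. The Normal is **not** truncated at
  zero: truncation would shift the planted correlation (below) away from
  its closed form, and ΔF/F_rest values slightly below zero are physical
  (activity below rest).
- Post-drug change d = slope·(b − μ_b) + ε, slope = −0.65,
  ε ~ Normal(0, 0.597). The planted population correlation between
  baseline and change is then

  ρ = slope·σ_b / √(slope²·σ_b² + σ_ε²) ≈ −0.547,

  with variance explained ρ² ≈ 30%. These parameter values are the
  package's reference configuration (`loco_gen_params()` defaults), with
  n = 313 ROIs, 6 pre- and 11 post-drug recordings.
- A shared multiplicative decay f(j) = 0.1 + 0.5·e^(−j/4) is applied to
  the designed per-recording values, so the detrending step has real work
  to do.
- Traces are constructed such that the 75th percentile over the motorized
  window *equals* the designed value exactly: frame-level jitter inside
  the window is re-centered by its own empirical 75th percentile
  (percentiles are translation-equivariant), so the designed value plus
  re-centered jitter has exactly the designed percentile. This makes the
  generator→pipeline loop an identity at every noise level, not just in
  expectation.
- The observed soma trace is soma_true + 0.7·neuropil, so the pipeline's
  neuropil correction inverts the contamination exactly; F_rest levels,
  encoder traces (free-walk speeds differ per recording so
  `select_least_active()` has a unique answer), and a rigidly shifted
  pre/post mask pair (`gen_roi_scene()`) complete the inputs.

`synthetic_locomotion_run()` chains generator and pipeline for one seed;
`null_classification_rate()` runs the classification on a no-effect,
no-decay null (i.i.d. Normal values) to measure the empirical type-I
rate against the nominal α.

What the generator does **not** emulate: realistic calcium-transient
kinetics (frames are value + jitter, not convolved spike trains),
brain-motion artifacts beyond rigid translation, overlapping or
re-segmented ROIs, or wash-in dynamics (the excluded recordings are drawn
from the post-drug model, which is conservative for the exclusion test).

## Problem sizes and performance

The reference configuration (313 ROIs, 17 recordings, 1200 frames at
30 Hz, 512×512 masks) runs through the full pipeline in a few seconds on
one CPU; the 25-replicate study used by `scripts/acceptance.R` takes
about two minutes. These sizes are the package's own reference choice for
a desk-scale, statistically stable benchmark — large enough that the
fitted r is within a few hundredths of the planted ρ, small enough to run
in test suites.

## Other numerical decisions

- **Wilcoxon signed-rank (stimulation module).** `wilcoxon_signed_p()`
  uses the exact null distribution for n ≤ 25 without tied absolute
  differences, and the normal approximation with continuity correction
  otherwise; zero differences are dropped (with an all-zero flag). The
  exact branch is verified in the test suite against full 2^n sign
  enumeration.
- **Decay fitting.** `nlsLM` (Levenberg–Marquardt) with analytic-free
  starting values (A from the last point, B from the first-minus-last,
  C from the index range) and a small positive lower bound on C; verified
  against a profile grid-search oracle.
- **Annulus areas (EM module).** For a convex PSD outline the area of the
  d-buffer is exact (Steiner: A + P·d + πd²), so band areas are exact
  differences; non-convex outlines and clipped analysis regions fall back
  to grid integration at 1 nm resolution.
- **Interchange formats.** Long-format CSV for traces and encoder data,
  JSON for metadata and results, PNG for label masks (16-bit labels split
  across two 8-bit channels so any PNG codec round-trips them
  losslessly). CSV was chosen over a binary container for
  inspectability; the reference problem sizes do not need more.

## Limitations

- The planted-model validation establishes that the pipeline recovers
  known effects, not that the model describes any particular dataset.
- The type-I calibration assumes i.i.d. Gaussian locomotion-fluorescence
  values under the null; serial correlation across recordings would
  inflate the realized rate.
- Registration is integer rigid translation only; rotation, scaling, and
  non-rigid warping are out of scope.

```{r session}
sessionInfo()
```
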