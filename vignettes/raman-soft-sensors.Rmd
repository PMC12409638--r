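---
title: "Raman soft sensors for dual-stage cross-flow filtration: models, preprocessing and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Raman soft sensors for dual-stage cross-flow filtration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramancff)
```

## The monitoring problem

Virus-like particles (VLPs) precipitated with ammonium sulfate (AMS) can be
recovered by a dual-stage cross-flow filtration (CFF) train: constant-volume
diafiltration (DF) washes the precipitant out of the first membrane stage
(0.2 µm), the re-dissolved VLPs pass into a second stage whose 300 kDa
membrane retains them, and a final ultrafiltration (UF) step concentrates the
product.  A Raman probe in an on-line loop of the second stage sees both
species at once: the sulfate ion of AMS dominates the spectrum (a strong
band at 980 cm^-1, weaker bands near 451, 618 and 1106 cm^-1), while the
protein contributes far weaker features (phenylalanine 1004, tyrosine 1206,
backbone 1249, backbone/tryptophan 1341, amide I 1660 cm^-1).

This sensitivity asymmetry drives every design decision in the package.
Protein monitoring needs a long detector exposure (1250 ms), but at that
exposure the 980 cm^-1 sulfate band exceeds the detector full scale over a
wide concentration range.  The package therefore implements
*attribute-specific* preprocessing pipelines and regression models, plus the
quality control needed to transfer models calibrated on stock solutions to
on-line process spectra.

## Spectral containers

A `raman_set` couples a strictly increasing wavenumber axis (instrument
grid: 200–3300 cm^-1 at 1 cm^-1, 3101 points) with an n × p intensity
matrix, per-spectrum acquisition metadata (exposure time, diafiltration
volume, acquisition mode) and optional reference concentrations.  Interior
gaps created by pre-cropping are tracked as axis segments.  Sets round-trip
through a wide CSV layout (`wavenumber_cm-1` column plus one column per
spectrum, metadata in a `.meta.csv` companion) and, for single spectra,
JCAMP-DX.

## Preprocessing pipelines

Each pipeline is an ordered recipe applied by `run_pipeline()`:

1. **Block averaging** (50 recordings) — reduces the per-recording read
   noise by √50.
2. **OH-band normalization** (AMS pipelines only) — division by the water
   OH-stretch intensity at 3299 cm^-1.  Neither analyte nor background
   interferes there, so the normalized spectrum is invariant to exposure
   time and turbidity; this single step is what lets a model calibrated at
   175 ms predict 110 ms or 1250 ms data.  The reference intensity is the
   mean over a 5-point window (3297–3301 cm^-1) for robustness to
   single-channel noise; a strict single-point mode is available.
3. **Pre-cropping** (VLP pipelines only) — removal of the sulfate-dominated
   interior regions (P1 = 920–1030 cm^-1 or P2 = 920–1200 cm^-1) *before*
   baseline correction.  The remainder is spliced, i.e. the baseline and
   smoothing filters see one concatenated vector: a baseline fitted across
   the dominant sulfate band would otherwise leak its shoulders into the
   protein region.  Per-segment filtering is available as an option.
4. **asPLS baseline correction** (below).
5. **Savitzky–Golay smoothing** — local quadratic least squares, window 11.
   Edges are refit on the first/last full window; edge regions are
   discarded by the subsequent cropping anyway.
6. **Cropping** to the model's wavenumber intervals.
7. **Unit-variance scaling** (VIP pipelines only), using training-set
   statistics stored with the model.

The shipped configurations (`builtin_pipelines()`) are: `LR_AMS` (single
wavenumber 980), `PLS_AMS` (340–2650 cm^-1), `PLS_VIP4_AMS` /
`PLS_VIP2_AMS` (VIP-derived intervals, scaled), and the four VLP pipelines
`PLS_P{1,2}_C{1,2}_VLP` combining the two pre-crops with cropping intervals
C1 = 1203–1349 and C2 = 1331–1349 cm^-1.  AMS pipelines use baseline
penalty λ = 6·10⁷ with a second-order difference penalty and tolerance
10⁻³; VLP pipelines use λ = 10⁹ and tolerance 10⁻⁴ (P1 rows with d = 2,
P2 rows with d = 3).  Note that λ is meaningful only as a large number — a
Whittaker penalty below 1 would leave a spectrum essentially unsmoothed —
so sub-unity renderings of these settings occasionally seen in print are
read as the corresponding powers of ten.  Standard-normal-variate or
multiplicative scatter correction are deliberately not offered: they would
rescale the sulfate band, which is itself a target analyte.

## Whittaker smoother and asPLS baseline

The Whittaker smoother finds the vector *z* minimising

$$\sum_i w_i (y_i - z_i)^2 + \lambda \sum_i (\Delta^d z)_i^2,$$

solved as a sparse symmetric positive-definite banded system (no dense
n × n matrix is ever formed; `Matrix` handles the factorisation).  With all
weights equal and λ → ∞ the fit collapses onto the penalty null space, a
polynomial of degree d − 1 — a limit the test suite exploits as an analytic
oracle.  Numerically that limit is only reachable for moderate problem
sizes: the condition number grows with λ, and for n in the hundreds the
round-off floor sits near 10⁻⁵ relative at λ = 10¹²; the oracle test
therefore runs at n = 50, λ = 10¹⁰.

asPLS (adaptive smoothness penalized least squares) wraps the smoother in
an iteratively reweighted loop.  From the residuals d = y − z and the
standard deviation s of the negative residuals, weights are updated with
the logistic rule w = 1/(1 + exp(2(d − s)/s)) — points above the running
baseline (Raman peaks) are driven towards zero weight — and a per-point
adaptive factor α = |d| / max|d| relaxes the smoothness penalty where the
residual is large.  Iteration stops when the relative change of the weight
vector drops below the tolerance, or after `max_iter` (default 100)
iterations, in which case the result is returned with `converged = FALSE`
rather than an error.  Initial weights are 1.  The adaptive factor is
floored at 10⁻⁴: on long flat stretches the residuals vanish, and an
unfloored α would leave rows of the penalized system near zero, degrading
its conditioning over many iterations.

One property of asPLS worth stating explicitly: the operator is positively
homogeneous (scaling the spectrum scales the baseline) but *not* additive.
On noiseless synthetic series the full pipeline is affine in concentration
to about 3·10⁻⁸ M at the shipped tolerance, which is what the end-to-end
identity test asserts; if the loop is driven to much deeper convergence the
residual non-additivity of the adaptive weighting becomes visible at the
10⁻⁵ M level.  Models that interpolate within their calibration range are
unaffected at realistic noise levels.

## Regression models

* **`fit_linear()`** — ordinary least squares of concentration on the
  preprocessed intensity at one wavenumber (980 cm^-1, the sulfate band
  maximum).
* **`nipals_pls_fit()`** — single-response PLS1 by NIPALS: per component
  the weight vector is the normalised covariance direction X'y, scores
  t = Xw, loadings p = X't/t't and q = y't/t't, with deflation of X and y;
  the coefficient vector is b = W(P'W)⁻¹q.  Scores are mutually orthogonal
  and the full-rank fit reproduces ordinary least squares — both asserted
  against an independent Krylov-basis construction in the tests.
* **`cv_select_components()`** — one random 80/20 split (seeded,
  validation at least 3 samples); the component count is the smallest A
  whose validation RMSE is within 5 % of the minimum over the search range
  2–10.  A numerical tie floor (10⁻⁸ · sd(y)) keeps machine-noise RMSE
  differences from defeating the parsimony rule when the fit is exact.  A
  plain argmin and a repeated-split mode are available by argument.  With
  only ~3 validation samples the 5 % band is tight relative to the
  sampling noise of the RMSE estimate, so the selected count can
  occasionally flip to 3 on individual splits; the acceptance workflow
  reports the median over three splits.
* **`vip_scores()` / `select_vip_intervals()`** — variable importance in
  projection, VIPⱼ = √(p Σₐ SSYₐ (wⱼₐ/‖wₐ‖)² / Σₐ SSYₐ) with
  SSYₐ = qₐ² tₐ'tₐ, satisfying Σ VIP² = p.  Wavenumbers with VIP ≥ 1 (the
  greater-than-one convention) are grouped into runs, runs separated by at
  most 5 cm^-1 merged, and runs narrower than 5 points dropped; threshold,
  gap and width are all arguments.  `run_calibration()` re-derives the VIP
  intervals from the data for the VIP configurations rather than using the
  shipped intervals; the `PLS_VIP2_AMS` refinement additionally discards
  intervals overlapping the saturation-prone 920–1030 cm^-1 region and
  keeps the two strongest of the remainder — the construction that stays
  usable when the 980 cm^-1 band clips.

Negative concentration predictions are reported as-is (flagged, never
truncated): transfer diagnostics depend on seeing raw model output.

## Quality control

**Saturation** (`detect_saturation()`): a spectrum is flagged within the
inspection band (default 900–1060 cm^-1) if at least 3 consecutive points
lie within 0.5 % of the detector full scale, or if the band shows the
split-peak signature — two local maxima of comparable height (each within
10 % of the band maximum; both flanks of a folded band pin near the clip
level) with an interior minimum deeper than 5 % of the band amplitude.  A
band whose maximum stays below 0.9 × full scale is never flagged.  The
thresholds are heuristics calibrated on the synthetic generator and are all
exposed.  Immediately above the saturation onset the fold-back dip is
shallower than both rules, so mild oversaturation manifests as biased
predictions rather than flags; the transfer layer therefore combines flags
with model-specific gating (below).

**Defective spectra** (`detect_defective()`): the total intensity of each
spectrum, normalised by the series median (making the score invariant to
global rescaling), is compared with its rolling median; the deviation is
divided by the rolling MAD *of the deviation series*, so a smooth process
trend — which the rolling median tracks — does not inflate the robust
scale.  A spectrum is flagged when the score exceeds k = 6 *and* the
deviation exceeds 2 % of the median total: a defective spectrum is a gross
baseline shift, and the absolute floor keeps sub-percent trend curvature
over a near-zero noise floor from being flagged.  For a defect persisting
over ~1 DV of 0.1-DV blocks the rolling window must span the defect run,
which is why the transfer layer defaults to a 31-block window.

**Transfer gating** (`run_transfer()`): QC runs on the raw block-averaged
spectra; a prediction is flagged `saturated` only when the model's retained
wavenumbers intersect the detected interval.  The 980-based models (LR,
full-spectrum PLS) are gated; a VIP model restricted to the 451 and
1106 cm^-1 bands keeps reporting through band oversaturation.  Flagged
predictions are emitted with their flag, never dropped, and `report()`
excludes them from error metrics by default.

## The synthetic-data generator

No instrument data ship with the package; `generate_stock_series()` and
`generate_process_spectra()` produce spectra with the statistical structure
the analysis assumes, so every stage is testable end-to-end.

The noise-free signal is I(ν) = t · [Σ c·A·g(ν) + drift + water] with
Gaussian bands at the assignments listed above, a flat dark signal
(8 counts/ms), and a broad concentration-dependent background emulating the
baseline drift that grows with analyte concentration.  Key parameter
choices:

* The 980 cm^-1 amplitude (214 counts/(M·ms)) is calibrated so a 0.2 M AMS
  solution at 1250 ms reaches the detector full scale (65535 counts, 16-bit)
  exactly — the critical concentration at which on-line monitoring at long
  exposure starts to clip.  The secondary sulfate bands are 9–14 % of the
  main band, realistic for aqueous sulfate, and the protein:sulfate
  amplitude ratio is ≪ 1, reproducing the sensor's sensitivity asymmetry.
* The detector model folds intensities above the full scale L:
  I_obs = L − k(I − L) with k = 0.15, floored at 0.8 L and capped at L.
  This produces the split-peak artifact — two flank maxima at L with an
  interior minimum that deepens with oversaturation.
* Read noise is additive Gaussian with σ = 0.3 % of full scale per
  recording, independent of exposure time; 50-recording averaging reduces
  it by √50.
* The drift background tapers smoothly to exactly zero above 2600 cm^-1, so
  the OH normalization reference region stays interference-free — the
  physical assumption that justifies OH normalization in the first place.
* AMS calibration series co-vary the wash/re-dissolution buffer composition
  with the AMS level (proportional mixing), plus a per-level preparation
  jitter of the mixing fraction (σ = 0.02).  The jitter is the second
  latent concentration source that makes two PLS components genuinely
  necessary.  VLP dilution series carry a fixed 0.1 M residual AMS
  background.
* Optional injections for process series: probe fouling (protein-band
  signal growing linearly with DV at 0.15 g/L-equivalent per DV, without
  changing the true concentrations) and defective windows (a broad baseline
  shift of 30 % of full scale).

What the generator does **not** emulate: cosmic-ray spikes, wavelength-axis
drift, detector nonlinearity below saturation, turbidity/Mie scattering
from the precipitation step, and any mechanistic fluorescence model (the
drift is phenomenological).  Passing tests therefore demonstrate that the
pipeline logic, the transfer mechanics and the QC rules are correct under
the stated statistical assumptions — not that the shipped pipeline
parameters are optimal for any particular instrument.

## Process simulator

`simulate_cff_process()` integrates the two-stage balance on the DV axis
(deSolve, tight tolerances): stage-1 washout C₁(v) = c₀e^(−v); stage-2
cascade dC₂/dv = ρ(C₁ − C₂) with ρ the stage-1:stage-2 volume ratio.  The
closed form for ρ = 1 is C₂ = c₀ v e^(−v) (peak c₀/e at v = 1), and in
general the peak sits at v* = −ln ρ/(1 − ρ).  The default ρ = 0.35 puts
the peak at 1.62 DV, the rise-then-fall timing characteristic of the
second membrane stage.  VLP re-dissolution is a logistic function of C₁
falling below a 0.6 M threshold (width 0.08 M); dissolved VLP washes out
of stage 1 and accumulates in stage 2 (fully retained).  The UF phase
shrinks the stage-2 volume 25 → 10 mL, scaling the retained VLP
concentration by the volume ratio while the membrane-permeant AMS
concentration stays level (permeate leaves at the retentate
concentration; no buffer is added).

## Problem sizes and determinism

The test and acceptance workflows run at the study's conditions: 12 AMS
levels × 50 recordings at 175 ms (test series at 110 ms), 8 VLP levels ×
50 recordings at 1250 ms, and a 7-DV continuous process at 0.1-DV blocks
of 50 recordings.  All randomness flows through explicit seeds; rerunning
any pipeline or calibration with the same inputs is bit-identical, which
the suite asserts.  Every calibration returns a manifest (steps, seeds,
derived intervals, model checksum) sufficient to reproduce the run.

## Known limitations

* QC detection has a gap just above the saturation onset (fold-back dip
  below both rule thresholds); predictions there are biased but unflagged.
  Consumers should treat the 0.18–0.25 M range at 1250 ms as suspect when
  the 980-based models are used — or use the VIP-restricted model, which
  is insensitive to the band.
* Defective-spectrum detection near the series boundaries inherits the
  usual limitation of rolling-median filters: a defect block adjacent to
  the start of a series contaminates its own truncated window and is only
  partially flagged.
* The single 80/20 CV split prescribed for component selection has high
  variance at calibration sizes of ~12 samples; the repeated-split mode is
  recommended for real campaigns.
* VLP models do not normalize by the OH band (it degraded protein-region
  accuracy) and are therefore locked to their calibration exposure time;
  `run_transfer()` enforces this.
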