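---
title: "Two-compartment signal-fraction mapping from combined T2- and diffusion-weighted MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-compartment signal-fraction mapping from combined T2- and diffusion-weighted MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2dwi)
```

## The model

Prostate DWI is usually summarized by a single apparent diffusion
coefficient (ADC), but T2 relaxation and diffusion are not independent in
prostate tissue: water in the glandular lumen has a long T2 and a high
ADC, while intracellular (largely epithelial) water has a shorter T2 and a
lower ADC. Acquiring trace-weighted DWI at several echo times makes the
joint (T2, ADC) signature measurable with a clinically short protocol.

`t2dwi` models the magnitude signal of each voxel as a mixture of two
compartments with *paired* relaxation and diffusion properties:

$$
SI(TE, b) = SI_0\left[
  SF_{slow}\, e^{-TE/T2_{slow}}\, e^{-b\,ADC_{slow}}
  + (1 - SF_{slow})\, e^{-TE/T2_{fast}}\, e^{-b\,ADC_{fast}}
\right],
$$

with $SF_{slow} + SF_{fast} = 1$. The slow compartment (low ADC, short T2)
is approximately epithelial/cellular water — abundant in tumors — and the
fast compartment (high ADC, long T2) luminal/stromal water. Units follow
radiological convention: b in s/mm², ADC in μm²/ms, so the exponent
carries a factor $10^{-3}$; this conversion lives in exactly one place
(`attenuationBasis()`).

The default acquisition design is the 2×2 grid TE ∈ {55, 73} ms ×
b ∈ {50, 700} s/mm², i.e. four measurements per voxel, in the canonical
order sorted by (TE, b).

Two reference models are fitted for comparison, both from the two b-value
measurements at the longest TE: the bi-exponential (ADC-only) two-pool
model, and the mono-exponential ADC.

## Parameters: what is fixed, what is fitted

Four parameters per voxel would be ill-posed against four measurements, so
the component diffusivities are fixed at population values
$ADC_{slow} = 0.3$, $ADC_{fast} = 2.6$ μm²/ms, and the component T2 pair
is calibrated **once per population**: for each candidate pair on a grid
(default $T2_{slow}$ ∈ 20–100 ms in 5 ms steps, $T2_{fast}$ ∈ 100–400 ms
in 10 ms steps, constrained to $T2_{slow} < T2_{fast}$), every pooled
training voxel is refitted and the pooled cost — the sum of per-voxel RMSE
— is recorded (`calibrateT2()`). The argmin of the surface is the
population T2 pair; exact cost ties break deterministically toward the
smallest $T2_{slow}$, then $T2_{fast}$. The grid brackets published
prostate compartment T2 values (epithelium ≈ 50 ms, stroma ≈ 80 ms,
lumen ≫ 100 ms). The pooled cost is summed on raw-intensity residuals, so
brighter voxels weigh more; `gridCost(perVoxelNormalize = TRUE)` exposes
the per-voxel-normalized alternative.

With the decays fixed, each voxel's fit is *linear* in
$(a, b) = (SI_0 SF_{slow}, SI_0 SF_{fast})$: a two-column non-negative
least-squares problem, convex with a unique minimizer and no
initialization or seed. Non-negativity of both components is what
constrains $SF_{slow}$ to [0, 1]; the model itself is silent on bounds,
but signal fractions are physical proportions. The 2-variable NNLS is
solved in closed form (unconstrained normal equations; if infeasible, the
better of the two single-component boundary solutions).

## Voxel exclusion

Two rules run before any fitting (`buildExclusionMask()`):

* **Noise floor.** The noise floor is the mean background (air) magnitude
  across all measurements; a voxel is excluded if *any* measurement is
  ≤ 3× that floor. The boundary is inclusive: exactly 3× is excluded.
* **Negative apparent decays.** A voxel is excluded if its signal rises
  with b at fixed TE (apparent ADC < 0) or rises with TE at fixed b
  (apparent T2 < 0). On a 2×2 design this is the only computable reading
  of "negative apparent ADC or T2": every adjacent pair along each axis
  is tested by sign, which is exactly equivalent to the log-ratio decay
  rate and needs no logarithms. Equality (zero decay) is kept.

Excluded voxels carry `NA` in every output map — never zero, because zero
is a legal signal fraction. An explicit background mask is required; the
package refuses to guess which voxels are air.

One boundary subtlety in the bi-exponential two-point fit: a *rising*
b-decay lies beyond the pure-slow end of the model range (the attenuation
ratio increases monotonically with $SF_{slow}$), so the exact solution
clips to $SF_{slow} = 1$, not 0; the voxel is flagged and is in any case
removed upstream by the sign rule.

## The phantom

The synthetic cohort generator stands in for the patient data, which are
not publicly available as raw volumes. Each patient is a 24×24×6 voxel
(2×2×3 mm) grid holding a box-shaped "prostate" region filled with
stroma-like tissue, lesion ellipsoids (radii 2.5×2.5×1.5 voxels, jittered
per patient) carved into it, and an air slab providing the background
region. Patient types carry the clinical ROI multiplicities: one tumor
region per cancer patient, plus one normal reference region when the
tumor is in the peripheral zone; one nodule region per BPH patient.

Default class parameters (slow signal fraction, mean ± patient-level sd,
with additional voxel-level sd):

| class  | mean | patient sd | voxel sd | rationale |
|--------|------|------------|----------|-----------|
| tumor  | 0.75 | 0.06       | 0.05     | high epithelial fraction |
| bph    | 0.65 | 0.06       | 0.07     | mimics tumor, slightly lower |
| stroma | 0.45 | 0.03       | 0.10     | heterogeneous background |
| normal | 0.30 | 0.06       | 0.05     | glandular, high ADC |

These are design choices, not measured values; they place tumor and
benign tissue on the same side of the classification threshold and normal
tissue on the other, the contrast structure the statistics modules need.
All classes share the generating T2 pair (45, 180 ms) so the pooled
calibration target is well-defined.

Noise is Rician — magnitudes are $\sqrt{(S+\epsilon_1)^2+\epsilon_2^2}$
with independent Gaussians of sd σ — because the inputs are MRI magnitude
images and the 3×-noise-floor rule needs a realistic floor
($\bar{|n|} = \sigma\sqrt{\pi/2}$ in air). The class base signal is
scaled so the class-mean SNR at the least-attenuated measurement
(TE 55 ms, b 50 s/mm²) is 40. On top of the base, per-voxel $SI_0$
carries log-normal heterogeneity (default sdlog 0.8) emulating
receive-coil sensitivity profiles and proton-density variation; this
value was calibrated once so that roughly 10% of tissue-region voxels
trip the exclusion rules at the default noise level — the exclusion rate
reported for the in-vivo cohort — and is not revisited per run.

Grade labels follow a minimal monotone mechanism: GGG is the clipped
rounding of an affine map of the patient's true tumor mean $SF_{slow}$
(slope: one grade per 0.06 of fraction, centered at grade 3 / fraction
0.75) plus Gaussian label noise (sd 2.0 grade units). The noise level is
chosen to give *fair* (≈ 0.3–0.5) population rank correlations rather
than strong ones, matching the regime the method is expected to operate
in; any one 31-patient test split scatters widely around that.

What the phantom does **not** emulate: anatomically realistic geometry,
partial-volume mixing at lesion borders, EPI distortion, motion between
measurements (inputs are co-registered by construction), diffusion-time
dependence of ADC, and Rician bias *correction* (the fits consume raw
magnitudes, as in the clinical analysis). Passing tests therefore show
the estimation and evaluation machinery is correct under the stated
model, not that the model captures everything in real prostate data.

## Cohort structure and statistics

The default cohort mirrors the clinical arms: 31 training + 31 test
cancer patients (25 and 24 with peripheral-zone tumors respectively) and
14 BPH patients. The evaluation reproduces the clinical analysis plan:

* paired Wilcoxon signed-rank tests, PZ tumor vs normal region means on
  the test set (24 pairs), per metric; zero differences dropped, exact
  distribution for n ≤ 25 non-zero pairs;
* unpaired Mann-Whitney U tests, non-PZ tumor (13) vs BPH (14) region
  means on all patients;
* Bonferroni over the 9 comparisons (3 metrics × 2 tests + 3
  correlations), working level 0.05/9 ≈ 0.006;
* voxel-wise ROC, test-set tumor-ROI voxels vs all other valid voxels
  inside the test-set box regions, per metric. AUC uses the rank
  (Mann-Whitney) formulation with mid-rank tie handling. Polarity is
  higher-is-tumor for both signal fractions and lower-is-tumor for ADC;
* the "optimal" threshold maximizes Youden's J on *training-set* voxels
  — the criterion is unstated in the clinical analysis, and Youden is the
  conventional reproducible reading — with J-ties broken toward the cut
  classifying fewer voxels as tumor. Test sensitivity/specificity are
  computed at that fixed threshold; test labels never inform it;
* Spearman ρ (mid-ranks, t-approximate p) between test-set tumor region
  means and GGG. Raw p-values and the adjusted α are reported separately
  rather than folded into a significance verdict.

## Numerical and design choices

* Measurement order is always the (TE, b)-sorted cross product;
  serialized volumes and tables are deterministic.
* The voxel NNLS and the two-point closed forms are exact; residuals are
  computed directly (not via the normal-equation identity) to avoid
  cancellation at noise-free inputs.
* All randomness flows from explicit integer seeds; a cohort is
  reproducible bit-for-bit from its spec, and geometry and noise carry
  separate derived seeds so one geometry can host independent noise
  realizations.
* Degenerate inputs: all-zero or non-finite voxels are invalid, not
  errors; an all-excluded ROI is an error naming the ROI; an empty
  background mask is an error naming the missing mask.
* Desk-scale problem sizes: phantom volumes hold 1024 box voxels per
  patient (the clinical boxes average ~167,000), and the calibration pool
  is capped at 20,000 voxels by seeded subsampling. Because the pooled
  cost is a sum over voxels, subsampling rescales the surface without
  moving its minimum in expectation; the cap and the grid are
  configurable.

## Known limitations

* The two-point bi- and mono-exponential fits are exact interpolants, so
  their per-voxel RMSE carries no information (zero for mono by
  construction); model comparison rests on the discrimination metrics.
* The phantom's tissue classes are internally homogeneous ellipsoids;
  between-class partial-volume voxels, which drive part of the in-vivo
  exclusion rate and threshold behavior, are absent.
* Magnitude bias at low SNR (Rician floor) biases fitted fractions in dim
  voxels; the exclusion rules bound but do not remove this, exactly as in
  the clinical processing chain.
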