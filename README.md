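# t2dwi

Two-compartment signal-fraction mapping from combined T2- and
diffusion-weighted MRI (T2-DWI) of the prostate.

Conventional prostate DWI compresses each voxel into one apparent
diffusion coefficient (ADC). But T2 and ADC are coupled in prostate
tissue: luminal water has long T2 and high ADC, cellular (epithelial)
water short T2 and low ADC — and tumors are epithelium-rich. Acquiring
trace-weighted DWI at two echo times (TE = 55, 73 ms) and two b-values
(b = 50, 700 s/mm²) gives a 2×2 measurement matrix per voxel, enough to
fit a two-component model with *paired* relaxation/diffusion properties:

```
SI(TE, b) = SI0 [ SFslow · exp(−TE/T2slow) · exp(−b·ADCslow)
                + (1 − SFslow) · exp(−TE/T2fast) · exp(−b·ADCfast) ]
```

with SFslow + SFfast = 1, b in s/mm², ADC in μm²/ms. The component
diffusivities are fixed (ADCslow = 0.3, ADCfast = 2.6 μm²/ms) and the
component T2 pair is calibrated once per population by a pooled grid
search minimizing the summed per-voxel fit RMSE over a training set, so
only (SI0, SFslow) are fitted per voxel — a convex non-negative linear
least-squares problem with a unique solution. The slow signal fraction
SFslow is the tumor marker: it is compared against conventional
bi-exponential and mono-exponential ADC fits via rank tests, voxel-wise
ROC with a training-derived threshold transferred to the test set, and
Spearman correlation with Gleason Grade Group.

The package is aimed at quantitative-MRI researchers: it implements the
signal models, the pre-fit voxel exclusion rules (noise floor, negative
apparent decays), the T2 calibration, a Rician-noise digital phantom
emulating a 76-patient cohort, the statistical evaluation, NIfTI I/O and
an end-to-end pipeline. See the vignette in `vignettes/` for the methods
account.

## Worked example

Forward-simulate one voxel and fit it back:

```r
library(t2dwi)
sch <- AcquisitionScheme()     # TE {55, 73} ms x b {50, 700} s/mm2
bas <- ComponentBasis()        # ADC (0.3, 2.6) um2/ms, T2 (45, 180) ms
s <- twoComponentSignal(100, 0.67, sch, bas)
round(s, 2)
#> [1] 40.79 19.94 32.35 14.29
fitTwoComponentVoxel(s, sch, bas)[c("si0", "sfSlow")]
#> $si0
#> [1] 100
#> $sfSlow
#> [1] 0.67
```

Run the full pipeline on the default phantom cohort (31 train / 31 test
cancer patients, 14 BPH; ~1 min on one CPU):

```r
res <- runPipeline(pipelineConfig(cohortSpec(seed = 7)))
res$calibration
#> CostSurface: 17 x 31 grid, pooled over 20000 voxels
#>   optimum: t2Slow = 45 ms, t2Fast = 180 ms (cost 12075.4)
res$diagnostics[, c("metric", "auc", "threshold", "sensitivity", "specificity")]
#>            metric   auc threshold sensitivity specificity
#> 1  sfTwoComponent 0.986     0.626        93.4        95.1
#> 2 sfBiExponential 0.976     0.333        91.5        93.6
#> 3         adcMono 0.976     1.357        91.5        93.6
```

The grid search recovers the generating T2 pair (45, 180 ms); the
two-component slow fraction separates tumor from non-tumor voxels
slightly better (AUC 0.986) than the two ADC-only references (0.976),
with the classification threshold (SFslow ≥ 0.63) sitting between the
tumor (0.75) and background (0.45) class means. For ADC the polarity is
reversed: a voxel must fall *below* the threshold (1.36 μm²/ms) to be
called tumor. Sensitivity/specificity are computed on the test set at
the training-derived threshold. Exclusion removed ~12% of tissue-region
voxels (`res$qcSummary`), and the rank tests / grade correlations are in
`res$stats`.

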