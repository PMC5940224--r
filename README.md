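# matvqsm

Quantitative susceptibility mapping (QSM) recovers the tissue magnetic
susceptibility distribution χ (ppm) from the local tissue field map φ that
MRI phase processing produces.  The forward model is diagonal in k-space,

    φ = Fᴴ D F χ,      D(k) = 1/3 − (k·b̂₀)²/|k|²,  D(0) = 0,

and D vanishes on the magic-angle cone, so the inversion is ill-posed.
This package reconstructs χ by weighted total-variation regularization:

    χ̂ = argmin_χ ‖W_m (Fᴴ D F χ − φ)‖₂² + λ ‖W_∇m ∇χ‖₁

with a magnitude-proportional fidelity weight W_m and a per-axis TV weight
W_∇m derived from the magnitude gradients.  Two weightings are built in:

* **MEDI-style hard threshold** — W_∇m = 1(|∇m| < c): the ~30 % of
  gradient voxels classified as boundary get no TV constraint;
* **MATV soft threshold** — W_∇m = 1 below c and sin((π/2)·c/|∇m|) at and
  above it: continuous at c, inversely proportional to the gradient at
  strong edges, and strictly positive, so edges keep a reduced — but
  nonzero — TV constraint.

The threshold c is the smallest value for which at most a target fraction
(default 30 %) of pooled in-mask gradient components lie at or above it.
The solver is smoothed-L1 Gauss–Newton with inner conjugate gradients, the
scheme of the published MEDI solver family, so the two modes differ in
nothing but the weight map.  The package is aimed at QSM method developers
and students of regularized dipole inversion: it is fully self-contained,
shipping a synthetic five-balloon gadolinium phantom simulator
(susceptibilities 0.05/0.1/0.2/0.4/0.8 ppm), evaluation metrics
(RMSE %, HFEN %, SSIM, ROI regression), NIfTI-1 I/O, and a CLI.

## Worked example

```r
library(matvqsm)

study <- simulateStudy(defaultPhantomSpec(), snr = 50, seed = 1)
wm <- computeDataWeight(study@magnitude, study@mask)
ew <- edgeWeights(study@magnitude, study@mask, fraction = 0.3, mode = "matv")
ew$threshold
#> EdgeThreshold c = 0.0305949 (target fraction 0.3, achieved 0.3)

D <- makeDipoleKernel(volumeGrid(study@field))
res <- solveMATV(study@field, wm, ew$weight, D,
                 SolverConfig(lambda = 0.0017), mask = study@mask)
res
#> SolveResult: 10 outer iterations (max iterations), objective 142.699 -> 9.26001

evaluateQSM(chiMap(res), study@chiTrue, study@mask)
#> MetricReport (n = 124800 in-mask voxels)
#>   RMSE    6.64 %
#>   HFEN    5.33 %
#>   SSIM  0.8802

roiRegression(chiMap(res), study@chiTrue, study@rois)
#> RegressionResult: slope 0.9755, intercept -0.003015 ppm, R^2 0.9999 (5 ROIs)
```

The threshold line says 30 % of magnitude-gradient components were
classified as boundary; the metric report compares the reconstruction with
the known ground truth inside the phantom mask (RMSE and HFEN are relative
error norms in percent, lower is better; SSIM closer to 1 is better); the
regression slope near 1 with R² ≈ 1 means the five balloon
susceptibilities are recovered essentially unbiased.  Swapping
`mode = "medi"` reruns the identical pipeline with the hard threshold —
on this study it gives RMSE 9.25 %, HFEN 6.06 %, SSIM 0.856 and a higher
mean absolute error over boundary voxels, the behavior the soft weighting
is designed to improve on.

## Command line

```sh
matvqsm simulate    --out study/ --shape 64 --snr 50 --seed 1
matvqsm reconstruct --field study/field.nii.gz --magnitude study/magnitude.nii.gz \
                    --mask study/mask.nii.gz --out chi.nii.gz \
                    --weight-mode matv --lambda 0.0017 \
                    --reference study/chi_true.nii.gz
matvqsm evaluate    --recon chi.nii.gz --reference study/chi_true.nii.gz \
                    --mask study/mask.nii.gz \
                    --rois study/roi_1.nii.gz,study/roi_2.nii.gz,study/roi_3.nii.gz,study/roi_4.nii.gz,study/roi_5.nii.gz
matvqsm weights     --magnitude study/magnitude.nii.gz --mask study/mask.nii.gz --out w
```

(`exec/matvqsm` is installed with the package; run it via
`Rscript <library>/matvqsm/exec/matvqsm …` or put it on your PATH.)
Every flag can also be supplied through `--config file.cfg`, a flat
`key = value` text file.

## Method vignette

`vignettes/matv-qsm.Rmd` documents the model, the weight-function design
(including why the soft threshold uses the inverse-argument sine), the
solver, the phantom generator's assumptions, and known limitations.
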