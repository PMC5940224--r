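---
title: "Morphology-adaptive TV regularization for quantitative susceptibility mapping"
author: "matvqsm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphology-adaptive TV regularization for quantitative susceptibility mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matvqsm)
```

## The inverse problem

Tissue magnetic susceptibility $\chi$ (in ppm) perturbs the main field of an
MR scanner; after phase unwrapping and background-field removal (both
upstream of this package), the measured local tissue field $\varphi$ (also
ppm) is the convolution of $\chi$ with the unit dipole response.  In k-space
the model is diagonal,

$$\varphi = F^H D F \chi, \qquad
  D(\mathbf{k}) = \frac{1}{3} - \frac{(\mathbf{k}\cdot\hat{b}_0)^2}{|\mathbf{k}|^2},
  \quad D(\mathbf{0}) = 0,$$

where $F$ is the 3D DFT and $\hat b_0$ the main-field direction.  $D$
vanishes on the magic-angle cone ($3\cos^2\theta = 1$, $\theta \approx
54.7^\circ$ from $\hat b_0$), so the inversion of $\varphi$ for $\chi$ is
ill-posed: direct deconvolution amplifies noise into streaking artifacts
along the cone.

The reconstruction solved here is

$$\hat\chi = \arg\min_\chi \; \|W_m (F^H D F \chi - \varphi)\|_2^2
  + \lambda \|W_{\nabla m}\, \nabla\chi\|_1,$$

with $W_m$ a diagonal fidelity weight proportional to the magnitude image
(phase noise is inversely proportional to signal magnitude; we normalize
$W_m$ to unit in-mask mean so $\lambda$ is invariant to the magnitude's
arbitrary scale), $\nabla$ the periodic forward-difference operator, and
$W_{\nabla m}$ a per-axis, per-voxel weight in $[0,1]$ derived from the
magnitude gradients.  The penalty is the anisotropic weighted total
variation.

## The morphology-adaptive weight

A threshold $c$ is chosen so that approximately 30% of the pooled in-mask
magnitude-gradient component values lie at or above it ("boundary"
voxels) — precisely, the smallest $c$ whose tail fraction does not exceed
the target, i.e. the 70% quantile for continuously distributed gradients.
Two weightings are provided:

* **hard (MEDI-style)**: $w = \mathbf{1}(|\nabla m| < c)$.  Boundary voxels
  receive no TV constraint at all; reconstruction noise concentrates there.
* **soft (MATV)**: $w = 1$ for $|\nabla m| < c$ and
  $w = \sin\!\big(\tfrac{\pi}{2}\, \tfrac{c}{|\nabla m|}\big)$ otherwise.

The soft weight is continuous at $|\nabla m| = c$ (where the sine reaches
$\sin(\pi/2) = 1$), decreases monotonically with gradient strength, and for
strong edges behaves as $(\pi c / 2)/|\nabla m|$ — inversely proportional
to the magnitude gradient and *strictly positive*.  Every voxel therefore
keeps some TV regularization; edges are merely penalized less than smooth
regions.  This is the design point of the method: the hard threshold trades
edge preservation for unregularized noise at boundaries, while the soft
weight preserves edges *and* suppresses boundary noise.

A note on the functional form: with the threshold inside the sine written
the other way around, $\sin(\pi |\nabla m| / (2c))$, the expression turns
negative beyond $2c$ and would have to be clamped, removing the TV
constraint entirely from the strongest edges.  We use the inverse-argument
form because it is the one consistent with a weight that is inversely
proportional to the gradient, positive everywhere, and distinct in kind
from the hard threshold; empirically it is also the form under which the
soft weighting outperforms the hard one near edges (see the acceptance
script), whereas the clamped form makes the soft mode strictly *more*
regularized than MEDI everywhere and inverts the comparison.

Both modes threshold each gradient component against the single pooled $c$,
and weights are zeroed outside the mask, where no reliable morphology
exists.  The magnitude gradient uses the same forward-difference stencil as
the penalized $\nabla\chi$, so weight and gradient live on the same
staggered locations.

## Solver

The objective fixes the model; the choice of minimizer is an
implementation decision.  We use the smoothed-L1 Gauss-Newton scheme of the published MEDI
solver family, which keeps the hard-threshold comparison mode faithful —
the two modes differ in nothing but the weight map:

1. smooth $|g| \approx \sqrt{g^2 + \varepsilon^2}$
   ($\varepsilon = 10^{-6}$ ppm/voxel by default);
2. at each outer iteration freeze the IRLS weights
   $v = 1/\sqrt{g^2+\varepsilon^2}$ at the current iterate and solve the
   normal equations
   $\big(A W_m^2 A + \tfrac{\lambda}{2} \nabla^T \mathrm{diag}(w\,v) \nabla\big)\,\delta = -\tfrac{1}{2}\nabla f$
   (with $A = F^H D F$, self-adjoint) by conjugate gradients to 1%
   relative residual (at most 100 iterations);
3. backtrack (step halving) in the rare case the exact — unsmoothed —
   objective would not decrease, zero the update outside the mask, and stop
   when the relative update norm falls below 1% or after 10 outer
   iterations.

The weight enters the penalty to the first power, $\lambda \sum w |g|$,
matching $\|W_{\nabla m}\nabla\chi\|_1$ with $W$ diagonal and
non-negative; for the binary hard weights first and second powers coincide.
The reported objective trace uses the exact L1 term, so the monotonicity
guarantee is about the true objective with $\varepsilon$ small.
Initialization is $\chi_0 = 0$: the smoothed objective is convex, so the
starting point affects iteration count only, and the solver is fully
deterministic.  Periodic boundary conditions are used throughout
(differences and FFTs share the same convention, making the
difference/divergence pair an exact adjoint pair); the mask confines the
physically meaningful voxels.  Differences are per voxel index, with grid
anisotropy absorbed by the data-driven weights — the convention of the
MEDI implementations this package's comparison mode mirrors.

Defaults: $\lambda = 7\times10^{-4}$ (the value used for in vivo brain);
the gadolinium phantom uses $\lambda = 1.7\times10^{-3}$.  Within the
solver, $\lambda$ trades fidelity against smoothness: the package asserts
(as a property test) that the total variation of the solution is
non-increasing in $\lambda$ over two decades.

## Synthetic phantom

`defaultPhantomSpec()` emulates the classic gadolinium balloon phantom:
five spheres with susceptibilities 0.05, 0.1, 0.2, 0.4 and 0.8 ppm in a
zero-susceptibility gel background, on a $64^3$ grid with isotropic 1 mm
voxels and $\hat b_0 = +z$, radii 6–8 voxels (desk-scale but
edge-resolving).  `simulateStudy()` applies the forward dipole model and
adds Gaussian noise to the *field map* with
$\sigma = \max_\text{mask}|\varphi| / \mathrm{snr}$ (default snr 50) —
additive field-domain noise, because the artifact enters the pipeline after
phase processing, which is out of scope.  The magnitude image is
piecewise constant (sphere level 2, gel level 1) plus Gaussian noise of
$\sigma = \mathrm{level}/\mathrm{snr}$ truncated at zero: without
magnitude noise the gradient distribution is discrete and the 30% boundary
rule degenerates; with it, gradients are continuously distributed as in
real GRE magnitude data, which is exactly the regime the threshold rule
presumes.  The support mask is a sphere enclosing all balloons, emulating
the gel container.

The optional `edgeMismatch` flag suppresses one sphere's magnitude
contrast: an edge present in $\chi$ but invisible in $m$, the documented
failure mode of all magnitude-prior methods (putamen/white matter have weak
magnitude contrast but strong susceptibility contrast, and get
oversmoothed).

What the simulation does *not* emulate: realistic anatomy, multi-echo
complex-signal (Rician) noise coupling between magnitude and field,
residual background fields and unwrapping errors, or multi-orientation
(COSMOS) acquisitions.  Tests passing on this phantom show the inversion,
weighting and metrics are correct and that the soft/hard contrast behaves
as designed; they do not certify in vivo image quality.

## Numerical choices and degenerate inputs

* $D(\mathbf 0) = 0$ enforces a zero-mean simulated field, the standard QSM
  convention; samples exactly on the magic-angle cone keep their formula
  value 0 — ill-posedness is handled by the regularization, not by kernel
  truncation.
* Frequencies are physical (cycles/mm) from the voxel size, so anisotropic
  voxels orient the kernel correctly; only the ratio
  $(\mathbf{k}\cdot\hat b_0)^2/|\mathbf{k}|^2$ matters.
* The r-space convolution reference (`rspaceConvolutionOracle`) samples
  $d(\mathbf r) = (3\cos^2\theta - 1)/(4\pi r^3)$, $d(\mathbf 0) = 0$, on
  the same periodic minimal-image lattice as the FFT path, so the two are
  comparable to machine precision.
* Degenerate inputs fail loudly rather than silently: zero magnitude in
  the mask (no fidelity weight), identically zero magnitude gradient (no
  threshold), zero reference norm or dynamic range (metrics), fewer than
  two ROIs (regression), overlapping spheres (phantom).
* With heavily tied gradient values the smallest-$c$ rule can only
  undershoot the target boundary fraction; the achieved fraction is
  reported alongside $c$.  If every pooled value is identical, $c$ is
  placed just above it and nothing is boundary.
* HFEN uses a $15^3$, $\sigma = 1.5$ voxel Laplacian-of-Gaussian kernel
  (zero-sum, so constants are annihilated), SSIM a $\sigma = 1.5$ Gaussian
  window with $C_1 = (0.01L)^2$, $C_2 = (0.03L)^2$ and $L$ the reference's
  in-mask dynamic range — the parameterizations of the metrics' source
  literature, since QSM papers typically quote the metrics without
  parameters.

## Problem sizes

The test suite and the acceptance script work at the generator's native
scale: one $64^3$ study with one MATV and one MEDI-mode reconstruction
(about 1.5 minutes each at 10 outer iterations), a $48^3$ single-sphere
recovery, and $8^3$–$32^3$ problems for operator algebra, solver
optimality (checked against a general-purpose L-BFGS minimizer of the
smoothed objective) and metric closed forms.

## Worked example

```{r example, eval = FALSE}
study <- simulateStudy(defaultPhantomSpec(), snr = 50, seed = 1)
wm <- computeDataWeight(study@magnitude, study@mask)
ew <- edgeWeights(study@magnitude, study@mask, fraction = 0.3,
                  mode = "matv")
D <- makeDipoleKernel(volumeGrid(study@field))
res <- solveMATV(study@field, wm, ew$weight, D,
                 SolverConfig(lambda = 0.0017), mask = study@mask)
evaluateQSM(chiMap(res), study@chiTrue, study@mask)
roiRegression(chiMap(res), study@chiTrue, study@rois)
```

## Known limitations

* Magnitude-derived priors mislead wherever magnitude and susceptibility
  boundaries disagree (`edgeMismatch` reproduces this).
* $\lambda$ is not selected automatically; L-curve/GCV/SURE-style selection
  is out of scope.
* Periodic boundaries mean objects close to the volume edge see wrapped
  field contributions; keep a margin of background around the object (the
  phantom generator does).
* The linear field fidelity assumes unwrapping and background removal were
  successful; nonlinear complex-domain fidelity variants are not
  implemented.
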