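---
title: "Benchmarking saliency methods against a synthetic ventricular-dilation ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking saliency methods against a synthetic ventricular-dilation ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Deep regressors that estimate brain age (BA) from T1-weighted MRI are hard to
trust without knowing *which voxels* drive the estimate. Attribution
("saliency") methods promise exactly that, but their outputs are rarely
validated: on real scans nobody knows the true importance of each voxel.
`ventbench` builds a setting where the truth *is* known. A known,
age-proportional anatomical change — dilation of the lateral ventricles into
adjacent white matter — is injected into one of two otherwise identical
training cohorts. Two networks with identical architectures are trained on
the unperturbed (ND) and perturbed (D) cohorts. Because the injected signal's
location is known exactly, the cohort-average absolute difference between
perturbed and unperturbed volumes is a *surrogate ground truth* against which
any saliency map can be scored.

## The phantom and what it does (and does not) emulate

Real multi-site MRI cohorts are access-restricted, so the benchmark generates
synthetic subjects: two ellipsoidal lateral ventricles inside a white-matter
ellipsoid wrapped by a gray-matter shell, on a dark background, with
FreeSurfer-style label codes (left/right lateral ventricle 4/43, white matter
2, gray matter 3). Intensities are tissue means plus zero-mean Gaussian noise
clipped at zero; defaults (CSF 30, gray 70, white 110 on an arbitrary T1w-like
scale) give the contrast a convolutional network needs, with CSF and white
matter separated by far more than two pooled standard deviations.

Age is encoded *solely* through ventricle size: the ellipsoid semi-axes grow
linearly with the latent age (base radius 1.5 voxels, slope 0.04 voxels/year
on the default 32^3 grid, ages uniform over 40–90 years). Growing ellipsoids
are nested, so the ventricle voxel set is non-decreasing in age — a property
the tests assert over a 20-age sweep. An optional cortical-thinning switch
adds a second age effect but is off by default: with a single age-coding
structure, the perturbation ground truth is the *only* age signal, which is
the cleanest test of the benchmark's logic. The linear age-to-anatomy map is
a modeling choice; real aging is not linear, and the phantom makes no claim
about MRI physics (no bias fields, skull, registration error, or
partial-volume effects). Passing benchmarks on phantoms therefore shows that
a saliency method can recover a *known, localized* signal through a trained
network — not that it behaves identically on clinical data.

## The perturbation

Each subject receives a dilation coefficient from their age: 0 at or below
the cohort's 5th age percentile, 1 at or above the 95th, linear in between
(linear-interpolation empirical percentiles). The ventricle's outermost
(edge) voxels are found with 6-connected (face) neighborhoods — the most
conservative deterministic reading of "adjacent" — and their non-ventricle
face-neighbors are split into adjacent white matter (AWM) and adjacent
non-white matter (ANWM). Exactly `round(coefficient * |AWM|)` AWM voxels
(rounding half away from zero, so a coefficient of 0.8 with 100 AWM voxels
converts exactly 80), drawn uniformly without replacement under a derived
seed, take the intensity and label of their nearest ventricle edge voxel
(ties broken toward the smallest linear index). Voxels that thereby become
the new ventricle boundary can optionally be redrawn from the empirical ANWM
intensity distribution to keep boundary statistics realistic; in the default
phantom the ventricles are fully embedded in white matter, ANWM is empty, and
the re-draw is a no-op. A coefficient of zero is a strict no-op.

The ground truth is the across-subject mean of |perturbed − original|,
normalized to sum to 1; its support is every voxel with a strictly positive
mean difference.

## The regressor

The network follows the four-block 3D CNN design: each block is a 6^3
convolution (stride 1), batch normalization, ReLU, and 2^3 max-pooling, with
dropout 0.2 on blocks 2–4; a flatten and two dense layers produce the scalar
BA estimate. Filter counts default to 16/32/64/128 and training uses MAE
loss with Adam (learning rate 1e-4) and early stopping after 20 epochs
without validation improvement. Choices the architecture description leaves
open were resolved as follows: convolutions use "same" padding so the
pooling arithmetic holds at any power-of-two input; ReLU follows batch
normalization; the dense head is flatten → dense(128) → ReLU → dense(1) with
no ReLU on the output (the output is a standardized age and must take
negative values); pooling saturates once the spatial extent reaches one
voxel, which admits small test configurations. Targets are standardized by
the training cohort's age mean and standard deviation, so the output layer
starts near the cohort center; MAE is always reported in years. A hard
`max_epochs` cap (default 200) bounds runs, and batch size defaults to 8.
The forward/backward passes are implemented in the package (C++ kernels via
im2col and BLAS for convolution and pooling), and the input gradients they
produce are verified against central finite differences.

## The attribution methods

Seven methods are implemented over two generics (`predict_scalar()`,
`input_gradient()`), so each can also be exercised on analytically solvable
models: plain gradient (G), input × gradient (IXG), masked gradient (MG;
gradient zeroed outside the brain mask, which is derived from the label
volume as all non-background voxels), guided backpropagation (GB; negative
incoming backward signals zeroed at every ReLU), GradCAM (channel-gradient
weighted, ReLU-rectified activation of the final convolutional block,
upsampled trilinearly), guided GradCAM (GGC = GB × GradCAM), integrated
gradients (IG; Gauss–Legendre quadrature with 50 nodes along the straight
path from an all-zero baseline, satisfying completeness to quadrature
accuracy), and gradient SHAP (GSHAP; 5 Gaussian noise draws, baselines drawn
from the unperturbed cohort, gradient at a uniform random interpolation
point; its noise standard deviation defaults to 0.1 × the input's intensity
standard deviation). Batch normalization and dropout are always in
evaluation mode during attribution, making every method except GSHAP
deterministic, and GSHAP deterministic under its seed. Absolute values are
taken only at density normalization (|attribution| / Σ|attribution|), never
inside a method, since positive and negative saliencies are deliberately not
distinguished. GradCAM can legitimately produce an all-zero map for a
subject (its ReLU may close everywhere); such subjects are skipped in the
cohort average rather than given an undefined density.

## Scoring

Cohort-average saliency densities are compared to the ground truth with five
measures: Sorensen–Dice (DC) on binarized supports, normalized mutual
information (NMI, the `(H(A)+H(B))/H(A,B)` variant ranging 1–2, 64
equal-width bins per map), normalized scanpath saliency (NSS, mean z-scored
saliency over the ground-truth support), Pearson correlation (CC), and
histogram intersection (SIM, sum of voxelwise minima of two densities). The
binarization needed by DC is matched-cardinality thresholding — the top
`|support|` saliency voxels, ties broken by value then index — because it
needs no arbitrary threshold and makes DC = 1 achievable; a fixed-percentile
alternative is available. Each method is reported as a percentage difference
from the MG baseline, and the MG row of the D-versus-ND contrast summarizes
how much the injected perturbation sharpened the saliency. All five
measures are cross-checked against independent brute-force implementations
in the test suite.

## Desk-scale study conditions

The package's reference experiment (`desk_experiment_config()`) is sized for
a single CPU: 200 training phantoms at 32^3 voxels (80/20 train/validation)
plus 12 held-out subjects, a slimmed network with filters 4/8/16/32 and
dense width 64, learning rate 1e-3, batch 8, and at most 6 epochs. The
32-voxel grid keeps all four pooling stages meaningful while making a full
paired run (two trainings, seven methods, scoring) take a few minutes; the
filter counts and learning rate were chosen once for that budget and
verified only to produce models that clearly beat the constant-age
predictor. At this scale the benchmark reproduces directional findings —
every measure on the MG maps increases from the ND to the D model, and the
masked/interpolation methods (IXG, MG, IG, GSHAP) concentrate far more
saliency mass inside the brain than G, GB and GGC — but the absolute
percentage differences of a GPU-scale 128^3 study are not expected to
transfer, and single seeds can deviate (the acceptance suite asserts the
directions over a majority of three seeds).

## Numerical conventions and edge cases

Empirical percentiles use R's default linear interpolation (type 7).
Standard deviations are the sample (n−1) convention throughout, including
the NSS z-scoring. Zero-variance saliency defines NSS as 0 with a warning;
a constant map makes CC an error (undefined) and NMI 1 with a warning; two
empty supports give DC 1, exactly one empty gives 0; a baseline measure of
exactly 0 leaves its percentage-difference column undefined rather than
infinite. Modal label downsampling breaks ties toward the smallest label
code. All randomness flows from per-stage seeds derived from one master
seed, so every artifact — including the written CSVs — is byte-reproducible
from the configuration alone.

## Running it

```r
library(ventbench)
cfg <- desk_experiment_config(seed = 1, out_dir = "bench-out")
bundle <- run_experiment(cfg, verbose = TRUE)
bundle$reports$D          # five measures per method against the ground truth
bundle$pct$D              # percentage differences vs the MG baseline
bundle$delta              # D-vs-ND change per method and measure
report_markdown(bundle, file.path(cfg$out_dir, "report.md"))
```

## Known limitations

The phantom's single age-coding structure makes the task easier than real
brain aging, where many structures change together; the paired design and
the directional claims are what transfer, not effect sizes. The network is
far smaller than a production BA estimator, and training for a handful of
epochs leaves run-to-run variability that the multi-seed acceptance checks
absorb but do not eliminate. Occlusion-style attribution methods, SmoothGrad
and DeepLIFT are out of scope, as are real-MRI preprocessing, registration,
and atlas overlays.
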