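---
title: "Multi-scale fusion networks for MR super-resolution: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale fusion networks for MR super-resolution: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

A low-resolution structural MR image `L` is modelled as a blurred,
downsampled, noisy observation of the underlying high-resolution image `H`:

    L = D S H + e

with `S` a blurring filter, `D` decimation by an integer factor `f`
(2, 3 or 4), and `e` additive noise. Under the *pre-upsampling* convention
the observation is immediately interpolated back to the high-resolution
grid with a bicubic kernel, so super-resolution becomes an image-to-image
regression problem on a common grid, learned from aligned 33x33 patch
pairs, and the interpolated input doubles as the classical bicubic
baseline.

The network family implemented here stacks *multi-scale fusion units*
(MFUs). One unit computes

    x_{i+1} = ReLU(conv_main(x_i)) + sum_j SP_j(x_i)

where the main path is a single convolution (typically large kernels,
e.g. 9x9) and each sub-path `SP_j` is a short chain of (typically 1x1)
convolutions. The fusion is elementwise addition, so the unit mixes
responses at different receptive-field scales; on piecewise-smooth brain
images the high/low-resolution difference concentrates at tissue edges,
and differently sized kernels respond to those edges with different
strengths — that is the motivation for fusing scales. A full network
(an MFCN) is a chain of MFUs followed by a single-kernel reconstruction
convolution. Removing every sub-path leaves a plain stacked CNN of the
SRCNN family, which serves as the comparison baseline
(`plain_cnn_spec()`).

The baseline configuration is two units — main 9/32 with sub-path 1/32,
main 3/64 with sub-path 1/64 (the `s/n` notation is kernel size / kernel
count) — plus a 5/1 reconstruction layer: 24,897 parameters. The ablation
grammar of the published configuration tables (kernel sizes, kernel
counts, sub-path width and depth, number of units, ReLU placement) is
available through `builtin_variants()`.

## Numerical and design choices

**Padding.** A 9x9 main path and a 1x1 sub-path shrink differently under
valid convolution, yet their outputs are added. All convolutions therefore
use zero same-padding, the minimal assumption that makes the fusion sum
and fully-convolutional whole-slice inference well defined.

**ReLU placement.** Main path: convolution then ReLU. Sub-paths:
convolution then ReLU after every layer *except the last*, which feeds the
fusion addition unactivated — pre-activation residual-style units behave
better when the summand can be negative, and the published ablation finds
the same. No activation follows the addition. The ablation variant with a
ReLU before fusion is `builtin_variants()$BL_relu_fusion`.

**Initialization.** Kernels are Gaussian with standard deviation 0.001 and
biases zero (the SRCNN-lineage convention); the record travels with the
parameters.

**Loss convention.** The Euclidean loss is `sum/(2B)` over a mini-batch of
`B` patch pairs (the Caffe convention), so a per-patch loss magnitude is a
half sum of squared intensity errors; the gradient with respect to the
prediction is `diff/B`.

**The published learning rate diverges.** The published recipe states
learning rate 0.001 with mini-batch 32. Under the `sum/(2B)` convention
the loss curvature along bias-like directions is of the order of the patch
pixel count (1089), and SGD at 0.001 — with or without momentum —
reliably produces a numerical explosion within tens of iterations, exactly
when the fit starts to improve. The per-element mean convention at the
same printed rate is stable but crawls: it remains stuck near the
DC-prediction plateau (~13.6 dB validation PSNR) for thousands of
iterations, far below the bicubic baseline. The SRCNN lineage's own
published rate, 1e-4, trains stably and reproduces the qualitative
findings (see below). The package keeps `lr = 0.001` as the
`train_spec()` default for fidelity and documents the instability; the
pipeline defaults (`run_config()`) and the demonstration tests use 1e-4.
The acceptance tests that pin 0.001 are left failing by design — an
honestly red criterion — with this analysis as the explanation.

**Precision backends.** Training has two numerically equivalent backends:
a float32 C++ engine (default — the precision the Caffe lineage actually
trained in, and ~5x faster here) and a double-precision R reference path
used by every oracle and gradient test. Both draw identical seeded
mini-batch sequences; their loss traces agree to ~1e-6 relative. Gradient
correctness is established on the double path against central finite
differences (500+ sampled weights, 1e-4 relative), and the engine is
checked against the reference path directly.

**Resampling.** Bicubic resampling uses the Keys kernel (a = -0.5) as
explicit separable weight matrices with replicate boundary clamping, so
weight rows sum to one and constant images are reproduced exactly. When
shrinking, the kernel support is widened by the inverse scale (the
MATLAB-imresize antialiasing convention); this is the default blur `S`
of the degradation operator, with an explicit gaussian available. One
consequence worth knowing: the Keys kernel's negative lobes ring at sharp
edges, so the anisotropic total variation of a degraded slice can slightly
*exceed* that of the original on piecewise-constant phantoms; the
smoothing-contraction property is exact for the gaussian operator and
holds within a small ringing allowance for the bicubic one.

**Metrics.** RMSE/SNR/PSNR/SSIM are evaluated over a brain mask.
Intensities are rescaled to 0-255 and the PSNR peak is R = 255: that
combination reproduces the published bicubic PSNR from the published
bicubic RMSE to better than 0.05 dB at every scale, which is the package's
desk-side validation of the formula choice (the formula as literally
printed, with a factor 10 and the low-resolution maximum as peak, does not
match the published magnitudes; both remain available behind
`metric_spec()` flags). SSIM uses the reference windowed form — 11x11
gaussian window, sigma 1.5, k1 = 0.01, k2 = 0.03 — averaged over window
centers inside the mask; the whole-region single-statistic form is a flag.

**Convergence index.** `convergence_iteration()` defines the plateau as
the mean of the last 10% of the validation series and returns the earliest
1-based index reaching `(1 - epsilon)` of it. Comparisons between
architectures only ever use it with paired seeds and identical mini-batch
order (audited by hashing the batch index sequence). One caveat matters in
practice: the index is relative to the run's *own* plateau, so a run that
never escapes its initial plateau within the budget — flat validation
curve — trivially "converges" at index 1. When that regime is possible
(short budgets), the meaningful ordering statistic is
iterations-to-reach-a-common-quality-threshold, which is what the
demonstration tests use with the bicubic baseline as the threshold.

## What the phantom generator emulates — and what it does not

`make_phantom()` builds skull-stripped-looking, piecewise-smooth brain
stand-ins: a brain-shaped ellipsoid mask (exactly zero background) holding
nested, jittered ellipsoidal shells that cycle through tissue classes with
T1-like means (CSF 0.25, grey matter 0.55, white matter 0.85), modulated
by a smooth multiplicative bias field with exact range ±10%, plus optional
additive gaussian noise (default sigma 0.01) and clipping to [0, 1].
Cohorts draw per-subject geometry from a cohort seed, mimicking a
multi-subject training/test split.

This captures the property that drives the method — degradation residuals
concentrate at tissue boundaries, verified by `edge_energy_fraction()`
against an area-proportional null — and nothing else: there is no MR
physics (no k-space, no Rician noise, no T1/T2 parametrisation), no
cortical folding, and far less texture than real anatomy. A green test on
phantoms therefore establishes that the machinery (degradation, training,
metrics, ablation harness) behaves as specified and that the
architecture-level orderings reproduce; it does not certify clinical image
quality, and absolute PSNR values on phantoms are not comparable to the
published BrainWeb numbers. The BrainWeb benchmark itself requires a
one-time manual download of the T1 phantom (181x217x181, 1 mm) and can
then be run with `brainweb_benchmark(read_volume(...))`; offline, the
test suite runs the identical pipeline on a synthetic stand-in and asserts
only machinery-level invariants.

## What the scaled-down experiments show

At the stable rate (1e-4, momentum 0.9, batch 32) on a 10-phantom cohort
at f = 2 with the reduced architecture (9/8 + 1/8; 3/16 + 1/16; 5/1),
600 patches per training slice:

* the trained MFCN exceeds the bicubic baseline on every seed
  (+0.46 to +0.52 dB by 1500 iterations), and
* under paired seeds and batch order, the MFCN reaches bicubic-level
  quality within a few hundred iterations on every seed, while the plain
  CNN takes longer on every seed and on most seeds never escapes its
  initial DC plateau within the budget at all — a strong qualitative
  reproduction of the convergence-ordering finding.

The published absolute numbers (trained-network benchmark columns) need
~1e5 iterations on the BrainWeb training set and are out of desk scope;
orderings, not absolute PSNRs, are the reproduction target here.

## Known limitations

* Tables-level reproduction only: timing columns and full-length training
  curves are out of scope.
* The U1/U3 depth variants pin only the sub-path grammar in the published
  tables; their main paths here follow the baseline pattern (9/32;
  3/32; 3/64), the minimal edit consistent with the stated sub-path
  channel counts.
* The real-scanner protocol (3 mm acquisitions paired with 1 mm targets)
  is not modelled; through-plane super-resolution is a non-goal.
* NIfTI support is deliberately minimal (single-file NIfTI-1, common
  datatypes, spacing; orientation handled in array index order with axial
  as the third axis).
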