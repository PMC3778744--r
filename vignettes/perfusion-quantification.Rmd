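---
title: "Perfusion quantification by truncated-SVD deconvolution: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perfusion quantification by truncated-SVD deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perfmap)
```

## The quantification model

Dynamic-contrast perfusion imaging acquires a 3D brain volume repeatedly
while a contrast bolus passes through the vasculature, giving every
voxel a concentration time curve $C_t(t_1),\dots,C_t(t_N)$ at a fixed
sampling interval $\Delta t$. The indicator-dilution model relates each
tissue curve to the arterial input function (AIF) $C_a$ measured in a
feeding artery:

$$C_t = C_a \otimes h + \epsilon,$$

where $h$ is the tissue's impulse response (flow-scaled residue)
function and $\epsilon$ is acquisition noise. On the regular grid the
convolution is a matrix product: the operator is the
$\Delta t$-scaled lower-triangular Toeplitz matrix

$$\mathbf{C}_a = \Delta t \begin{pmatrix}
C_a(t_1) & 0 & \cdots & 0\\
C_a(t_2) & C_a(t_1) & \cdots & 0\\
\vdots & \vdots & \ddots & \vdots\\
C_a(t_N) & C_a(t_{N-1}) & \cdots & C_a(t_1)
\end{pmatrix},$$

built by `build_aif_matrix()`. Because the matrix is triangular its
determinant is $(\Delta t\, C_a(t_1))^N$: the system is formally
invertible whenever the first AIF sample is nonzero, but for a smooth
bolus the rows are near-linear combinations of one another and the
inversion is severely ill-conditioned. `perfmap` therefore solves the
system by truncated SVD: with $\mathbf{C}_a = U\,\mathrm{diag}(w)\,V^T$,
singular values strictly below `rel_threshold` $\times\, w_{\max}$ are
zeroed and the voxel's response is

$$\hat h = V\,\mathrm{diag}(w_i^{-1}\ \text{or}\ 0)\,U^T C_t .$$

The threshold is *relative* (a fraction of the largest singular value)
so that rescaling the AIF does not change which components are kept.
Whether to truncate on a relative or an absolute scale is a genuinely
open choice in this family of methods; the relative rule was chosen for
its scale invariance. The boundary case $w_i = \tau\,w_{\max}$ is kept
(strict less-than truncates). The default `rel_threshold = 0.2` is the
customary value in the perfusion-SVD literature and is fully
configurable (`--svd-threshold` on the command line).

From $\hat h$ and $C_t$ the per-voxel parameters are:

| map | definition | unit |
|-----|------------|------|
| CBF | $\max_t \hat h(t)$ | IRF amplitude |
| CBV | $\Delta t \sum_t \max(\hat h(t), 0)$ | amplitude · s |
| MTT | CBV / CBF | s |
| TTP | $\Delta t\,\cdot$ (0-based index of the first maximum of $C_t$) | s |
| TA  | $\Delta t\,\cdot$ (0-based index of the first sample $\ge$ `rise_frac` $\times \max C_t$) | s |

Two conventions deserve emphasis:

* **MTT is CBV/CBF**, the central volume theorem. Statements of the
  method occasionally print the inverted ratio; the procedural
  definitions (and physical units) make CBV/CBF the only consistent
  choice, and that is what this package computes.
* **CBV discretizes the integral as $\Delta t \sum$** rather than a bare
  sum, so results are invariant under temporal resampling, and negative
  lobes of $\hat h$ -- truncation ringing, not physiology -- are clipped
  to zero in the sum only. CBF uses the raw maximum, so a genuinely
  positive peak is never masked. A voxel is *invalid* (NaN in all maps)
  when CBF or CBV is not strictly positive.

Maps are in relative units. Absolute quantification in ml/100 g/min
requires tissue-density and hematocrit constants that are deliberately
out of scope.

## Arterial input functions

Three modes are supported (`aif_mode` in `run_config()`):

* **file** -- the user supplies the AIF (plain-text vector, one value
  per line, or an `aif_vector`). This bypasses all selection heuristics
  and is the right choice when an AIF has been measured independently.
* **global** -- one AIF for the whole brain, selected automatically:
  every in-mask voxel curve is scored by
  $\text{peak} / (1 + \text{zero-based time-to-peak index})$
  and the `global_top_k` (default 5) best curves are averaged. The score
  encodes the two properties the literature uses to recognise arterial
  voxels: a high and an early bolus. Ties break deterministically by
  ascending voxel index.
* **local** -- one AIF per voxel, the same scoring restricted to the
  cubic neighbourhood of half-width `local_radius` (default 5 voxels)
  around the target voxel; if fewer than `local_top_k` candidates have a
  positive peak the global AIF is used as fallback, so a usable kernel
  always exists. Local AIFs relax the assumption that contrast reaches
  the whole brain simultaneously -- the assumption that fails precisely
  in acute stroke -- at a cost of one SVD per voxel instead of one per
  run (the engines count these; see `n_svd` on the result).

The selection heuristic is deliberately simple and replaceable; there is
no universally agreed vessel-detection criterion, and a user-supplied
AIF always takes precedence.

## Preprocessing

Denoising is an optional 2D, 3D or 4D weighted-mean filter
(`kernel_spec()`), applied on the voxel-major layout in the same pass as
reorganisation. Border handling truncates the window to its in-bounds
part and renormalises the weights over it -- chosen over zero padding,
which darkens edges. Any normalised kernel preserves a constant field
exactly, and the output is always bounded by the local window extremes.
No radius or weights are canonical for this filter family; the defaults
(uniform weights, radius 1) are this package's choice. Note that a 4D
kernel averages along time and therefore blunts fast boluses; the 3D
spatial kernel is the safer default when the sampling is coarse.

Baseline correction (`baseline_frames`) subtracts the per-voxel mean of
the leading pre-bolus frames; masking (`mask_frac`, default 0.15)
excludes voxels whose time-averaged intensity falls below that fraction
of the volume maximum. Both are off/mild by default because the pipeline
treats its input as already being concentration-like curves.

## The two engines and the identity contract

`run_serial()` processes voxels in index order; `run_parallel()`
partitions them into chunks (one axial slice per chunk by default,
matching the natural slice-wise result collection of this pipeline; any
fixed voxel count also works) and distributes chunks over a pool of R
worker processes. Each worker holds one reusable deconvolution
workspace, allocated once and recycled across its chunks -- the CPU
analogue of a pre-allocated scratch-memory pool -- and each result is
written at the voxel's global index.

The two engines are guaranteed **bit-identical**: every voxel's result
is produced by the same function executing the same floating-point
operation sequence, voxels never participate in cross-voxel reductions,
and scheduling only changes *when* a voxel is processed, never *how*.
The test suite asserts bitwise equality across worker counts and chunk
sizes, including chunk sizes that do not divide the volume. Voxels are
chunked rather than dispatched individually because process scheduling
overhead would dominate per-voxel dispatch on CPU worker pools.

Determinism extends run-to-run: the pipeline contains no randomness (the
generator's noise is seeded and drawn before the engines see the data),
so identical inputs and configuration reproduce identical bytes.

## The digital phantom

`build_phantom()` emulates a bolus passage with known ground truth:

* a gamma-variate arterial curve
  $C_a(t) = A\,(t - t_0)^{\alpha} e^{-(t - t_0)/\beta}$ (unit peak by
  default), with the first sample floored at $10^{-6} A$ so the
  convolution matrix is never exactly singular;
* tissue regions carrying exponential residues
  $h(t) = \mathrm{CBF}\cdot e^{-(t - \text{delay})/\mathrm{MTT}}$, zero
  before the arrival delay;
* an arterial block carrying the AIF at 3x amplitude (vessel-like
  signal, and what the global-AIF selector should find);
* background at a constant baseline; seeded i.i.d. Gaussian noise
  everywhere.

The forward model uses the *same* discrete convolution operator the
solver inverts, so noise-free recovery at threshold 0 is an exact
algebraic round trip rather than an approximation claim -- the package's
strongest correctness anchor, asserted at $10^{-6}$ relative error
(measured: $\sim 10^{-15}$). Ground truth is recorded in the same
discrete terms the pipeline can attain: CBF as the maximum of the
sampled residue, CBV as its clipped $\Delta t$-sum, MTT as their ratio.
Preset region delays are positive multiples of $\Delta t$, which makes
the sampled residue attain its nominal peak exactly (the discrete/
nominal CBV ratio is recorded per region as `correction`).

Two bolus regimes are provided deliberately:

* `tiny` (and the scale presets) uses a *sharp* bolus
  ($\alpha = 2, \beta = 1$ s) that rises within one sampling interval.
  Its operator has condition number $\approx 20$, so the exact
  round-trip anchor is numerically meaningful.
* `tiny-smooth` uses a slow-rise bolus ($\alpha = 3, \beta = 1.5$ s)
  whose operator condition number exceeds $10^{13}$ at 40 samples. This
  is the ill-posed regime that motivates truncation: at 5% noise the
  untruncated solution is useless (median CBF error $\sim 10^{11}$)
  while threshold 0.2 brings it to $\sim 0.2$. On the well-conditioned
  sharp bolus, by contrast, truncation only *adds* bias -- regularise
  when the problem is ill-posed, not reflexively.

One subtlety the tests document: at threshold 0 on noisy data the MTT
estimate is biased *upward* by noise rectification -- the CBV sum clips
negative noise excursions but keeps positive ones -- so the
truncation-bias trend (MTT bias growing with the threshold) is asserted
over thresholds that actually truncate the spectrum (0.1-0.3), with the
untruncated point dominated by the rectification effect instead.

The phantom emulates curve shapes, amplitude relations, arrival delays
and sensor noise. It does **not** emulate vascular geometry, partial
volume, bolus dispersion and delay between artery and tissue,
susceptibility artifacts, or the nonlinear signal-to-concentration map
of real scanners -- passing tests demonstrate the correctness of the
numerics, not clinical validity on real data.

## Numerical choices and degenerate inputs

* All computation is in 64-bit floating point after load; maps are
  written as float32 NIfTI.
* Argmax ties (TTP, AIF scoring) take the first occurrence; AIF top-k
  ties break by ascending voxel index.
* An all-truncated spectrum (possible only for a zero matrix) is an
  error; an all-zero voxel curve is not -- it yields an invalid voxel.
* Degenerate display ranges render at LUT index 0; voxels outside the
  validity mask render black.
* Reading a NIfTI header trusts its time step only when it is positive
  *and* carries a declared time unit (s/ms/us); otherwise `dt` must be
  supplied, because writers normalise an absent step to 1.
* The generic LU determinant is numerically untrustworthy for these
  Toeplitz operators beyond roughly 45 time points (relative errors can
  exceed unity); structural identities are asserted through the exact
  triangular diagonal product instead.

## Problem sizes used by the test suite

The unit and property tests run on 16 x 16 x 2 x 40 phantoms (seconds
per test); the scale check runs the full 128 x 128 x 22 x 80 MR-size
phantom end to end through the chunked engine (about half a minute, a
few hundred MB). The 128 x 128 x 11 x 44 CT-size preset is validated at
the spec level. These sizes were chosen so the whole suite gives quick
feedback while still exercising the engines at a clinically realistic
volume.

## Known limitations

* No delay/dispersion-insensitive variant (block-circulant SVD) and no
  Tikhonov or iterative regularisation; the truncated SVD of the causal
  Toeplitz operator is sensitive to tracer arrival preceding the AIF.
* AIF selection is heuristic; partial-volume correction of the AIF is
  out of scope.
* Maps are relative, not absolute, quantities.
* DICOM ingestion, motion correction and spatial resampling are out of
  scope; input is a 4D NIfTI-1 series.
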