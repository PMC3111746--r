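---
title: "Slicewise quality control for diffusion-weighted MRI: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slicewise quality control for diffusion-weighted MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwiqc)
```

## The artifact and the detection model

A diffusion-weighted acquisition consists of one 3-D volume per
diffusion-encoding direction $\vec g_j$ at diffusion weighting $b$. Subject
motion during the diffusion preparation of a single excitation destroys the
signal of the slices acquired in that excitation, producing volumes in
which one or a few axial slices are strongly attenuated while the rest of
the volume is intact. Because each volume contributes one direction to the
tensor fit, the standard remedy is to eliminate the whole corrupted volume.

The detector works on per-slice mean intensities. With $\bar a_j$ the mean
intensity of a given slice position in volume $j$ and $\bar a_i$ the same
slice in a comparison volume $i$, the relative pairwise deviation is

$$\Delta I_{ji} = \frac{|\bar a_i - \bar a_j|}{\bar a_i + \bar a_j} \in [0, 1],$$

a scale-free quantity (invariant under global intensity rescaling,
symmetric, zero iff the means agree). Slice means differ legitimately
across volumes because different encoding directions attenuate anisotropic
tissue differently; comparisons are therefore weighted by direction
similarity, $w_{ij} = |\vec g_i \cdot \vec g_j|$, and the per-slice score of
volume $j$ is the weighted mean over its $V-1$ comparison volumes,

$$\Delta I_j = \frac{\sum_{i \ne j} w_{ij}\, \Delta I_{ji}}{\sum_{i \ne j} w_{ij}}.$$

A volume is flagged as soon as one evaluated slice has
$\Delta I_j$ above the threshold. The statistic is computed separately per
b-shell (default split at 500 s/mm²), because slice means of low-b and
high-b volumes are not comparable.

Two deliberate readings are built into the default form of the score:

* **Antipodal weighting.** The diffusion-weighted signal depends on the
  encoding direction only through the quadratic form $\vec g^T D \vec g$,
  so it is invariant under $\vec g \to -\vec g$; antipodal directions carry
  identical contrast and must be maximally similar. The default weight is
  therefore $|\vec g_i \cdot \vec g_j|$; a signed variant (clipped below at
  zero) is available via `qc_config(antipodal_weights = FALSE)`.
* **Weight normalization.** Dividing by $\sum w_{ij}$ rather than by the
  raw comparison count makes the score of a uniform dropout with residual
  signal fraction $a$ equal to $(1-a)/(1+a)$ — e.g. $1/3$ at half signal —
  independent of how many directions were acquired and how they are spread.
  An unnormalized $\tfrac1N\sum w_{ij}\Delta I_{ji}$ variant
  (`normalize_weights = FALSE`) exists, but its scale shrinks with the mean
  pairwise weight of the scheme (about $0.5$ for a uniform hemispherical
  set), which would make a fixed flagging threshold acquisition-dependent:
  at threshold 0.2 a half-signal dropout (raw score $\approx 0.17$) would
  escape. The normalized form keeps the clean-data scores well below 0.2
  and dropout scores well above it, which is what makes the threshold
  transferable; this is the package's own calibration choice.
* **Self-comparison.** The sum runs over $i \ne j$: including the index
  volume (weight 1, deviation 0) would only dilute the statistic.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `threshold` | 0.2 | flagging bound on $\Delta I_j$ (dimensionless). Uniform dropouts of attenuation $\le 0.5$ score $\ge 1/3$, so any value in 0.2–0.3 flags the same volumes; 0.2 is the conservative end. |
| `b_split` | 500 s/mm² | shell boundary; volumes with $b \le$ split form the low shell. |
| `background_floor` | 5 % of the shell's 99th-percentile intensity | slices whose *median* slice mean across volumes falls below the floor are not evaluated. At the apex and base of the head the means are noise-dominated and the ratio $\Delta I_{ji}$ becomes unstable. The median (not the minimum) over volumes is used deliberately: a strong dropout pushes its own slice mean toward zero, and a per-volume rule would let the corrupted slice exclude itself. |
| `antipodal_weights` | `TRUE` | see above. |
| `normalize_weights` | `TRUE` | see above. |

Low-b anchor volumes (and $b = 0$ volumes, which carry a zero direction
vector) are compared with uniform weight 1 within their shell: at
$b \approx 100$ s/mm² direction contrast is negligible.

### Review statistics

Alongside the flags, `run_qc()` reports, per (volume, slice) cell of the
high shell, the number of voxels deviating from their direction-weighted
mean across the other volumes by more than 2 direction-weighted standard
deviations (weighted first and second moments with the same $w_{ij}$; the
band is strict, so exactly replicated volumes count zero). This voxel-level
map, rendered by `render_review_panel()`, is the visual-review complement
to the slice-level statistic: corrupted cells light up in both.

## Tensor fit and FA

The tensor is estimated by ordinary least squares on log-signals: row $v$
of the design is
$(-b g_x^2, -b g_y^2, -b g_z^2, -2b g_x g_y, -2b g_x g_z, -2b g_y g_z, 1)$
against $\log S_v$, giving the six tensor components and $\log S_0$; the
exponentiated intercept is the effective unweighted image. Low-b volumes
enter as ordinary rows with their true b-value. No weighting or iterative
refitting is applied — the plain linear fit is the method under study, and
it is what the QC protects. Numerical guards:

* intensities are clamped to $\max(S, 10^{-4}\,\hat S_0)$ before the
  logarithm ($\hat S_0$ = per-voxel mean over the lowest shell), because
  the Rician magnitude floor can produce zeros;
* the fit refuses rank-deficient designs (fewer than 6 distinct
  non-antipodal directions plus an anchor — also enforced by `apply_qc()`
  after volume removal);
* negative fitted eigenvalues are clipped to 0 before FA, keeping
  $\mathrm{FA} = \sqrt{\tfrac12}\,
  \frac{\sqrt{(\lambda_1-\lambda_2)^2 + (\lambda_2-\lambda_3)^2 +
  (\lambda_1-\lambda_3)^2}}{\sqrt{\lambda_1^2+\lambda_2^2+\lambda_3^2}}$
  inside $[0, 1]$;
* the default foreground mask is $S_0$ above 10 % of its 99th-percentile
  maximum, since no anatomical mask exists for a phantom.

FA smoothing (`smooth_map()`, FWHM in mm, $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$)
uses masked renormalized convolution — map and mask indicator are smoothed
separately and divided — so values near the brain edge are not diluted by
background zeros and constants are preserved exactly. Smoothing is for
reporting parity with group pipelines and is off by default.

## What the synthetic phantom emulates — and what it does not

`build_phantom()` + `simulate_signal()` emulate a single-shell clinical
protocol: 64 directions at $b = 1000$ s/mm² on a deterministic spherical
Fibonacci hemisphere plus 8 anchors at $b = 100$ s/mm², 2.3 mm isotropic
voxels, 40 axial slices, Rician noise (magnitude of two Gaussian channels,
$\sigma$ = mean foreground $S_0$ / SNR), and multiplicative whole-slice
dropouts with ground-truth labels. The default phantom contains an
isotropic region ($\lambda = 0.7 \times 10^{-3}$ mm²/s, FA 0) and an
anisotropic region with eigenvalues $(1.7, 0.3, 0.3) \times 10^{-3}$ mm²/s
(FA ≈ 0.80). The anisotropic region's per-voxel principal directions
sample the sphere quasi-uniformly (identically in every slice), emulating
the orientation diversity that dominates whole-slice means in real brain
tissue — this is what keeps clean-data $\Delta I_j$ far below threshold in
vivo, and a phantom meant to validate the threshold must reproduce it. A
coherent fixed-axis region (`phantom_region(direction = "fixed")`) is
available for studying the opposite extreme; a fully coherent phantom is an
adversarial input for any slice-mean statistic, since its slice means swing
strongly with direction.

Simulated at SNR 20 with the default scheme, the clean-data maximum
$\Delta I_j$ is ≈ 0.025 — an order of magnitude below the threshold — and
injected dropouts with attenuation ≤ 0.6 are recovered with sensitivity
and specificity 1, identically at thresholds 0.2 and 0.3. Noise also sets
a floor on FA itself: in the isotropic region the fitted FA has median
≈ 0.05 at SNR 20–30 (the eigenvalue-dispersion statistic is positively
biased under noise), halving as SNR doubles and vanishing in the
noise-free limit.

The phantom does **not** model: partial-slice or interleave-striped
dropouts (real dropout profiles are richer than uniform attenuation),
eddy-current and susceptibility distortion, cardiac pulsation, spatially
varying coil sensitivity, or realistic brain geometry. Passing the
simulation suite therefore demonstrates the statistic's behaviour under
its stated signal model, not performance on any particular scanner's data;
on real data the threshold retains its meaning because the score of a
uniform dropout is scheme-independent by construction, but background
masking and partial dropouts deserve visual review (`render_review_panel()`).

## Problem sizes and determinism

The test suite validates the deviation computation against an independent
brute-force double loop (100 random instances, tolerance $10^{-12}$),
tensor recovery on random symmetric-positive-definite tensors (50 tensors,
tolerance $10^{-10}$, plus an independent per-voxel `lm()` cross-check),
FA rotational invariance ($10^{-8}$), and detection on 20 independently
seeded corrupted acquisitions (32 + 4 volumes on a 24 × 24 × 30 grid,
attenuations drawn from [0.2, 0.5], SNR 20). The full-size acceptance runs
use the default 32 × 32 × 40 phantom with 64 + 8 volumes at SNR 20 —
sizes chosen so the whole validation executes in well under a minute while
keeping ≥ 30 well-spread directions, where the weighted statistic is in
its intended regime. Every stochastic step draws from an explicit seed
through `withr::with_seed()`; nothing reads or perturbs the global random
state, so identical inputs and seeds give byte-identical results.

## Known limitations

* Exclusion is the only repair: no registration-based correction or
  outlier replacement, and no rigid-body pre-alignment (registration of
  high-b volumes across differing contrasts is its own hard problem).
* The statistic is 2-D (slicewise) by design; artifacts that scale a whole
  volume uniformly change no slice *relative to the others in that
  volume*, but are still caught because all their slices deviate from the
  other volumes.
* Volumes are flagged per subject and shell in native space; no
  population-level criteria are applied.
* FA is the only derived scalar; mean/axial/radial diffusivity and
  tractography are out of scope.
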