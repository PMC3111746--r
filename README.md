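# dwiqc

Slicewise quality control and tensor fitting for diffusion-weighted MRI
(DWI).

## The problem

In diffusion tensor imaging (DTI), one 3-D volume is acquired per diffusion
gradient direction. Spontaneous subject movement during the diffusion
preparation destroys the signal of individual axial slices of individual
volumes ("slice dropout"). Left in the data, such volumes bias the tensor
fit and every scalar derived from it — most prominently fractional
anisotropy (FA) — which matters for studies of movement-disorder
populations, where the patients who move most are exactly the ones whose
data need the most care. dwiqc implements an automated, threshold-based
detector for these volumes, the tensor/FA pipeline needed to quantify the
effect of removing them, and a synthetic phantom simulator with
ground-truth artifact labels for validating the detector end to end.

## The statistic

For every volume *j* and every axial slice position, the mean slice
intensity ā<sub>j</sub> is compared against the same slice in every other
volume *i* of the same b-shell through the relative deviation

> ΔI<sub>ji</sub> = |ā<sub>i</sub> − ā<sub>j</sub>| / (ā<sub>i</sub> + ā<sub>j</sub>) ∈ [0, 1],

and the per-slice score is the direction-weighted average

> ΔI<sub>j</sub> = Σ<sub>i≠j</sub> w<sub>ij</sub> ΔI<sub>ji</sub> / Σ<sub>i≠j</sub> w<sub>ij</sub>,  w<sub>ij</sub> = |g<sub>i</sub> · g<sub>j</sub>|,

where g are the diffusion-encoding unit vectors: directions with similar
encoding see similar anatomy-driven contrast, so they are the fair
comparison partners. A volume is eliminated as soon as one of its slices
exceeds a threshold (default 0.2; detection is insensitive to the exact
value between 0.2 and 0.3, since a uniform dropout of attenuation *a*
scores (1 − a)/(1 + a), e.g. 0.33 at half signal). The statistic is applied
separately per b-shell, and background slices are excluded by a robust
floor. Tensors are then fitted by ordinary least squares on log-signals
(which also yields an effective b = 0 image as the exponentiated
intercept), FA is computed from the tensor eigenvalues, and
with/without-QC FA maps are compared voxelwise.

## Worked example

Simulate a 72-volume single-shell acquisition (64 directions at
b = 1000 s/mm², 8 anchors at b = 100 s/mm², 2.3 mm voxels, 40 slices,
SNR 20) from the built-in phantom, corrupt 5 volumes with slice dropouts at
60 % residual signal, and run QC:

```r
library(dwiqc)
truth  <- build_phantom()
scheme <- default_gradient_scheme(64, 8)
ds  <- simulate_signal(truth, scheme, snr = 20, seed = 42)
inj <- inject_artifacts(ds, artifact_spec(volume = c(7, 19, 33, 46, 58),
                                          slice_lo = 10, slice_hi = 12,
                                          attenuation = 0.6))
report <- run_qc(inj$dataset)
report
#> <qc_report> 72 volumes, 40 slices; 5 volume(s) flagged at threshold 0.2
#>   flagged volumes: 7, 19, 33, 46, 58
subset(report$worst_slice, flagged)
#>    volume_index shell worst_slice   delta_I flagged
#> 7             7  high          12 0.2317816    TRUE
#> 19           19  high          11 0.2381989    TRUE
#> 33           33  high          11 0.2322789    TRUE
#> 46           46  high          11 0.2331409    TRUE
#> 58           58  high          10 0.2384422    TRUE
```

All five corrupted volumes (and no clean ones) exceed the 0.2 threshold —
their scores sit near the theoretical (1 − 0.6)/(1 + 0.6) = 0.25 for a
uniform 0.6 attenuation. Scoring against the simulator's ground truth and
quantifying the effect of the cleanup on FA:

```r
evaluate_detection(report, inj$truth)
#>   tp fp fn tn sensitivity specificity jaccard
#> 1  5  0  0 67           1           1       1

fa_all <- compute_fa_map(inj$dataset, mask = truth$mask)
fa_qc  <- compute_fa_map(apply_qc(inj$dataset, report$flagged_volumes),
                         mask = truth$mask)
fa_difference_report(fa_all, fa_qc)
#>        median       mean        p95        p99       max  frac_ge_0.1 n_voxels
#> 1 0.005158931 0.00909332 0.03113385 0.07092571 0.1191321 0.0006751543    20736
```

The median per-voxel |ΔFA| caused by removing the 5 corrupted volumes is
≈ 0.005 — the per-subject QC effect is small (well under 0.1) even though
every corrupted volume is caught.

The same pipeline is available from the shell via the bundled wrapper
(`simulate`, `qc`, `fa`, `compare-fa`, `evaluate` subcommands):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "dwiqc.R", package = "dwiqc"))')" \
    simulate --shape 32x32x40 --snr 20 --seed 42 --artifact 7:10-12:0.6 --out phantom
```

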