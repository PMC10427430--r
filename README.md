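# endopol

Simulation, reconstruction and analysis for tissue polarimetric imaging:
the snapshot polarimetric-endoscopy pipeline (division-of-focal-plane
micro-polarizer camera) and benchtop Mueller polarimetry with the
Lu–Chipman polar decomposition.

## Why

Collagen in the lamina propria of healthy mucosa is birefringent, and bulk
scattering depolarizes light; cancer disrupts both. Two scalar maps carry
that contrast:

- **Retardance magnitude** — under circular illumination, the degree of
  linear polarization of the backscattered light:
  `A_δ = |sin δ_L| = sqrt(S1² + S2²) / S0`
- **Circular depolarization** — the complement of the circular
  polarization degree: `A_dep = 1 − |S3 / S0|`

The snapshot endoscope measures these with a DoFP camera (2×2 super-pixels
of 90°/45°/135°/0° micro-polarizers) and a removable quarter waveplate; the
benchtop Mueller polarimeter measures the full 4×4 Mueller matrix `M` from
4 generator × 6 analyser states and factors it as `M = M_Δ · M_R · M_D`,
with `T_dep = 1 − (tr M_Δ − 1)/3`, `A_dep = 1 − |M_Δ(4,4)|`,
`R = cos⁻¹(tr M_R / 2 − 1)`, `A_δ = sin R`.

The package is aimed at researchers prototyping polarimetric imaging
pipelines: every stage — sensor forward model with fixed-pattern gain and
shot/read noise, flat-field calibration, bilinear demosaicing,
partial-Stokes reconstruction, exposure masking, Mueller estimation,
decomposition, RMS contrast, grid-unit statistics, linear-SVM
classification with ROC/AUC — is exercised against a built-in ground-truth
scene simulator, so no restricted patient data is needed to validate any
of it.

## Worked example

An M-shaped uniform retarder (60° phase) over a depolarizing background,
brightness-matched so it is invisible in intensity and colour:

```r
library(endopol)

phantom <- make_m_phantom(c(256, 256), delta_target = pi / 3, seed = 42)
scene   <- scene_to_stokes(phantom$truth)
raw     <- simulate_dofp_mosaic(scene, exposure_scale = 255,
                                noise = list(shot = TRUE, read_sd = 1),
                                seed = 42)
ps   <- partial_stokes_linear(demosaic_bilinear(raw))
amap <- retardance_map(ps, exposure_mask(ps$S0, 8L))
amap
#> <parameter_map A_delta> 256x256, 100.0% valid, range [0.000, 1.000]

target <- phantom$truth$labels == 2
median(amap$values[target])    # 0.862 — the film's sin(60°) = 0.866
median(amap$values[!target])   # 0.067 — shot-noise floor of a non-retarder

# colour carries ~100x less contrast than retardance for this target
hs <- hue_saturation_from_rgb(scene_to_rgb(phantom))
rms_contrast_medians(median(amap$values[target]), median(amap$values[!target]))
#> 0.562
rms_contrast_medians(median(hs$hue[target]), median(hs$hue[!target]))
#> 0.0055
```

The map medians say the glyph reconstructs at the film's true retardance
while the background stays at the noise floor, and the median-contrast
ratio (~100×) quantifies why the target is visible polarimetrically but
not chromatically.

The classifier path, on a synthetic larynx strip scene (3 strips × 22
units of 30×30 px = 66 samples, labelled by ground truth):

```r
fs <- larynx_feature_study(seed = 7)
svm_classify(fs$table, "ret+dep", seed = 7)
#> <classification_report ret+dep> AUC=1.000 sens=1.000 spec=0.952 (n_test=26)
```

A command-line front end wrapping these functions is in
`inst/cli/spe.R` (subcommands `simulate`, `reconstruct`, `mueller`,
`analyze`, `retindex`).

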