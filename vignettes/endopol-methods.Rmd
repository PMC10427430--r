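---
title: "Polarimetric endoscopy with endopol: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polarimetric endoscopy with endopol: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endopol)
```

## The imaging problem

Normal mucosa owes much of its mechanical structure to the collagen fibrils
of the lamina propria. Collagen is birefringent: it introduces a phase delay
(linear retardance, $\delta_L$) between orthogonal polarization components
of light traversing it. Bulk scattering in tissue, in turn, randomizes
polarization (depolarization). Cancerous growth disrupts the collagen
network and the scattering architecture, so maps of retardance and
depolarization carry diagnostic contrast that ordinary colour imaging does
not.

`endopol` implements the full computational chain of two complementary
instruments:

* a **snapshot polarimetric endoscope**: circularly polarized illumination,
  a division-of-focal-plane (DoFP) camera whose pixels sit behind micro
  linear polarizers at 90/45/135/0 degrees, and a removable quarter
  waveplate selecting one of two imaging modes;
* a **benchtop Mueller polarimeter**: four generator states times six
  analyser states, per-pixel least-squares Mueller-matrix estimation, and
  the Lu--Chipman polar decomposition.

No patient data is involved anywhere: a scene simulator provides ground
truth against which every stage is validated.

## Conventions

All angles are radians internally (degrees only at the command-line
boundary). Stokes vectors are $(S_0, S_1, S_2, S_3)$ with $S_3 > 0$ for
right-circular light. The linear retarder with fast axis $\theta$ and phase
$\delta$ uses the rotation convention spelled out in
`?mueller_linear_retarder`; the corresponding handedness choice routes the
polarization-maintaining circular component to the 0-degree analyzer when
the depolarization-mode waveplate is in place. Hardware conventions of real
instruments are rarely published; every quantity the package reports
downstream ($A_\delta$, $A_{dep}$, $T_{dep}$, $D$) is a magnitude and is
therefore convention-free, while signed intermediates ($S_3$, fast-axis
angles) are internal to the convention. Coordinates are 0-based concepts
realized as 1-based R indices, row-major, top-left origin; the super-pixel
phase is defined relative to the top-left pixel.

Physicality of a Stokes vector means
$\sqrt{S_1^2+S_2^2+S_3^2} \le S_0(1+\varepsilon)$ with
$\varepsilon = 10^{-9}$ for noise-free algebra; the tolerance is an
argument of `is_physical_stokes()` because measured states need a looser
one.

## Snapshot reconstruction

The sensor model is Malus projection: a pixel behind a micro-polarizer at
angle $\alpha$ expects
$g \cdot E \cdot \tfrac12 (S_0 + S_1\cos 2\alpha + S_2 \sin 2\alpha) + o$
counts, with per-pixel gain $g$ (the fixed-pattern signature of variable
micro-polarizer diattenuation), exposure scale $E$ and offset $o$. Shot
noise is Poisson on the photo-signal, read noise Gaussian, and quantization
clips then rounds half-up to the bit depth (default 8).

Reconstruction proceeds in five steps:

1. **Fixed-pattern correction** `(raw - offset)/gain`, floored at zero.
   The calibration is estimated from flat-field frames of uniform
   unpolarized illumination (`estimate_calibration()`): each pixel's gain is
   its value over the mean of all pixels sharing its orientation. This
   identifies the gain up to one scale per orientation, which is exactly
   the freedom that leaves the ratio maps below unchanged.
2. **Bilinear demosaicing** of the four orientation sub-lattices to full
   resolution. The interpolation operator reproduces native sites exactly
   and affine intensity fields exactly in the interior; outside the
   outermost native sites values are edge-replicated, so quantitative
   round-trip contracts exclude a 2-pixel border.
3. **Partial Stokes.** Retardance mode (no waveplate):
   $S_0 = (I_0+I_{45}+I_{90}+I_{135})/2$, $S_1 = I_0 - I_{90}$,
   $S_2 = I_{45}-I_{135}$. Depolarization mode (quarter waveplate at 45
   degrees to the super-pixel axes): $S_0 = I_0 + I_{90}$,
   $S_3 = I_0 - I_{90}$.
4. **Maps.** $A_\delta = \sqrt{S_1^2+S_2^2}/S_0$, the degree of linear
   polarization of the emergent light, equals $|\sin\delta_L|$ for a pure
   retarder under circular illumination. $A_{dep} = 1 - |S_3/S_0|$, the
   complement of the circular polarization degree. Both are clipped to
   $[0,1]$; pixels with $S_0 \le 0$ are masked invalid rather than given
   sentinel values.
5. **Exposure masking and display.** Before any gamma correction, a pixel
   is overexposed when $S_0/2 > 0.95\,(2^{bit}-1)$ and underexposed when
   $S_0/2 < 0.03\,(2^{bit}-1)$; such pixels are excluded from every
   statistic and rendered pure green so they cannot be mistaken for
   measurements. The optional intensity-reference gamma is $1/2$ by
   default; unsharp masking (sigma 2 px, amount 0.8 --- deliberately mild)
   is cosmetic, off in all quantitative paths.

A known, documented bias: the depolarization mode cannot distinguish
depolarization from circular-to-linear conversion by retardance, so a pure
retarder of phase $\delta$ reads $A_{dep} = 1-|\cos\delta|$ even though it
depolarizes nothing. The test suite pins this curve analytically.

## Mueller polarimetry and the decomposition

The generator is a 0-degree polarizer plus quarter waveplate at
$\{-45, 0, 30, 60\}$ degrees, giving states
$(1, \cos^2 2t, \cos 2t \sin 2t, \sin 2t)$; the analyser bank is four
linear polarizers ($-45, 0, 45, 90$ degrees) and both circular polarizers.
The 24 measurements relate linearly to the 16 Mueller elements through the
operator $B$ with rows $w_k^\top \otimes a_j^\top$; its condition number
(about 6.3 for the default geometry) is computed at construction and a
rank-deficient geometry is rejected before any pixel work. Estimation is
least squares over all 24 equations --- the natural choice for an
overdetermined system; nothing in the contract depends on the estimator
beyond exact recovery in the noise-free case, which the property suite
verifies to $10^{-8}$ over 1000 random depolarizer-retarder-diattenuator
compositions. Per-pixel solves are batched into one QR solve over the whole
image; the result is bit-identical to a per-pixel loop.

`lu_chipman()` factors $M = M_\Delta M_R M_D$ after normalizing by
$m_{00}$. The diattenuation vector is the first row; the depolarizer block
is the symmetric square root of $m'm'^\top$ assembled from its eigenvalues
with the sign of $\det m'$; the retarder block is the remainder. When the
smallest eigenvalue falls below $10^{-12}$ (relative), the closed form is
numerically meaningless and an SVD branch supplies the orthogonal retarder
factor, flagged `degenerate`; the scalar summaries remain defined from
$M_\Delta$. Scalars follow the standard definitions: total depolarization
$T_{dep} = 1 - (\mathrm{tr}\,M_\Delta - 1)/3$, circular depolarization
$A_{dep} = 1 - |M_\Delta(4,4)|$, retardance
$R = \cos^{-1}(\mathrm{tr}\,M_R/2 - 1)$ on the principal branch $[0,\pi]$,
and $A_\delta = \sin R$ --- note $A_\delta$ is therefore non-injective
above $R = \pi/2$, a property of the definition, not a defect. The
depolarization *map* uses the circular term $M_\Delta(4,4)$, matching what
the snapshot depolarization mode measures; $T_{dep}$ and $D$ maps are
returned alongside.

## The scene simulator

Scenes are per-pixel ground truth (retardance $\delta$ and fast axis
$\theta$, diagonal depolarizer factors $a, b, c$, brightness, region
labels) from which both imaging paths are derived with one model,
$M = M_\Delta(a,b,c)\, M_R(\delta,\theta)$, applied to the illumination
state. Diattenuation is omitted by default --- tissue diattenuation is
typically very small --- and the component order matches the decomposition
order, making simulation and decomposition mutually consistent. Circular
depolarization is controlled directly by $c$ ($A_{dep} = 1-c$ for pure
depolarizers); the linear factors default to 1, which also makes the
snapshot $A_\delta$ and the decomposition's $\sin R$ agree exactly on
non-diattenuating scenes (the cross-path property test).

Two stock scenes:

* `make_m_phantom()`: an M-shaped, spatially uniform retarder (default
  $\delta = 60°$, fast axis uniform as for a real birefringent film) over a
  purely depolarizing background, brightness-matched so the glyph is nearly
  invisible in intensity and in the synthetic colour photo but at full
  contrast in the retardance map.
* `make_larynx_scene()`: normal mucosa ($\delta \sim U(50°, 80°)$,
  $c \sim U(0.1, 0.4)$ --- strongly retarding, strongly depolarizing)
  with embedded lesions ($\delta \sim U(0°, 15°)$, $c \sim U(0.5, 0.8)$ ---
  collagen disrupted, scattering reduced), plus blood patches dark enough
  to underexpose and specular patches bright enough to saturate. The class
  distributions encode the qualitative finding that cancerous laryngeal
  tissue shows low retardance *and* low depolarization; absolute per-tissue
  values are not published, so analyses on this scene are
  ordering/significance properties, never absolute-value reproductions.

Parameters vary as smooth random fields: coarse uniform draws bilinearly
upsampled with correlation lengths of 16 px for $\delta$ and $c$ and 32 px
for $\theta$. Sixteen pixels correspond to roughly 0.5--0.7 mm at
endoscopic working distance --- the same scale at which the grid-unit
analysis treats tissue as locally homogeneous. Pixel-wise independent
texture would be both unphysical and unresolvable by any mosaic sensor,
whose orientations sample the scene on a 2-pixel pitch. All randomness
flows from one seed through named substreams (`scene`, `gain field`,
per-mode acquisition), so adding a stage never shifts another stage's
draws, and regenerating with the same seed is bit-identical.

What the simulator does **not** model: polarized Monte-Carlo photon
transport, wavelength dependence, surface-geometry effects, and the
two-layer epithelium/lamina-propria radiative structure (its consequences
are emulated phenomenologically through the class distributions). Passing
tests therefore demonstrate the correctness of the reconstruction and
analysis chain under the stated optical model --- not the biological
fidelity of the parameter values.

The default illumination is ideal right-circular $(1,0,0,1)$;
`spe_illumination(ideal = FALSE)` provides a characterized state with
residual linear polarization (degree 0.028) for perturbation studies ---
its effect on $A_\delta$ is bounded by that degree, which the scene tests
check.

## The analysis layer

* RMS contrast of a channel is the sample standard deviation (divisor
  $n-1$) of $[0,1]$-scaled values; the two-category median contrast is
  $\sqrt{(m_1-\bar m)^2 + (m_2-\bar m)^2} = |m_1-m_2|/\sqrt2$.
* Grid-unit means (`grid_unit_means()`): non-overlapping
  $16\times16$-pixel units whose means are treated as independent
  observations. A unit is dropped if it is not fully inside the region
  or contains *any* exposure-invalid pixel --- the conservative reading of
  "excluded areas", configurable via the mask arguments.
* Mann--Whitney comparisons use `stats::wilcox.test`, exact for two
  groups of at most 20 without ties, otherwise the normal approximation
  with continuity correction (the switch is reported in the result).
* Classification (`svm_classify()`): linear-kernel SVM (`e1071`),
  single seeded 0.6/0.4 split (a stratified split and split-averaged ROC
  are possible variations; the single split is the documented default),
  features z-standardized with training-split statistics (standard SVM
  practice), regularization $C = 1$ (AUC is insensitive across
  $C \in \{0.1, 1, 10\}$ in the suite --- a sensitivity check, not a
  contract). ROC/AUC from `pROC` on the test split only, with sensitivity
  and specificity reported at the fitted boundary (decision value 0). A
  split that strands a class on either side is redrawn with the next seed,
  with a warning.
* The retardance index of a polarization-microscopy image gates pixels by
  hue in $[0.05, 0.45]$ (inclusive; golden to dark green, the interference
  colours of birefringent fibres between crossed polarizers) and averages
  the grey level $0.2989r + 0.5870g + 0.1140b$ on the 0--255 scale,
  returning 0 when no pixel qualifies.

## Numerical choices, in one place

* Retarder/polarizer angles wrapped to their periods; no errors for
  out-of-range angles.
* Quantization: clip to $[0, 2^{bit}-1]$, then round half-up.
* Demosaic boundary: edge replication; contracts exclude a 2-px border.
* Lu--Chipman: eigenvalue threshold $10^{-12}$ (relative) for the
  degenerate branch; `acos` argument clamped to $[-1, 1]$;
  near-unity diattenuation ($|D| \to 1$) switches the inverse of $M_D$ to a
  pseudo-inverse.
* Map values clipped to $[0,1]$; validity carried as masks, never
  sentinels; green is applied at render time only.
* Float TIFF pages are stored affinely rescaled to $[0,1]$ (TIFF float
  semantics are only defined there) with the range in the JSON sidecar.

## Problem sizes in the shipped tests

The suite exercises $256\times256$ scenes for the grid-unit statistics, a
$128\times672$ strip scene for the 66-unit classification table, 1000
random Mueller compositions for the decomposition property, and Monte-Carlo
checks at 8 seeded replicates --- sizes chosen so the whole suite stays
interactive on a laptop while keeping every statistical check comfortably
powered.

## Known limitations

* The snapshot depolarization mode over-estimates depolarization for
  strongly retarding media (the $1-|\cos\delta|$ bias above); only Mueller
  polarimetry separates the two effects.
* $A_\delta = \sin R$ folds retardance above $\pi/2$.
* The flat-field calibration estimator assumes the flats are unpolarized
  and uniform; it does not reproduce any camera vendor's proprietary
  calibration.
* Scene realism is phenomenological; see the simulator section for the
  explicit list of unmodelled physics.
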