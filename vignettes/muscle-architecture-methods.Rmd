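---
title: "Measuring 3D muscle architecture from diffusion-tensor tractography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring 3D muscle architecture from diffusion-tensor tractography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myotract)
```

## The problem and the model

Skeletal-muscle force capacity and excursion are governed by muscle
architecture: how long the fascicles are, at what angle they insert on
the tendinous sheets (pennation), how curved they run, and how much
muscle volume feeds each unit of fascicle length (the physiological
cross-sectional area, PCSA = volume / fascicle length). In complex,
compartmentalised muscles such as the human soleus — four compartments,
medial/lateral x anterior/posterior, each with its own fibre
orientation — two-dimensional ultrasound cannot capture this
three-dimensional organisation.

Diffusion-tensor imaging (DTI) can. Water diffuses more freely along a
muscle fibre than across it, so the per-voxel diffusion tensor $D$ has
its principal eigenvector $e_1$ aligned with the local fibre direction.
`myotract` implements the full chain from diffusion-weighted volumes to
compartment-level architecture statistics:

1. **Tensor fit** (`fit_tensor`): per voxel, log-linear least squares on
   $\log(S_k/S_0) = -b\, g_k^T D\, g_k$.
2. **Eigen maps** (`eigen_maps`): sorted eigenvalues
   $\lambda_1 \ge \lambda_2 \ge \lambda_3$, eigenvectors, fractional
   anisotropy
   $\mathrm{FA} = \sqrt{\tfrac12 \sum_{i<j} (\lambda_i-\lambda_j)^2 / \sum_i \lambda_i^2}$
   and mean diffusivity $\mathrm{MD} = \bar\lambda$.
3. **Geometry** (`build_surface`, `make_seed_and_boundary_masks`):
   closed triangulated surface models per compartment, divergence-theorem
   volumes, the muscle long axis, and seed/boundary masks on the DTI
   grid (seeds at least two voxels from the surface; tracking terminates
   in the two-voxel boundary layer, where partial-volume voxels corrupt
   $e_1$).
4. **Tractography** (`track_compartment`): deterministic bidirectional
   streamlines through the $e_1$ field with the field's standard muscle
   windows: $0.1 \le \mathrm{FA} \le 0.5$,
   $1\cdot10^{-3} \le \mathrm{MD} \le 2\cdot10^{-3}\ \mathrm{mm^2/s}$,
   per-step angle $\le 10^\circ$, 1 mm steps, accepted length
   15–200 mm, seeding until 1000 accepted tracts per compartment.
5. **Fascicle reconstruction** (`fit_polynomial`,
   `extrapolate_to_surface`, `accept_fascicle`): a cubic polynomial per
   coordinate over the normalised cumulative-chord parameter, linear
   extension of both endpoint tangents to the compartment surface, and a
   plausibility filter (total extension < 20 mm and < 50% of the
   fascicle length).
6. **Metrics and statistics** (`pennation_angle`, `mean_curvature`,
   `pcsa`, `compartment_table`, `lmm_compartment`, `lmm_lengthening`):
   per-fascicle length, 3D pennation (angle between the
   origin–insertion chord and the long axis), mean Frenet–Serret
   curvature $\kappa = |r' \times r''| / |r'|^3$ at 100 points
   equidistant in arc length along the fitted polynomial, and
   random-intercept mixed models across subjects.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| FA window | [0.1, 0.5] | – | muscle tissue; excludes fat/fluid and crossing artefacts |
| MD window | [1e-3, 2e-3] | mm²/s | muscle water diffusivity at body temperature |
| max angle | 10 | deg/step | fascicles curve gently; sharper turns are tracking errors |
| step | 1 | mm | half the in-plane voxel scale |
| length window | [15, 200] | mm | below 15 mm tracts are fragments; above 200 mm non-anatomical |
| extension filter | < 20 mm and < 50% | mm, fraction | an attachment reconstructed mostly by extrapolation is unreliable |
| boundary layer | 2 | voxels (Chebyshev) | partial-volume voxels at muscle borders corrupt e1 |
| n_target | 1000 | tracts | compartment means stabilise well below this |

"Two voxels" is interpreted in DTI voxel units with Chebyshev distance
despite the anisotropic voxels (1.875 × 1.875 × 5 mm), because the rule
is stated in voxels, not millimetres.

## The phantom: what it emulates and what it does not

No raw scans are redistributable, so validation uses a synthetic
pennate-muscle phantom with analytically known architecture
(`phantom_four_slab`, `generate_phantom`, `synthesize_dwi`).

* **Geometry.** Compartments are idealised slabs between two parallel
  aponeurosis planes. Straight-fascicle slabs satisfy
  length = thickness / sin(pennation) exactly. The slab end-caps are cut
  *parallel to the fascicle direction*, so every extrapolation ray
  attaches to an aponeurosis face and tracts truncated near the caps are
  restored by extrapolation — the same mechanism the method relies on in
  real muscles. Curved-fascicle compartments are annular sectors of
  concentric arcs with radii $\rho \in [R - t/2,\, R + t/2]$; over the
  area-uniform sector $E[1/\rho] = 1/R$ exactly, so the ground-truth
  mean curvature is $1000/R$ per metre.
* **Signal.** Every in-compartment voxel carries a tensor with
  eigenvalues (1.7, 1.3, 1.1)·10⁻³ mm²/s (FA 0.22, MD 1.37·10⁻³ —
  typical muscle values, inside the tracking windows) and $e_1$ equal to
  the prescribed fascicle tangent at the voxel centre. DWI synthesis
  uses $S = S_0 e^{-b\,g^T D g}$ at b = 500 s/mm² on a frozen
  16-direction electrostatic hemisphere scheme, with optional Rician
  noise (magnitude of a complex Gaussian perturbation, independent per
  measurement).
* **Preset.** The four-slab preset uses pennations 28/30/38/35° and
  thickness 24.375 mm (13 in-plane voxels, so slab faces fall exactly on
  voxel boundaries and the truth is exact). The anterior compartments'
  published pennations (22–27°) are *not* copied verbatim: with 1.875 mm
  voxels and the 2-voxel boundary layer, tract endpoints sit
  ~4 mm from the aponeurosis, so per-end extrapolation is
  ~4/sin(θ) mm and the 20-mm filter provably rejects *every* fascicle
  below θ ≈ 25°. The preset therefore uses distinct pennations within
  the physiological 22–38° range that the filter tolerates.
* **What a green test does not establish.** The phantom has no
  curved aponeuroses, no fibre-orientation dispersion, no T2/EPI
  artefacts, no eddy-current residuals and no inter-muscle
  partial-volume mixing; its compartments are convex and its noise (if
  enabled) is stationary. Recovery on the phantom validates the
  numerics, not in vivo accuracy.

## Numerical choices

* **Tensor fit**: unweighted log-linear least squares (deterministic and
  adequate at phantom SNR); weighted or nonlinear estimators are an
  extension point. Voxels with non-positive signal are excluded;
  negative eigenvalues under noise are clamped to zero for FA only and
  flagged.
* **Interpolation**: trilinear for $e_1$ (with per-corner sign alignment
  to the previous step direction — eigenvectors have no global sign),
  FA and MD; nearest-neighbour optional. Termination is evaluated at
  the candidate point *before* stepping, so no partial steps exist.
  Ties at exactly 10° are accepted (the rule is a maximum).
* **Voxelisation**: a voxel belongs to the compartment with the majority
  of 8 sub-points; an exact compartment/background tie is resolved by
  the voxel centre (a background-default tie rule would erode every
  grid-misaligned face by a quarter voxel, a systematic −2 to −3% volume
  bias). On the anisotropic grid, slab end-caps tilted relative to the
  5-mm slices can still beat against the slice grid (a moiré of order
  1–3% in volume); this is a property of the stated voxel grid, not of
  the surface extraction, which reproduces the voxel-count volume
  exactly.
* **Surfaces**: the boundary-face mesh of the voxel mask (exactly
  closed, outward-oriented, volume equal to the voxel-count volume).
  No smoothing is applied; meshes can be watertight yet non-manifold
  where voxels touch diagonally, so "closed" is checked as directed-edge
  balance rather than the manifold two-faces-per-edge rule.
* **Curvature**: evaluated on the fitted polynomial only (the extensions
  are straight; including them — config-switchable — dilutes the mean).
  The 100 evaluation points are equidistant in arc length, found by
  inverting a dense cumulative-length table.
* **Filter semantics**: "total length" is fit + both extensions;
  "extended by" is the sum of both ends' extensions; both bounds are
  strict (<). This interpretation is recorded in the run manifest.
* **Mixed models**: REML random-intercept fits via `lme4` with
  cell-means coding; Wald contrasts, unadjusted, plus a clearly labelled
  Holm-adjusted column. Simulation-recovery checks use t-based 95%
  intervals with subject-level degrees of freedom (n − 1), the standard
  small-sample choice. A zero-variance fit is retained and flagged
  singular, and equals OLS.
* **Long axis**: supplied as two world points, or automated as the first
  principal component of the pooled surface vertices; phantom runs use
  the prescribed axis (the analogue of the manually picked
  anterior-surface points).

## Known limitations

* The published whole-muscle table cannot be reproduced to the last
  printed digit from the printed compartment cells alone: the published
  aggregation averaged unrounded per-subject values, so four cells
  (PCSA at the long length and its change, pennation and curvature at
  the long length) differ by exactly one printed ulp (0.1). The
  acceptance test asserts printed precision and is deliberately left
  red for those cells.
* The published per-centimetre changes (e.g. fascicle length
  +3.7 ± 0.8 mm per cm of muscle–tendon lengthening) require per-subject
  muscle–tendon length changes that are inputs here; they are covered by
  simulation recovery, not by re-derivation.
* Bipennate (mirrored-slab) compartments are generated and tracked, but
  the recovery guarantees apply to unipennate slabs: at the central
  aponeurosis the direction field flips, tracking terminates on the
  angle rule, and extrapolation crosses into the mirrored half, so most
  such fascicles are (correctly) rejected by the extension filter.
* Streamline CSV/VTK and ASCII STL/PLY writers favour verifiable text
  formats over binary variants.
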