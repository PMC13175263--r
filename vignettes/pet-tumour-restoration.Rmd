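---
title: "Restoring ground-truth activity in simulated PET lung tumours"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restoring ground-truth activity in simulated PET lung tumours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Quantification of radiotracer uptake in lung tumours on PET images — usually
through standardised uptake values, SUV = concentration / (injected dose /
body weight) — is degraded by two coupled effects. The partial volume effect
(the scanner's ~4–6 mm resolution smears activity out of structures of
comparable size) biases uptake estimates in small tumours, and Poisson
counting noise makes single-voxel statistics such as SUV~max~ unstable.
Resolution modelling inside the reconstruction sharpens small lesions but
introduces Gibbs-like edge overshoot that *inflates* SUV~max~ near sharp
boundaries.

`petrestore` implements a supervised restoration approach to this problem:
simulate tumours whose true activity is known exactly, reconstruct realistic
PET images from simulated raw data, and train a 3D convolutional network to
map reconstructed image patches back to their ground truth. Because the truth
is synthetic, recovery can be measured exactly — something impossible with
patient data, where the true radionuclide distribution is never known.

## Pipeline

1. **Phantom** (`make_torso_phantom`, `make_tumour`,
   `assemble_ground_truth`). A procedural torso (elliptical soft-tissue body,
   two lung ellipsoids, heart, spine and rib bands) provides a realistic
   background of activity and 511 keV attenuation. Tumours with volumes
   configurable over 0.01–200 ml carry one of three uptake patterns:
   uniform; split halves with two different activities; or hollow, where a
   shell of thickness half the equivalent-sphere radius surrounds a core at
   background activity (a necrotic-core surrogate). Tumour activities are
   drawn from 6–35 kBq/ml and the whole background is scaled so the
   tumour-to-background ratio is exactly 10. Placement is uniform over
   positions fully inside the left lung.
2. **Analytic raw-data simulation** (`forward_project`,
   `scale_and_contaminate`, `poisson_sample`). Slice-wise 2D parallel-beam
   line integrals with per-line attenuation factors, an anisotropic Gaussian
   point-spread function applied in image space (default FWHM 4.5 mm
   transaxial, 4.0 mm axial = 4.5/1.125), scaling to a target prompt count
   with a uniform scatter+randoms background, and independent Poisson draws
   per bin. With the default trues fraction of 0.352, 100 M prompts
   correspond to 12.4 M noise-equivalent counts under NEC = T²/P.
3. **Reconstruction** (`osem_reconstruct`). Ordinary-Poisson OSEM, 6
   iterations × 21 interleaved subsets, image-based PSF modelling (the same
   Gaussian blur inside the forward and backward model), no post-filter.
   With one subset the update is exactly MLEM; the test suite verifies this
   update-by-update, checks the noiseless fixed point, and confirms the
   characteristic RC~max~ > 1 edge overshoot on a ≥5 ml uniform sphere.
4. **Restoration** (`build_model`, `train_cnn`, `restore_crop`). A 7-layer
   3D CNN (32 filters of 3×3×3 per hidden layer, ReLU, batch normalisation
   after every convolution except the final one, dropout 0.3 after the first
   two batch norms, linear single-channel output) trained with Adam at
   learning rate 0.001 on the mean squared error between min-max-normalised
   reconstructed crops and ground-truth crops.
5. **Quantification** (`rc_metrics`, `mssim`, `sphericity`,
   `binned_rc_summary`, ...). Recovery coefficients for the maximum, median
   and peak (1 cm³ spherical VOI) activity inside the ground-truth mask;
   mean structural similarity over 7×7×7 windows; mesh-free sphericity;
   half-ratio analysis; volume-binned cohort tables.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| voxel size | [2.09, 2.09, 2.03] mm | grid pitch of phantom and reconstruction |
| PSF FWHM | 4.5 mm transaxial, /1.125 axial | scanner resolution model |
| prompts | 10⁸ (paper preset) / 3·10⁶ (desk) | total expected coincidences |
| trues fraction | 0.352 | sets NEC = T²/P; remainder is uniform background |
| OSEM | 6 iterations × 21 subsets | no post-filter |
| tumour activities | U(6, 35) kBq/ml | primary (and secondary via ratio U(1.2, 3)) |
| TBR | 10 | background = max tumour activity / 10 |
| crop | 50³ (paper) / 18³ (desk) | patch fed to the network |
| training | Adam 0.001, MSE; 500 epochs × batch 50 (paper), 16 × batch 5 (desk) | |

## Design choices

* **Tumour shape model.** An ellipsoid with a seeded random orientation and
  an elongation parameter (axis ratio (1+e)^{3/2}), modulated by a smoothed
  Gaussian random radial field; a binary search on the implicit-surface
  scale matches the voxelised volume to the target. This gives continuous
  volume control, a single 26-connected component, and sphericity that
  decreases monotonically with elongation.
* **Hollow-core rule.** The core is the set of voxels whose Euclidean
  distance (exact anisotropic distance transform) to the outside exceeds
  half the equivalent-sphere radius — for spheres this reduces to a shell of
  thickness r/2.
* **Halves split.** A plane through the mask centroid with orientation drawn
  uniformly on the sphere; the activity ratio between halves is uniform in
  [1.2, 3].
* **Projector geometry.** The simulator and reconstruction share a
  slice-wise 2D parallel-beam geometry (168 angles, radial bins at the voxel
  pitch spanning the grid diagonal) with the axial PSF handled in image
  space. A full 3D cylindrical scanner geometry with detector normalisation
  is deliberately out of scope: the phenomenology that drives the method —
  resolution loss, Gibbs overshoot, Poisson noise, attenuation — is
  preserved, while keeping single-CPU runtimes. Consequently absolute count
  levels are calibrated per simulation (`trues_scale`), and reconstructed
  images are returned in kBq/ml by dividing by that known factor.
* **Scatter/randoms.** Modelled as a spatially uniform expected background
  added inside the forward model (ordinary-Poisson OSEM) rather than
  pre-subtracted, keeping the Poisson likelihood exact. The paper-style
  noise level fixes only their total, not their spatial law.
* **Network ordering.** Convolution → ReLU → batch norm (→ dropout for the
  first two hidden layers). Batch-norm momentum is 0.9 so the running
  statistics converge within desk-scale step counts; its epsilon is 10⁻³.
  The final convolution has a single filter: the output must be a
  single-channel image.
* **Normalisation scope.** Min-max scaling is fitted per case on the
  reconstructed crop; the ground-truth target is scaled with the *same*
  record, and the stored record is inverted on the network output before
  any quantitative analysis. This keeps the input in [0, 1] while letting
  the target exceed 1 where reconstruction undershoots the truth.
* **SSIM constants.** The standard C1 = (0.01 L)², C2 = (0.03 L)²,
  C3 = C2/2 with L the data range of the reference (ground-truth) image;
  exponents are all 1; windows are fully interior with stride 1 (a 50³ crop
  has 44³ windows).
* **Surface area for sphericity.** Exposed voxel faces are counted with
  each face weighted by the matching component of the local surface normal
  (estimated from a Gaussian-smoothed copy of the mask, σ = 1.5 voxels).
  The weighting is exact for planar interfaces of any orientation, so both
  the sphere (→ 1) and the cube (→ (36π)^{1/3}/6 ≈ 0.806) converge with
  resolution; a marching-tetrahedra mesh of the smoothed mask is available
  as `method = "mesh"` but carries a larger orientation bias on binary
  masks. Volumes always come from the voxel count.
* **Peak VOI.** Sphere of exactly 1 ml (radius ≈ 6.20 mm) in voxelised
  form; candidate centres are mask voxels whose full VOI lies inside the
  image, and the reported peak is the maximal VOI mean.
* **Numerical floors.** Forward-model denominators carry ε = 10⁻¹²; voxels
  whose subset sensitivity falls below 10⁻⁸ of its maximum are frozen at
  zero; FWHM = 0 is an explicit identity flag for the blur.

## Scale presets

The `"paper"` preset reproduces the full protocol (344×344×127 grid, 2110
cases — 800 uniform / 721 halves / 589 hollow, 100 M prompts, 50³ crops,
500 epochs with batch 50, augmentation of larger tumours by factors
0.5–0.8). Those settings assume GPU/cluster hardware.

The `"desk"` preset — used by the test suite — keeps every pipeline stage
identical but shrinks the problem so one experiment runs in minutes on one
CPU: 64×64×32 grid at the same voxel size, 120 cases (40 per pattern),
3·10⁶ prompts, 84 projection angles (4 per subset; at this grid width the
reconstruction is indistinguishable from the 168-angle geometry), 18³
crops, 16 epochs with batch 5, and 12 augmented cases. Tumour volumes are
drawn half from U(5, 8) ml and half log-uniformly from [0.5, 5] ml so the
≥5 ml evaluation stratum is populated, and the elongation range is capped
at 0.35 because the miniature desk lung (shortest semi-axis ≈ 21 mm)
cannot contain longer shapes; the paper preset keeps the full ranges. The
generalisation runs reuse the experiment-1 model on 12 cases with PSFs
drawn from N(4.5, 0.2²) mm and on 8 hollow >5 ml tumours at half and
double the prompt count.

## What the synthetic data do and do not show

The generator reproduces the features the restoration method depends on:
activity patterns with sharp boundaries, a fixed tumour-to-background ratio,
attenuation heterogeneity, resolution blur matched between simulation and
reconstruction, and count-limited Poisson noise. It does **not** model
intra-tumour texture heterogeneity beyond the three patterns, respiratory or
cardiac motion, tracer kinetics, spatially variant or mismatched PSFs,
realistic scatter spatial distributions, or detector effects (dead time,
normalisation, time-of-flight). Passing tests therefore demonstrate that the
network can invert the simulated degradation — the mechanism the approach
relies on — not that a clinically deployable SUV correction has been
achieved.

## Known limitations

* The 2D slice-wise projector ignores oblique lines of response; axial
  resolution enters only through the image-space PSF.
* At desk scale the network is trained for a few dozen Adam steps; it
  reliably improves RC~max~ and MSSIM over the reconstruction, but its
  absolute metric values are not comparable to a 500-epoch GPU run.
* Median RCs for small (<1 ml) tumours are dominated by the handful of mask
  voxels and are reported but noisy.
* The halves pattern uses a planar split; real heterogeneous tumours are
  not piecewise-constant.
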