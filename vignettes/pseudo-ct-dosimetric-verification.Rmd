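---
title: "Pseudo-CT synthesis by rigid registration with outer-body correction, and its dosimetric verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-CT synthesis and dosimetric verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rtpseudo)
```

## The problem

MRI is the preferred imaging modality for delineating brain tumours, but
radiotherapy dose calculation needs electron density, which MRI does not
measure. When a patient has a prior diagnostic CT (DCT), a *pseudo-CT* can
be built by rigidly registering that CT into the planning geometry. Rigid
registration cannot absorb anatomical change between the two imaging
sessions; the working assumption — reasonable for adult heads — is that all
inter-scan differences are confined to the outer scalp surface, while the
skull and everything inside it are unchanged. The residual outer-body
mismatch is then removed by an explicit HU correction:

* **tissue excess** — voxels inside the diagnostic-scan body contour but
  outside the reference body contour — is set to air, **-1000 HU**;
* **tissue deficiency** — voxels inside the reference body but outside the
  diagnostic body — is set to soft tissue, **0 HU**;
* **unscanned anatomy** — voxels the diagnostic scan never covered (its
  inferior extent is usually limited) — is likewise set to **0 HU**.

After correction the pseudo-CT has the reference scan's outer body shape
exactly, and scanned voxels inside both bodies carry their original
diagnostic HU untouched. `rtpseudo` implements this workflow end-to-end
and, because no patient data ships with it, verifies it on digital head
phantoms that emulate the acquisition differences the method must survive.

## Pipeline

`generate_pseudo_ct()` runs the five steps: (1) rigid fusion of the
planning MR (PMR) to the planning CT (PCT) by mutual information — skipped
in MRI-only mode, where the PMR grid itself is the reference; (2) rigid
registration of the DCT, by default against the PCT with a bone-masked
mean-squared-difference metric (the skulls are what must match); (3)
interpolation onto the PMR-sized reference grid, with voxels outside the
DCT's extent marked by a non-finite out-of-scan sentinel rather than any
fake HU; (4) density-threshold body contouring of both scans
(largest connected component above -400 HU, holes filled slice-wise and in
3D so sinuses stay inside the body); (5) the outer-body correction above,
with a fixed precedence: unscanned-inside-reference first, then
deficiency, then excess; sentinel voxels outside both bodies become air so
the result is dose-calculable everywhere.

Registration is 3-level multi-resolution Nelder-Mead over 6 pose
parameters (degrees and millimetres, rotation about the moving body
centroid), initialized by body-centroid alignment plus a deterministic
coarse rotation lattice, with one fresh-simplex restart per level to break
premature simplex collapse. There is no stochastic sampling anywhere, so
a registration is bit-reproducible; when moving and fixed images are
identical it returns the exact identity, which in turn makes the
zero-perturbation experiment reproduce itself with strictly zero metric
differences.

## Dose engine

Clinical implementations of this workflow compute dose with commercial
treatment-planning systems. Here dose is computed by a deliberately simple
primary-photon model, which is what the package needs: a deterministic
engine *sensitive to electron-density errors*, not a clinical dose
algorithm. For each beam,

$$ D(p) = w\, e^{-\mu\, d_\mathrm{eff}(p)}\,
   \left(\frac{\mathrm{SAD}}{r(p)}\right)^2 f_\mathrm{lat}(p), $$

where $d_\mathrm{eff}$ is the water-equivalent depth obtained by an exact
Siddon line integral of relative electron density from the source to the
voxel, $r$ the source distance, and $f_\mathrm{lat}$ a Gaussian-smoothed
square aperture projected to the isocenter plane. HU convert to relative
electron density through a piecewise-linear calibration with anchors
$(-1000, 0.0)$, $(0, 1.0)$, $(1500, 1.85)$, clamped outside. Defaults:
$\mu = 0.05\,\mathrm{cm}^{-1}$ (a 6 MV-like primary magnitude),
SAD $= 1000$ mm, penumbra $\sigma = 3$ mm. Scatter, electron transport and
MLC shaping are out of scope; the skull-shadow effect the verification has
to expose (a few percent behind bone) is carried entirely by
$e^{-\mu d_\mathrm{eff}}$ and is demonstrated by a dedicated test
(water-override changes the dose behind the skull by more than 1% at 2 cm
depth).

Plans hold five beams — four coplanar plus one tipped toward the vertex —
with the isocenter at the PTV centroid and a square field covering the PTV
with a 3 mm margin. Any beam whose entry ray crosses the unscanned region
is rotated in 5-degree steps to the nearest admissible gantry angle,
because HU in that region are assigned, not measured. Beam weights are
adjusted by a bounded multiplicative loop (at most 50 iterations) pushing
the maximum PTV dose under 110%, and the final global normalization sets
D95(PTV) $= 100\%$ exactly, so the 100% isodose covers exactly 95% of the
PTV up to voxel granularity. With an unmodulated engine the conformity
index settles around 1.3–1.4 — above the 1.2 planning goal that fluence
modulation achieves clinically; this is a known limitation of the
simplified engine, not of the correction scheme under test, and none of
the verification comparisons depend on it.

The verification arm recomputes the *frozen* plan — same beams, same
weights, same normalization factor — on the reference CT
(`recompute_plan_dose()`); every reported difference is therefore
attributable to the CT volumes alone.

## Evaluation

`plan_metrics()` reports Min/Mean/Max PTV dose, V95%, V100% and the
conformity index, defined as the volume receiving at least the
prescription dose divided by the PTV volume (ideal 1.0; values below 1
would mean under-coverage, and the definition is oriented so that reported
values are $\ge 1$ for covering plans). `dose_difference()` and
`gamma_index()` compare dose planes pixel by pixel on an axis-aligned
10 × 10 cm plane through the isocenter (coronal by default), in percent of
prescription with **global** normalization. The gamma search is exhaustive
on a sub-grid of step one tenth of the distance criterion within a radius
of three times the distance criterion, with the evaluated dose interpolated
bilinearly — no pruning, so the discrete minimum is exactly what the
definition states, and a brute-force oracle reproduces the engine to
1e-6. Full-3D gamma is not implemented; the plane ROI is the quantity the
verification protocol reports.

## The phantom: what it emulates and what it does not

`generate_head_phantom()` builds nested ellipsoids — scalp, skull, brain,
a CSF ventricle — with textbook HU (air -1000, scalp 40, skull 700, brain
30, CSF 10), an MR intensity table with the bone/fluid contrast inverted
(ventricle bright, skull dark), and Gaussian scanner noise (8 HU / 15 MR
units). Three spherical PTVs of 13.5 mm radius cover the placements of interest: a deep parasagittal site, one abutting the ventricle (the
lowest-density neighbour), one abutting the inner skull (the highest).
Volumes are in the ~10 cc range, a typical brain-tumour target
scale.

The acquisition model reproduces the features the correction must handle:
the diagnostic CT has 5 mm slices, a gantry tilt drawn uniformly from 0 to
23.3 degrees (a realistic diagnostic-CT tilt range, chosen per-patient to
spare the lenses), a patient set-up mismatch of up to
5 degrees / 8 mm, and an inferior cutoff 25 mm above the lowest anatomy,
leaving genuinely unscanned tissue; the planning CT has 1.25 mm slices and
the planning MR 2.5 mm slices, both untilted. Thick slices are simulated
by box-averaging along the slice normal (a simple finite slice-sensitivity
profile). The inter-scan body change is a uniform scalp
dilation/erosion (default +2 mm) through a Euclidean distance transform
with a half-voxel surface-offset correction, leaving every voxel at or
inside the skull bit-identical — the geometric embodiment of the
outer-skull-only assumption. One scanner-noise field is drawn per
experiment and shared by both CT sessions where labels agree, so session
differences are purely morphological and geometric; with zero perturbation
the two sessions are bit-identical, which is what makes the
zero-perturbation contract (all metric deltas exactly 0) testable at
machine precision.

What the phantom does *not* model: real tissue texture and HU
heterogeneity within organs, MR pulse-sequence physics and geometric
distortion, contrast agents, partial-volume effects beyond linear
averaging, and non-uniform (e.g. posture-dependent) body change. Passing
tests therefore demonstrate the *mechanics* of the method — registration
recovery, the outer-body identity guarantee, frozen-plan dosimetric
agreement — not its clinical accuracy on patients.

## Numerical choices

* Out-of-scan voxels carry `NA`, never a surrogate HU; converting a
  sentinel to density is an error, forcing correction before dosimetry.
* Trilinear sampling snaps indices within 1e-6 of a grid node, so identity
  resampling is exact and grid-coincident samples are bit-stable.
* D95 is the `ceiling(0.95 n)`-th largest PTV dose, making D95
  normalization exact and V100% equal to `100 * ceiling(0.95 n) / n`
  (95.0 up to voxel granularity; about 95.03 for the ~1830-voxel default
  PTV).
* Dose comparisons use a 1e-6 absolute tolerance on threshold tests
  (`>= 95`, `>= 100`, gamma `<= 1`) to keep exact-boundary voxels on the
  intended side after floating-point normalization.
* The body threshold is -400 HU: halfway-ish between air and soft tissue,
  more than 30 noise standard deviations from both.
* The bone threshold for CT-CT registration is 300 HU, separating the
  700 HU skull from 40 HU soft tissue at any plausible noise level.
* Problem sizes: the default phantom uses a 1.25 mm truth grid
  (141 × 169 × 161), a 1.5 × 1.5 × 2.5 mm reference grid (~1M voxels) and
  ~1830-voxel PTVs — small enough that the full study (phantom through
  gamma) runs in about a minute on one core, large enough that V100%
  granularity (0.055 percentage points) resolves the coverage criterion.

## Design choices that were genuinely open

* Commercial registration tools do not expose their metric or optimizer. Both a bone-masked CT–CT route and a
  mutual-information intermodal route are provided; the CT–CT route is the
  default for the DCT because the planning CT and reoriented MR share a
  grid and "bone best matched" is the stated intent.
* Whether gamma used global or local normalization is unstated; global
  matches reporting everything in percent of prescription.
* The conformity index is implemented as irradiated volume over PTV volume
  so that the ideal is 1.0 and covering plans score above 1, so the ideal is approached
  from above by covering plans.
* Precedence when a voxel is unscanned *and* outside the diagnostic body
  but inside the reference body: deficiency rules win (0 HU), consistent
  with assigning unscanned tissue no measured density.
* HU tables are configurable defaults, since the source material never
  tabulates them.

## Limitations

Rigid-only alignment (deformable correction is explicitly out of scope),
a primary-photon dose model without scatter, plane-based (not 3D) gamma,
and phantoms whose anatomy is analytic. The MRI-only mode contours the
reference body on MR intensities, which on real images would need a
carefully chosen threshold or segmentation; here the MR table makes a
simple fraction-of-maximum threshold sufficient.
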