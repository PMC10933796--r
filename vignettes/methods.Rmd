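---
title: "Registering stand-alone histology sections to 3D MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registering stand-alone histology sections to 3D MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A histology section is a 2D image of a thin tissue slice whose position
inside the organ is, in general, unknown: the section is deformed by
mounting and staining, the tissue slab it came from was cut by hand, and
the whole organ deformed between dissection and MRI scanning. Registering
a *single* such section to a whole-organ 3D MRI volume therefore requires
(a) undistorting the section, (b) locating it within the organ without
anatomical labels, and (c) allowing the cutting plane itself to be tilted
and curved in MRI space. `histoslice` implements a four-stage pipeline
that solves these sub-problems using two photographic intermediaries that
are routinely collected at dissection: a photograph of the excised tissue
block, and photographs of the brain slab before and after each block was
cut out.

- **Stage 1** maps histology pixels onto the tissue-block photograph
  (2D -> 2D, deformable).
- **Stage 2** maps the block photograph onto the brain-slab photograph
  (2D -> 2D, with automatic detection of the sampling site).
- **Stage 3** maps the slab photograph onto a curved surface inside the
  MRI volume (2D -> 3D, the algorithmically hardest part).
- **Stage 4** refines the composed mapping directly between histology and
  MRI with deliberately reduced degrees of freedom.

Because each stage produces a *transformation chain*, the stages can be
optimised independently and concatenated afterwards, including with
FLIRT-style inter-modality affines; vector data (e.g. fibre orientations)
are reoriented by the rotational part of the local Jacobian.

## The transformation-chain engine

Images are held in a `tensor_image`: an N-D grid with a mm/pixel
resolution, an optional weight mask, and a *domain* that splits the
grid-to-world mapping into an internal chain (resolution scaling and
padding offsets, managed by the package) and an external chain (the
optimisable transformations). Grid indices are 0-based and pixel-centred;
physical coordinates are in millimetres. Padding an image updates only the
internal chain, so the physical position of every pre-existing pixel is
preserved exactly — a property the test suite asserts to 1e-12 mm.

Supported transformations: 2D/3D rotations (degrees; 3D rotations use
intrinsic x-y-z Euler angles about a stated centre — the reference work
does not state a convention, so this one is fixed and documented),
isotropic scaling, translations, affines, a 2D-to-3D embedding (z = 0), a
dense per-pixel displacement field, and a sparse control-point field
interpolated with Gaussian radial basis functions
`phi(r) = exp(-r^2 / (2 sigma^2))`. The kernel width defaults to the mean
nearest-neighbour spacing of the control points (not stated in the
reference; exposed in the configuration). Dense-field queries outside the
field's grid return the nearest-edge vector, avoiding discontinuities at
image borders. "Spline" interpolation is cubic (Keys kernel, a = -0.5);
the reference states spline without an order.

## MIND similarity

Histology, blockface photographs and MRI have unrelated contrasts, so all
stages compare *modality-independent neighbourhood descriptors* (MIND)
instead of intensities: each pixel is replaced by the 8-vector
`exp(-Dp(x, x + r) / V(x))` over its immediate neighbours `r`, where `Dp`
is the mean squared intensity difference over a 3x3 patch and `V(x)` the
mean of the 8 patch distances, floored at `1e-6 * range^2` so constant
regions are well-defined. Each descriptor is rescaled to maximum 1, making
it exactly invariant to positive affine intensity rescaling (asserted to
1e-6 in the tests). The MIND *cost* is the weighted mean of pixelwise
Euclidean distances between descriptor vectors over the evaluation domain
(the reference says "sum"; the mean is used so values are comparable
across pyramid levels and mask sizes, and the raw sum remains available
via `aggregate = "sum"`). The moving image is resampled onto the
evaluation domain first and descriptors are recomputed on the resampled
image (resample-then-describe); the alternative — warping precomputed
descriptors — was considered and rejected because descriptor channels are
not equivariant under rotation.

## Optimisation

All linear steps use bounded derivative-free minimisation. The contract is
BOBYQA-like: any bounded local optimiser that never returns an infeasible
or worse-than-initial point would satisfy it; the implementation wraps
Powell's BOBYQA from the `minqa` package. Default trust radii are 10% of
the bound width and the stopping tolerance 1e-4 (the reference gives
neither). The non-linear steps of Stages 1-2 estimate a dense displacement
field by Gauss-Newton iterations (at most 20 per pyramid level, as stated)
on the objective `sum w |MIND_moving - MIND_fixed|^2 + alpha |grad u|^2`,
with the diffusion term's graph Laplacian assembled sparsely, a ridge of
`1e-6 x` the mean data-term diagonal, and a step-halving line search (at
most 5 halvings) that keeps the objective non-increasing. The field is
stored in millimetres and upsampled linearly between levels. The
channel-gradient linearisation treats the warped descriptor image as
locally translating — the standard demons-style approximation; its
adequacy is checked empirically by the warp-recovery test (>= 80% error
reduction on a 3 px sinusoidal warp).

`alpha` is the one parameter users must tune per dataset: it trades
deformation fidelity against smoothness. The shipped defaults are 0.4
(Stage 1 and 2) and 0.6 for slab-pair alignment during sampling-site
detection, the reference's empirical values; the Stage-1 accuracy
criterion is evaluated at 0.35, inside the reported optimal band
0.3-0.4.

## Stage specifics and the choices behind them

**Stage 1.** The histology image is smoothed with a FWHM 6.25 px Gaussian
(`sigma = FWHM / sqrt(8 log 2)`, reflect boundary) and resampled to the
block-photo resolution, padded by 1/6 per edge (padding prevents the
trivial cost reduction of sliding one image off the other), and
centre-aligned. Steps: rotation search (30-degree grid then bounded
refinement), similarity, affine, then the Gauss-Newton field at
0.8/0.4/0.2 mm/px.

**Sampling-site detection.** Slab photographs are ordered by descending
foreground pixel count (the reference says "most intact" without a
metric). Consecutive pairs are aligned (rigid/affine/non-linear at
1.5/1.0 mm/px, alpha 0.6, no masks), binarized at 10% of each image's
maximum (the same rule as the Stage-2 masks; the reference does not state
the XOR binarization threshold), and XOR-ed. Components below 1 cm^2 or
narrower than 4 mm are discarded; "width" is the minimum caliper (Feret)
diameter, computed over 1-degree directions. Surviving centroids are
mapped through the pairwise chains onto the most intact photograph.

**Stage 2.** The block is initialised at every site over a grid of
rotations (30-degree increments) and translations (+/-10 mm around the
site; the grid step is not stated in the reference — 5 mm is used); the
best three candidates per site are refined and the global best fixes the
sampling-site offset. Foreground masks (10% threshold) apply throughout.

**Stage 3.** The photo is embedded as the middle layer of a user-supplied
prior slab (2 cm thick by default). The rigid search crosses 5 positions
along the slab axis with 3 rotation samples per axis in a 30-degree range,
interpreted as {-15, 0, +15} degrees (the reference's "3 values in a 30
degree range" is ambiguous between this and [0, 30]; the symmetric
reading is used). Candidates are ranked after a cheap cost evaluation at
the coarsest level, the best 24 are refined, and half (at least 3)
survive each pyramid level — the reference says results are "constantly
ranked" without ratios; retaining fewer than ~20 candidates was observed
to lose the true basin for some perturbations. The control points (32 by default; 16
at desk scale) are placed on a rectangular grid clipped to the foreground
and jittered to avoid collinearity, with seeded randomness. Step 3
optimises in-plane displacement components only; step 4 all three.

**Stage 4.** The composed Stage 1-3 mapping is reparameterised by least
squares on a 32x32 sample grid: a Kabsch fit gives the rotation and
translation, the residual is projected onto the 16-point RBF basis, and a
median residual above 0.5 mm is an error advising more control points.
Refinement restricts perpendicular travel to +/-2 mm; the non-linear
steps are off by default (they are reported to help only for sections
with salient anatomy) and can be switched on in the configuration.

**Hemisphere merging.** Two hemisphere-specific Stage-3 chains are blended
pointwise on the photo domain (`w T_left + (1 - w) T_right`) and stored as
a single dense 2D-to-3D map; a logistic midline ramp of 6 mm width is the
suggested weight map. Log-domain composition was considered and rejected
as unnecessary for the near-parallel chains this operation receives.

## The synthetic phantom: what it emulates and what it does not

No real brains ship with this package; every quantitative claim is
evaluated on a deterministic synthetic world scaled to desk size:

- a 96^3 volume at 0.5 mm/voxel holding two ellipsoidal "hemispheres"
  with a folded bright ribbon (cortex-like), dark interior cavities
  (ventricle-like), smooth texture, deliberate left-right asymmetry (so
  pose is identifiable), and 0.01 additive Gaussian noise;
- slab photographs: planar resamplings of the volume at 0.2 mm/px;
- blocks: rectangular crops; at desk scale the slab cross-section is only
  ~38 x 28 mm, so the multi-block suites use 20 x 26 mm blocks while the
  acceptance target keeps the reference's 25 x 35 mm footprint (partly
  covering background, as real blocks do);
- histology: block content pushed through a monotone contrast inversion,
  a seeded smooth warp (2 px amplitude by default) and fine texture;
- simulated slices: the volume resampled onto analytic planar or
  quadratic surfaces (`z = f(x, y)` in a tilted coronal frame, deflection
  kept under 3 mm), with the surface itself as ground truth.

Pose perturbations for the slice simulations draw uniformly from +/-8 mm
along the surface normal, +/-4 mm in-plane and +/-10 degrees per axis.
The reference reports the resulting initial errors (about 5-8 mm median)
but not the draw ranges; these ranges were chosen once to reproduce that
scale and are fixed.

A green test on this world establishes that the algorithms converge to
the stated accuracy when their model assumptions hold. It does not
establish robustness to real histology artefacts (tears, folds, staining
gradients), to photographic nuisances (glare, perspective), or to
anatomy whose cross-sections are less distinctive than the phantom's;
the masking machinery exists for exactly those cases but is exercised
only lightly here.

## Numerical choices and degenerate inputs

- FWHM-to-sigma uses `sqrt(8 log 2)` exactly; smoothing uses reflect
  boundaries.
- Resampling out-of-bounds fill is 0 (declared per call); identity
  resampling is bit-exact for nearest/linear interpolation.
- All-constant images pass through MIND via the variance floor rather
  than erroring; an empty unmasked overlap (degenerate pose) is an error
  that names the step.
- Singular Gauss-Newton systems fall back to a 100x larger ridge;
  duplicate control points are an error listing the offenders.
- Ties in candidate ranking break by candidate ordinal, which together
  with seeded jitter makes entire pipeline runs bit-reproducible.
- Chain files store parameters as 17-significant-digit decimal strings:
  JSON floating-point output was measured not to round-trip doubles
  bit-exactly, and the serialisation contract demands 0 ulp.

The step-monotonicity acceptance test allows a 0.02 mm slack on the
rigid -> affine -> final decline of the median registration error: the
reference's own planar results fluctuate by that order between the last
steps (0.013 mm -> 0.015 mm), so a strict inequality would fail even a
perfect reimplementation. The slack was fixed before the suite was first
run.

## Known limitations

- Runtime-oriented scale-down: the shipped test/acceptance configuration
  uses the reduced pyramid (final level = voxel size), 16 control points
  and 4-slice series so everything finishes in minutes on one CPU; the
  reference-scale settings (0.25 mm levels, 32+ points, 10-slice series)
  are reachable through the configuration but untested here.
- TIFF input and whole-slide (SVS) formats are not supported (no reader
  in the target environment); PNG and PGM are.
- Volumes with oblique affines are handled by moving the rotation into
  the external chain; shear in the voxel-to-world mapping is not.
- Tensor (rank-2) reorientation is out of scope; vectors only.
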