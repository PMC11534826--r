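---
title: "Quantifying treatment effects on cortical bone shape: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying treatment effects on cortical bone shape: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Longitudinal microCT of rodent long bones shows how a treatment — here,
in vivo mechanical loading of an ovariectomized (OVX) mouse tibia —
reshapes the cortical midshaft over weeks. Standard morphometry reduces
each scan to a handful of scalar indices and discards the spatial
pattern of adaptation. `tibiassm` implements an alternative: a
statistical shape model (SSM) of the midshaft built from voxel images,
whose principal components ("modes") are 3D displacement patterns of the
endosteal and periosteal surfaces, and whose per-sample coefficients
("scores") can be tested for treatment-related temporal change.

The pipeline is:

1. **Binarization and geometry correction** (`compute_threshold()`,
   `binarize()`, `fill_small_holes()`, `resolve_large_features()`,
   `check_topology()`): every axial slice of a corrected section must
   contain exactly one cortical wall and one enclosed medullary cavity,
   so that the endosteal and periosteal surfaces are well defined and
   topologically equivalent across samples.
2. **Reference surface** (`extract_surfaces()`, `coarsen()`): the
   bone/background interface of one reference sample is triangulated and
   decimated to a working mesh whose vertices define the correspondence
   for the whole population.
3. **Deformable registration** (`register_volumes()`,
   `interpolate_displacement()`, `warp_mesh()`): a cubic grid with nodal
   spacing NS (default 5 voxels) parameterizes a displacement field
   mapping the reference onto each sample; warping the reference mesh
   gives anatomically corresponding vertices on every bone.
4. **PCA shape model** (`assemble_dataset()`, `fit_pca()`): the M
   corresponding shape vectors (3N coordinates each) are centered into a
   matrix P and factorized as P = aY with orthonormal mode rows Y and
   scores a; at most M - 1 modes carry variance.
5. **Treatment categorization** (`score_changes()`, `mode_report()`):
   per-subject temporal score changes are tested within each group
   (two-sided Wilcoxon signed rank), between groups (Mann-Whitney U), and
   at baseline; each mode is categorized as a treatment-only effect, a
   non-treatment temporal effect, a partial effect, or no temporal
   effect. Flagged modes are summarized by Cohen's d and by the median
   surface change field `MSC_k = median(a_t2 - a_t1) * Y_k`.

No animal data ship with the package: a synthetic phantom generator
(`make_midshaft_phantom()`, `make_population()`,
`make_image_population()`) provides study material with known ground
truth, and a validation harness (`study_suite()`, `run_study()`)
reproduces a six-study protocol of virtual displacement fields for
quantifying registration accuracy and precision.

## The registration model

`register_volumes(fixed, moved, ns)` estimates nodal displacements
$\hat u$ minimizing

$$\sum_x w(x)\,\bigl(M(x) - F(x + u(x))\bigr)^2 \;+\;
  \lambda \sum_{\text{nodes}} \lVert L\hat u\rVert^2,$$

where $M$ is the (pre-blurred) moved/reference image, $F$ the fixed
image, $u(x)$ the trilinear interpolation of the nodal vectors at $x$,
$L$ the discrete 6-neighbour graph Laplacian on the grid, and $w(x)$ a
0/1 mask. The displacement lives on the *moved* image domain: adding
the interpolated displacement to a reference vertex gives the
anatomically corresponding location on the fixed image, which is the
orientation the mesh-mapping step needs.

Numerical choices, all deterministic:

* **Pre-blur, zero-padded.** Binary images carry no gradients; both
  inputs are blurred with a Gaussian of `sigma = 1.5` voxels before
  matching. The blur uses zero padding so that it commutes with content
  shifts on the zero background: a translated copy of an image then has
  *exactly* zero residual at the true displacement, which keeps the
  translation studies unbiased. A plain 1-voxel blur leaves voxel
  staircase gradients on rethresholded surfaces that act as misleading
  texture; 1.5 voxels suppresses them while preserving the ~1-voxel
  surface relief that makes tangential motion observable.
* **Masked truncation.** Voxels whose warped position falls within
  $3\sigma$ of the fixed-image border are excluded from the data term
  ($w = 0$): content there has been truncated by the border and carries
  no displacement information. The Laplacian term extends the field
  smoothly into masked regions.
* **Solver.** Gauss-Newton on the active voxels (those inside the blur
  transition band of either image), with a supernodal sparse Cholesky of
  the normal matrix. The normal matrix is refreshed only every few
  iterations (the gradient is exact every iteration); steps are
  backtracked so the objective never increases, and the update stops
  when the largest nodal change drops below `tol = 5e-4` voxels.
* **Multiresolution and capture range.** A 2x image pyramid (never
  descending below 32 voxels per axis, where the thin cortical wall
  would vanish) plus an FFT cross-correlation integer-shift
  initialization at the coarsest level capture rigid offsets of several
  voxels before the local solver refines them.
* **Regularization weight.** `lambda = 0.05`, scaled relative to the
  mean diagonal of the data normal matrix, so its effect is comparable
  across image sizes. Because the penalty is the Laplacian of the
  field, constant (translation) and piecewise-linear (affine) fields are
  penalty-free away from region boundaries, and the identity case
  returns a strictly zero field.

## What the phantom generator emulates

`phantom_spec()` builds a hollow, eccentric tube with a sharp anterior
crest (a Gaussian ridge in polar angle at the anterior direction, -x),
mimicking a tibial midshaft section at 10.4 um voxels. Three layers of
seeded, reproducible surface structure make it a usable registration
benchmark:

* low-order angular perturbations that rotate helically along the axis
  (`radius_jitter`, default 4% of the outer radius),
* localized bumps and pits on both surfaces (vascular-ridge-like
  features, up to 40% of the wall thickness),
* fine-scale correlated roughness on both surfaces (`roughness`,
  default 1.2 voxels RMS, correlation length of a few voxels).

The roughness layers matter: a smooth surface of revolution leaves the
tangential and axial components of any displacement field unobservable
to intensity-based registration (the aperture problem), so a perfectly
smooth phantom cannot validate the mapping step at all. Real cortical
surfaces at ~10 um resolution are rough at about this amplitude. A
pointwise clamp keeps the endosteal surface at least ~2.5 voxels away
from the periosteal one, so every generated slice is an annulus and
passes `check_topology()` after binarization.

What the phantom does **not** emulate: trabecular architecture, cortical
porosity, scanner physics (beam hardening, ring artifacts), partial
rigid misalignment beyond translations, or biological growth fields.
Passing the validation suite on phantoms therefore demonstrates the
solver's and pipeline's correctness under controlled conditions, not its
performance on any particular real dataset.

`make_population()` plants known, mutually orthogonal per-vertex
displacement fields on a reference mesh and draws subject scores from a
two-timepoint model (baseline spread, treated/control shifts at the
second timepoint, within-subject noise); cohort sizes default to 5
control and 6 treated subjects, the design whose exact signed-rank test
can reach p = 0.03125 (treated, n = 6, all changes one-signed) but at
n = 5 can never cross 0.05 (minimum two-sided p = 0.0625).
`make_image_population()` is the image-level counterpart used by
`run_pipeline()`: treated subjects gain an enlarged anterior crest at
the second timepoint.

## Geometry-correction rules

* Holes are per-slice enclosed background components. "Perimeter" is
  the count of component pixels having an 8-neighbour outside the
  component; components with perimeter < 50 pixels are filled
  (`fill_small_holes()`).
* Larger features are resolved on the aligned timepoint pair
  (`resolve_large_features()`): a feature present for fewer than 7
  adjacent slices at *both* timepoints is treated as a trabecula-bounded
  chamber and its bounding strut is deleted — implemented as removal of
  the bone corridor on minimal feature-to-cavity paths (two BFS distance
  transforms), which merges the chamber into the cavity. Features
  failing the slice rule are classified by their structural change:
  a span change of 3 slices or more marks an evolving trabecular cavity
  (strut deleted); stable features are cortical pores (filled).
* Transverse gaps that breach the cortex are closed by the smallest
  morphological closing that restores the one-wall/one-cavity slice
  topology. Removal of thin spurs protruding into the cavity
  (early-stage trabeculae) is available behind `remove_spurs = FALSE`:
  the underlying decision was operator-reviewed in the original
  protocol, so the automated rule is off by default.
* Connectivity: 8-connected foreground against 4-connected background in
  slices (the standard complementary pairing), 6-connected grouping of
  features across slices, 26-neighbourhoods for boundary voxels.

The threshold comes from a smoothed 256-bin histogram: the dominant peak
(background) and the strongest local maximum outside a quarter-range
exclusion window (bone) are averaged. Images without a second peak
raise an error asking for a manual threshold.

## Surface extraction and coarsening

Surfaces are extracted by marching tetrahedra (a Kuhn 6-tetrahedra
decomposition of each voxel cube, conforming across cubes) at the 0.5
level of the binary image. The x/y faces of the volume are padded with
background so the periosteal shell closes laterally; the z crop planes
are left open — a cropped section has no anatomical end caps, so the two
shells are open tubes whose rims are preserved during decimation by
boundary constraint quadrics. Vertices are labeled endosteal or
periosteal by adjacency to the enclosed cavity versus the outer
background; the rare vertex touching both is assigned periosteal with a
warning.

Coarsening is quadric-error edge collapse with a manifold (link
condition) guard; collapses never merge vertices of different labels.
The coarsening error — the distance from every input vertex to the
coarse surface — is measured on every run and attached to the result; on
the bundled phantoms a 90% reduction keeps the mean error near 0.1
voxels (about 1 um at the default spacing).

## Statistics

* Exact Wilcoxon signed-rank and Mann-Whitney U p-values are used for
  small tie-free samples, with tie-corrected normal approximations
  otherwise (`stats::wilcox.test` supplies the distributions; the test
  suite cross-checks them against exhaustive enumeration of sign
  patterns and group assignments up to n = 8). Zero changes are dropped
  before the signed-rank test, following the original treatment.
* The baseline week-18 group comparison uses the rank-sum form: the two
  groups are unpaired and of unequal size, so a signed-rank (paired)
  test is not applicable there.
* No multiple-testing correction is applied across modes by default,
  mirroring the original reporting convention; `mode_report(holm =
  TRUE)` applies a Holm correction to the within-group p-values.
* Cohen's d is mean/SD of the within-group score changes (sample SD,
  n - 1); a zero SD yields an infinite-effect sentinel with a warning.
* The median of an even number of score changes is the midpoint of the
  two central values.
* Total-variance bookkeeping divides by M - 1 (observations minus one).
  The normalization cancels in every reported fraction, so the choice is
  visible only in absolute variance logs, which are labeled accordingly.
* PCA mode signs are pinned (largest-magnitude component positive) so
  that reports are reproducible; signs are otherwise arbitrary.

## Validation harness and problem sizes

`study_suite()` encodes six studies of increasing complexity: integer
translations (2/4/6 voxels per axis), an anisotropic translation
(2, 2, 4), a fractional translation (2.5, 2.5, then 2 along z) on binary
and on grayscale-then-binarized images, four local affine deformations
(posterior half at Tc = 0.95, a smaller posterior part — default 25% of
the x extent — at Tc 0.85/0.95/1.15, anterior half at Tc = 1.2), and the
affine set on noise-injected grayscale images at NS = 5 and 10, with
measured per-region noise SDs. Errors are Euclidean norms of the
difference between estimated and imposed displacement at the bone
boundary voxels (voxels whose 26-neighbourhood contains both bone and
background), summarized as mean (accuracy) and SD (precision); per-axis
mean absolute differences are also emitted.

The z translation of the fractional study uses nearest-neighbour
resampling for its integer component, and binary images are
re-thresholded at 0.5 after any linear interpolation (the symmetric
choice).

Default problem sizes keep a full run on one CPU practical: six 96^3
phantoms for the registration suite, a 48-slice phantom coarsened to
~400 vertices for shape-model simulations, and 200 replicates for the
power and type-I studies. These sizes are stated in
`scripts/acceptance.R` and the test suite; the methods scale to larger
images unchanged.

## Known limitations

* The registration is SSD-based and assumes pre-aligned inputs up to a
  few voxels plus an integer-shift initializer; it is not a replacement
  for grayscale mutual-information rigid registration of raw scans.
* Error magnitudes on phantoms depend on the surface texture the
  generator plants; smooth regions are registered by regularized
  extrapolation and carry larger tangential uncertainty — as do
  featureless regions of real bones.
* The geometry-correction classification of large features automates a
  step that was operator-reviewed in the original protocol; the rules
  are deterministic stand-ins, and `remove_spurs` stays off by default.
* The shape model is linear (PCA); curved shape manifolds and
  probabilistic extensions are out of scope.
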