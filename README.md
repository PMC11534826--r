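# tibiassm

Statistical shape modelling of longitudinal cortical bone microCT.

`tibiassm` quantifies the 3D geometric effect of a treatment on a
long-bone midshaft section imaged at two timepoints. It is aimed at
preclinical bone researchers who scan rodent tibiae in vivo (e.g.
ovariectomized mice with and without tibial mechanical loading) and want
the *spatial pattern* of cortical adaptation, not just scalar
morphometry.

The core model: after binarization and topological geometry correction,
a reference bone surface (endosteal + periosteal, N vertices) is mapped
onto every sample by deformable registration on a cubic nodal grid
(nodal spacing NS, trilinear displacement interpolation). Each sample j
becomes a shape vector `x_j = (x_j^1, y_j^1, z_j^1, ..., z_j^N)`; the
centered matrix `P` (rows `x_j - x0`) is decomposed by PCA,

    P = a Y,

with orthonormal mode shapes `Y` (rows) and scores `a` (M x (M-1)).
For each mode k the per-subject temporal score change
`Δa_j^k = a_j,t2^k - a_j,t1^k` is tested within groups (two-sided
Wilcoxon signed rank) and between groups (Mann-Whitney U); a mode whose
median change differs from zero only in the treated group is a
treatment-only effect. Flagged modes are summarized by Cohen's
d = mean(Δa)/SD(Δa) and by the median surface change field

    MSC^k = median(Δa^k) · Y^k,

a per-vertex displacement whose sign against the outward normal
distinguishes bone formation from resorption.

No animal data are required: a synthetic midshaft phantom generator and
a six-study virtual-displacement validation harness exercise the whole
pipeline with known ground truth.

## Worked example

```r
library(tibiassm)

# synthetic longitudinal cohort: 2 treated + 2 control subjects,
# two timepoints, treated bones grow a larger anterior crest
res <- run_pipeline(pipeline_config(
  out_dir = tempfile("run"), n_treated = 2, n_control = 2,
  target_vertices = 350, seed = 1,
  base_spec = phantom_spec(n_slices = 48, size_xy = 56, outer_radius = 15,
                           wall_thickness = 5, crest_amplitude = 4,
                           eccentricity = 0.25, roughness = 0.8)))
res$report[1:3, c("mode", "variance_fraction", "p_treated", "p_control",
                  "category", "d_treated")]
attr(res$report, "changes")[, 1:3]
```

A run of the above printed:

```
  mode variance_fraction p_treated p_control category d_treated
1    1            0.9118         1     0.500     none     0.690
2    2            0.0504         1     0.346     none     0.689
3    3            0.0290         1     0.500     none     0.647

  subject   group delta_mode1
1     S01 treated   -5.28e-01
2     S02 treated    4.36e+01
3     S03 control    1.42e-14
4     S04 control    5.68e-14
```

The treated subjects carry large temporal score changes while the
control changes are numerically zero (their two timepoints are the same
anatomy). With only two subjects per group the exact signed-rank test
cannot reach p < 0.05, so no mode is flagged in this smoke run; at the
study design of 6 treated and 5 control subjects a planted 2-SD score
shift is classified `treatment_only` in ~87% of replicates (the
acceptance script's power result).

Registration on its own:

```r
img   <- make_midshaft_phantom(phantom_spec(n_slices = 96, size_xy = 96))
bone  <- preprocess_volume(img)
fixed <- apply_deformation(bone, translation_deformation(c(2, 4, 6)), "nearest")
grid  <- register_volumes(fixed, bone, ns = 5)
bv    <- boundary_voxels(bone)
err   <- interpolate_displacement(grid, bv) -
         imposed_displacement(translation_deformation(c(2, 4, 6)), bv)
mean(sqrt(rowSums(err^2)))   # ~1e-12 voxels: integer shifts are exact
```

## Command line

A thin CLI over the same functions ships in `inst/cli/tibiassm.R`:

```sh
Rscript inst/cli/tibiassm.R phantom    --out vol.mhd --slices 96 --size 96
Rscript inst/cli/tibiassm.R preprocess --in vol.mhd --out bin.mhd
Rscript inst/cli/tibiassm.R register   --fixed f.mhd --moved m.mhd --ns 5 --out grid.csv
Rscript inst/cli/tibiassm.R run        --out rundir --seed 1
```

See `vignettes/tibiassm-methods.Rmd` for the full model description,
parameter meanings and design decisions.
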