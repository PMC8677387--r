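# GaborDictSeg

Patch-based 3D liver segmentation for CT volumes, built around a Gabor
sparse dictionary of boundary patches selected inside a registered prior
boundary — for researchers in medical image analysis who want a fully
tested, self-contained R implementation of this class of single-atlas,
texture-dictionary methods.

## The method

Given a training CT `V_o` with an expert gold-standard liver mask `V_s`,
a target CT `V_u−s`, and ≥ 5 paired anatomical landmarks:

1. **Registration.** A deformation field `s_opt` is interpolated from the
   landmark pairs (global affine + cubic B-spline residual, pull-back
   convention); the warped gold mask `I_s ∘ s_opt` gives the *prior
   boundary* in the target volume.
2. **Gabor features.** Each in-plane patch is encoded as the mean
   absolute response of a 24-filter bank (6 orientations × 4 scales,
   zero-mean unit-norm even Gabor kernels); feature columns are
   L2-normalized so that dictionary matching measures texture pattern,
   not energy.
3. **K-SVD dictionary.** `N` patches sampled on the training gold
   boundary train an overcomplete dictionary `D ∈ R^{m×t}` (unit-norm
   atoms) under the sparse model

   min ‖Y − DX‖²_F  s.t. ‖x_i‖₀ ≤ T0,

   alternating OMP sparse coding with rank-1 SVD atom updates.
4. **Boundary selection.** For each prior-boundary vertex `v`, the 30
   axis-neighborhood candidates `v ± k·e_axis` (k = 1..5) are scored by
   the OMP reconstruction error `L_patch = ‖y − Dx‖`; the per-vertex
   argmin is a predicted boundary point.
5. **Void filling.** The point cloud is dilated into a shell, octree
   scan-conversion + border-anchored parity labelling recover the
   inside/outside field, and dual contouring (surface nets) extracts a
   watertight mesh; its enclosed voxels are the final mask.
6. **Evaluation.** VOE, RVD, ASSD, RMSSSD and MSSD against a gold mask,
   with mean ± sample-SD aggregation across cases.

A synthetic phantom generator (`makePhantomPair`) produces
training/target pairs with a known deformation, gold masks, landmarks,
and a textured organ boundary, so the full pipeline runs and is tested
without any external data.

## Worked example

```r
library(GaborDictSeg)

p <- makePhantomPair(phantomSpec(seed = 1L))
p$targetVolume
#> CTVolume 96x96x96 | spacing 1, 1, 1 mm | origin 0, 0, 0 mm | range [-18.16, 231.5]
p$landmarks
#> LandmarkSet with 27 paired points (mm)

res <- runSegmentation(p$trainingVolume, p$trainingMask, p$targetVolume,
                       p$landmarks, pipelineConfig(seed = 1L),
                       targetGoldMask = p$targetMask, verbose = FALSE)
res$mesh
#> SurfaceMesh: 14120 vertices, 28236 triangles (watertight)
res$boundary
#> BoundaryPoints (predicted): 3928 voxels
res$metrics
#> VOE 9.30% | RVD -0.79% | ASSD 0.847 mm | RMSSSD 1.104 mm | MSSD 4.472 mm
```

Reading the numbers: the segmentation disagrees with the target gold
mask on 9.3% of the union volume (VOE), is 0.8% smaller than the gold
volume (signed RVD), and its surface sits 0.85 mm from the gold surface
on average (ASSD), with a worst-case deviation of 4.5 mm (MSSD) — on a
phantom whose prior boundary started several voxels off after a 4 mm
synthetic deformation. `res$mask` is the solid `CTMask`, exportable with
`writeVolume()`; the mesh exports with `writeMeshSTL()`/`writeMeshPLY()`.

A command-line front end over the same functions lives at
`inst/cli/gabordictseg.R` (subcommands `phantom`, `register`,
`train-dict`, `fill`, `evaluate`, `run`).

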