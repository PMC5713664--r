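# gmidemons

Deformable registration of multimodal medical image pairs — the scenario is
aligning an anatomical CT onto a functional PET of the same subject — using
the **demons** optical-flow algorithm augmented with an external force equal
to the **gradient of Parzen-window mutual information**, inside a
coarse-to-fine multiresolution driver with a rigid mutual-information
pre-alignment stage.  The package is aimed at researchers who need a
transparent, fully scriptable multimodal registration with synthetic
ground-truth validation: every stage (phantom generation, rigid alignment,
deformable registration, Hausdorff-family evaluation) is an exported R
function, and a CLI wraps the same functions for shell use.

## The method

A displacement field `v` on the reference grid pulls floating intensities:
the registered image is `o(P) = F(P + v(P))`.  Each iteration updates

```
v^{n+1} = G_sigma * ( v^n  +  (r - f) ∇r / (||∇r||^2 + (r - f)^2 / k^2)  +  alpha · N · ∇MI(v^n) )
```

where `f = F(P + v^n)` is the warped floating intensity, `G_sigma` is
Gaussian regularization of the summed field, and `∇MI` is the analytic
derivative of the Parzen-window mutual information

```
MI(v) = ∬ p(i,j) log[ p(i,j) / (p_R(i) p_F(j)) ] di dj ,
p(i,j) = (1/N) Σ_P K_δ(R(P) − i) K_δ(F(P+v) − j)
```

with respect to each voxel's displacement.  The intensity-difference
(demons) force drives monomodal structure; the MI force carries the
multimodal structure where intensities disagree — with a non-monotone
intensity relation between the modalities, the difference force alone is
misdirected and the normalization constant `k` gates it out of strongly
mismatched regions.  Registration quality is evaluated with the modified
Hausdorff distance (M-HD) between feature point sets: the symmetrized mean
of minimal point-to-set distances, `max( mean_a min_b ||a−b||,
mean_b min_a ||b−a|| )`, robust to stray points.

See `vignettes/gmi-demons-methods.Rmd` for the full model, discretization
choices, parameter table and known limitations.

## Worked example

Generate a synthetic multimodal phantom pair — one anatomy rendered as a
"PET-like" channel (with a bright lesion blob only that channel sees) and a
"CT-like" channel under a non-monotone intensity remap, misaligned by a
known smooth deformation (max 5 voxels) plus a (5, −3) voxel / 5° rigid
offset — then register and evaluate:

```r
library(gmidemons)

pair <- generate_phantom_pair(phantom_spec(seed = 42))
manifest <- run_pipeline(pair$reference, pair$floating)
print(manifest)
#> <run_manifest> gmidemons 0.1.0
#>   MI   before / global / deformable: 0.40299 / 0.8005 / 0.89672 nats
#>   M-HD before / global / deformable: 3.6296 / 0.72125 / 0.16667 voxels

result <- attr(manifest, "result")
print(result$global_transform)
#> <rigid_transform> rotation 5.037 deg | translation (4.871, -3.461) voxels

truth_total <- compose_rigid_field(pair$truth_field, pair$truth_rigid)
est_total   <- compose_rigid_field(result$field, result$global_transform)
endpoint_error(est_total, truth_total, pair$body_mask)$mean
#> 0.8249...
```

Reading the numbers: mutual information between the channels rises at every
stage (0.40 → 0.80 → 0.90 nats), and the modified Hausdorff distance
between the body contours falls from 3.6 voxels before registration to 0.72
after the rigid stage and 0.17 after the deformable stage — the monotone
improvement pattern the two-stage design is built to deliver.  The rigid
stage recovers the generated 5° / (5, −3) offset to within a tenth of a
degree and half a voxel, and the final field is within 0.82 voxels (mean,
inside the body) of the known ground truth.

The same pipeline from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/gmidemons.R", package = "gmidemons"))')
Rscript $CLI make-phantom --seed 42 --out-dir case1
Rscript $CLI run --reference case1/reference.nii.gz --floating case1/floating.nii.gz --out-dir case1/out
Rscript $CLI evaluate --reference case1/reference.nii.gz --warped case1/out/warped.nii.gz
```

Subcommands: `make-phantom`, `global-register`, `register`, `evaluate`,
`run`.  Images are NIfTI (`.nii`/`.nii.gz`) or a portable raw-float32 +
JSON-sidecar format; point sets are CSV/whitespace tables; transforms,
configurations and run manifests are JSON.

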