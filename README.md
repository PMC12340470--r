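# prosegvar

Quantifying inter- and intra-observer variability of manual and
semi-automatic 3D prostate surface segmentation on transrectal ultrasound
(TRUS) geometry.

Prostate segmentation on 3D TRUS is the geometric backbone of MRI–TRUS
fusion biopsy and an increasingly common source of "ground truth" for
training AI models. Experts segment either **manually** — placing sparse
boundary points on axial/sagittal/coronal slices, from which a surface
must be reconstructed a posteriori — or **semi-automatically**, where a
shape-constrained deformable mesh is generated from three reference
landmarks (apex, base, posterior) and refined interactively. How much the
resulting surfaces differ between experts, between repeat sessions of the
same expert, and between reconstruction methods determines which protocol
should define the reference standard.

`prosegvar` implements the full analysis pipeline for that question, for
people studying segmentation variability or building reference datasets:

- **Geometry**: triangle meshes (PLY/STL/OBJ), sparse point annotations
  with the apex/base/posterior landmark triplet (CSV/JSON), exact
  closest-point-on-mesh queries, and Procrustes alignment.
- **Metrics**: average surface distance (ASD) — points-to-mesh
  `mean_i d(p_i, S)` and symmetric mesh-to-mesh — volumetric Dice
  `2|A∩B|/(|A|+|B|)` on a common 0.46 mm voxelization, and the symmetric
  Hausdorff distance.
- **Statistical shape model (SSM)**: generalized Procrustes + PCA over
  corresponded meshes; `fit_ssm_to_points()` computes the *strict* mesh
  `x = x̄ + Φb` (pose ∘ subspace) closest to an expert's points
  ("manual_SSM").
- **Soft SSM**: the strict fit warped by a cubic B-spline free-form
  deformation minimizing Σ d(p_i, S)² + w·(lattice bending energy)
  ("manual_soft-SSM" / the semi-automatic method).
- **STAPLE-like mesh consensus**: EM over raters — weights
  w_i ∝ 1/(d_i² + ε²) from each mesh's ASD to the evolving consensus,
  consensus vertices updated as weighted averages of surface projections.
- **Statistics**: median (IQR) summaries, Wilcoxon tests with Bonferroni
  correction, and cross-study Cohen's d with σ ≈ IQR/1.35 and pooled
  SD √((s₁²+s₂²)/2).
- **Spatial variability maps**: manual points registered onto the mean
  shape; kernel density and kernel-weighted ASD per vertex, exposing the
  apex/base sparsity–variability relationship.
- **Synthetic cohort generator**: a fully deterministic multi-expert study
  (shared subset, repeat "bis" sessions, per-expert bias fields,
  slice-quantized noisy point placement, pole sparsity) so the entire
  pipeline is testable without clinical data.

## Worked example

```r
library(prosegvar)

ssm   <- build_toy_ssm(seed = 1)               # shape model, 50 shapes
truth <- simulate_patient(ssm, seed = 42)      # ground-truth surface
ann   <- simulate_manual_annotation(            # one expert's session
  truth, expert_profile("A", cohort_config(), seed = 7),
  cohort_config(), seed = 99)

strict <- fit_ssm_to_points(ssm, ann)$mesh     # manual_SSM
soft   <- fit_soft_ssm(ssm, ann)               # manual_soft-SSM

asd_points_to_mesh(annotation_points(ann), strict)
#> [1] 0.7518777
asd_points_to_mesh(annotation_points(ann), soft)
#> [1] 0.6265141
```

The strict reconstruction is confined to the model subspace and cannot
follow this gland's out-of-model detail, so it sits ~0.75 mm from the
expert's points; the deformable reconstruction follows them to ~0.63 mm.
Scaling that contrast up to a full cohort:

```r
cfg <- cohort_config(n_patients = 6, n_experts = 4, seed = 5,
                     shared_subset_size = 6, bis_subset_size = 3,
                     manual_points_range = c(80, 160),
                     semi_auto_points_range = c(30, 60))
res <- run_variability_study(generate_cohort(cfg))
res$summaries[1:6, c("table", "method", "median", "n")]
#>                table   method    median  n
#> 1       manual_inter      SSM 0.9902065 72
#> 2       manual_inter soft_SSM 0.9375415 72
#> 3       manual_intra      SSM 0.7941139 12
#> 4       manual_intra soft_SSM 0.7059969 12
#> 5 mesh_method_impact      SSM 0.6889640 24
#> 6 mesh_method_impact soft_SSM 0.5098014 24
res$maps$spearman_rho
#> [1] -0.7168598
```

Medians are ASD in mm. The table reproduces the qualitative structure of
multi-expert TRUS studies: soft reconstruction lowers inter-expert
variability, intra-expert variability is below inter-expert for both
methods, the deformable mesh is intrinsically more faithful to the placed
points, and the negative Spearman correlation says that the regions where
experts place few points (apex/base) are exactly the regions of highest
manual-vs-semi-automatic disagreement.

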