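---
title: "Methods: quantifying observer variability in 3D prostate surface segmentation"
author: "prosegvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying observer variability in 3D prostate surface segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, parameters and
numerical choices. Everything quantitative stated here is computed by the
test suite or by `scripts/acceptance.R`; nothing is asserted that the code
does not measure.

## The problem

On 3D transrectal ultrasound (TRUS), a prostate segmentation is ultimately
a closed triangulated surface in millimetre coordinates. Experts produce
it in one of two ways. In the *manual* protocol they place three reference
landmarks (apex, base, posterior) and then sparse boundary points on one
medial sagittal slice, one medial coronal slice, and a stack of axial
slices — without ever seeing a reconstructed contour. A surface must then
be built from the points a posteriori. In the *semi-automatic* protocol
the same three landmarks initialize a shape-prior mesh which the expert
refines by adding correction points; the deformable surface re-evolves
after each interaction.

Variability — between experts, between repeat sessions, and between
reconstruction methods — decides which protocol yields the most reliable
reference standard. The package measures it with three metrics: the
average surface distance (ASD; for manual sessions necessarily the
points-to-mesh form, because a point cloud has no surface of its own),
the volumetric Dice coefficient on a common voxelization, and the
symmetric Hausdorff distance.

## Surface reconstruction from sparse points

### Strict statistical-shape-model fit (`fit_ssm_to_points`)

The statistical shape model is a mean shape $\bar{x}$ with orthonormal
variation modes $\Phi$ and eigenvalues $\lambda_k$, obtained by
generalized (rigid) Procrustes alignment of corresponded training meshes
followed by PCA of the stacked vertex coordinates. The strict fit finds
the mesh $T(\bar{x} + \Phi b)$ — a similarity/rigid pose $T$ composed with
a point in the model subspace — closest to the annotated points.

Numerically this is solved by alternating exact closest-point
correspondence (a compiled point-to-triangle kernel, identical in value to
the exhaustive scan) with a **joint Gauss–Newton step** over $(b, \omega,
t)$ — mode loadings, rotation increment, translation — using
point-to-plane residuals plus a lightly weighted (0.001) point-to-point
term. Two details matter and were chosen after observing the obvious
alternatives fail:

* A *block alternation* (solve $b$, then update the pose by Procrustes)
  converges at the classic slow ICP rate because pose and shape share a
  shallow valley; the joint step removes it, and the point-to-plane form
  lets correspondences slide tangentially, giving convergence to
  numerical precision in 10–20 iterations on in-subspace data.
* The ridge is a prior-scaled (Mahalanobis) penalty
  $\alpha \sum_k b_k^2/\lambda_k$ with
  $\alpha = 10^{-3}\bar{\lambda}\cdot 3/n$: essentially unbiased for
  dense point sets (the recovery test demands coefficients within 2% of
  $\sqrt{\lambda_k}$ from 200 noiseless points) while keeping
  rank-deficient landmark-only fits stable. A flat identity ridge at a
  fixed weight either biases dense fits or under-regularizes sparse ones.

Loadings are clamped to $\pm 3\sqrt{\lambda_k}$ (the standard guard
against implausible shapes), backtracking keeps the objective trace
monotone, and the pose is initialized from the three landmarks against
the model's landmark convention (apex = min-z vertex, base = max-z,
posterior = min-y).

### Soft (deformable) fit (`fit_soft_ssm`)

Stage 1 is the strict fit. Stage 2 warps it with a cubic B-spline
free-form deformation minimizing

$$\sum_i d(p_i, S)^2 \; + \; w \, E(\text{lattice})$$

where $E$ is the lattice regularizer: squared second differences
(bending) along each axis, a first-difference membrane term (weight 2),
and a small magnitude term ($10^{-2}$). The membrane term is not
cosmetic: pure bending energy has an affine null space, so a single
correction point would drag the entire mesh linearly; with the membrane
term a 5 mm pull moves the far hemisphere by under ~0.3 mm on the default
lattice (the locality test asserts < 10% of the pull). The magnitude term
makes the large-weight limit exactly the strict fit.

Defaults: control spacing 7 mm, weight $w = 0.01$. These are surrogate
choices — the clinical implementation this emulates is proprietary and
publishes no constants — set so that the deformable stage genuinely
captures out-of-model surface detail (noiseless residual ~0.1 mm vs
~0.4 mm for the strict fit). At the stiffer settings one might first
guess (spacing 10 mm, weight 1) the two stages are nearly
indistinguishable and the whole strict-vs-soft contrast, which is the
point of the analysis, vanishes. All constants live in
`soft_fit_config()`, not in code.

`incremental_refine()` models the interactive loop. Given the landmark
triplet it re-runs the full two-stage fit on the accumulated point set,
so a sequence of refinements ends at *exactly* the mesh a single batch
fit of the same points produces — the order of interaction cannot leak
into the result.

## STAPLE-like mesh consensus

The consensus of $N$ corresponded meshes starts from the unweighted
vertex mean and iterates an EM loop: (E) each mesh's symmetric ASD $d_i$
to the current consensus becomes a reliability weight
$w_i \propto 1/(d_i^2 + \varepsilon^2)$, $\varepsilon = 0.1$ mm (a
Gaussian kernel is available as a sensitivity variant); (M) every
consensus vertex moves to the weighted average of its **closest-point
projections** onto the raters' surfaces, until the maximum displacement
falls below $10^{-4}$ mm (cap 100 iterations).

Averaging projections rather than raw vertex positions is deliberate:
independently fitted meshes share topology but not within-surface vertex
placement, and raw vertex averaging measurably shrinks and smooths the
consensus — enough, in cohort experiments, to invert the expected
ordering between consensus-based and pairwise comparisons. Projection
averaging is also the reading most consistent with "iteratively adjusting
the point positions of the computed mesh". The weight kernel and
convergence rule are not published for the original platform; both are
exposed in the function signature.

## Effect sizes from printed summaries

Cross-study comparisons standardize differences with Cohen's d. When a
study reports median (IQR), the SD is approximated by
$\sigma \approx \text{IQR}/1.35$ (the normal-theory width of the
interquartile range), medians stand in for means, and the pooled SD is
the unweighted two-group form $\sqrt{(s_1^2+s_2^2)/2}$ — the variant that
reproduces every printed cross-study value to two decimals from printed
inputs alone, which the test suite and `scripts/acceptance.R` verify
against an independent transcription of the formulas. Thresholds 0.2 /
0.5 / 0.8 on $|d|$ classify effects. Within-study *paired* effect sizes
require the SD of paired differences, which printed summaries do not
contain; the package therefore reports its own paired d values for
synthetic cohorts but makes no claim to reproduce printed paired values.

The eight-row fixture `inst/extdata/cross_study_summaries.csv` carries
the printed inputs; `reference_summaries.csv` records the reference
study's summary tables, including both printed variants of the
intra-observer upper quartile (2.5 in the results table, 2.6 in the
abstract), flagged in its `note` column.

## The synthetic cohort

No clinical TRUS dataset is deposited, so the package ships a generator
whose defaults emulate the study design: 4 experts, 100 patients, a
shared subset of 12 segmented manually by everyone, 5 re-segmented
("bis"), manual sessions capped at 25 per expert, manual point counts
spanning the observed 81–573 envelope and semi-automatic counts 31–105,
semi-automatic repeats by two experts. `cohort_design()` gives the exact
record-count arithmetic implied by a configuration and is the oracle the
generator is audited against.

Mechanisms, and what they emulate:

* **Training shapes / toy model**: triaxial ellipsoids (sizes chosen so
  sampled volumes stay in a prostate-plausible 15–90 mL) with smooth
  low-order harmonic radial perturbations on shared icosphere topology —
  correspondence is free by construction; establishing correspondence on
  arbitrary clinical meshes is explicitly out of scope.
* **Ground-truth patients**: model samples ($b_k \sim N(0,\lambda_k)$,
  truncated at $3\sigma$) plus a 1 mm-RMS field of localized Gaussian
  bumps. The bumps are intentionally *outside* what low-order harmonics
  span: real glands are not perfectly captured by any finite shape model,
  and this residual detail is the mechanism behind the strict-vs-soft
  reconstruction gap. (Perturbing with the same harmonic family as the
  training shapes fails silently — the model absorbs it.)
* **Point placement**: contour points on axial planes at 2 mm spacing
  plus one medial sagittal and one medial coronal slice; iid Gaussian
  jitter of 0.6 mm (calibrated from the reported ~0.5 mm soft-mesh
  point fidelity, since $E|N(0,\sigma)| \approx 0.8\sigma$ along the
  surface normal); a smooth per-expert radial bias field of 0.5 mm RMS —
  the minimal mechanism making inter-expert exceed intra-expert
  variability.
* **Polar degradation**: sampling density inside 25%-area apex/base caps
  reduced by 60%, and click noise doubled there — including for the apex
  and base landmarks themselves. Both reflect how poorly those regions
  are visualized on axial slices. Without the landmark part, the poles
  are anchored by nearly exact landmarks and come out as the *most*
  accurate regions, producing a positive density–ASD correlation — the
  opposite of what sparse-annotation physics should give.
* **Semi-automatic sessions**: noisy landmarks → prior-only fit →
  batches of 8 correction points drawn with probability proportional to
  squared surface error (error-weighted, not argmax: a pure argmax expert
  stacks every point in one spot and produces unrealistically bad
  surfaces), each batch followed by a full re-fit.

Everything is a deterministic function of the configuration and its seed;
the manifest hash test asserts bit-reproducibility.

What the generator does **not** emulate: ultrasound speckle or any image
formation, pathology (median lobes), catheter/probe deformation,
expert learning effects. Passing the pipeline's tests on this cohort
shows the *analysis machinery* reproduces the qualitative structure of
multi-expert TRUS variability under these mechanisms; it is not evidence
about any particular clinical dataset.

## The study driver and problem sizes

`run_variability_study()` executes the full design: manual
reconstructions by both methods; inter-individual manual ASD (each
expert's points against every other expert's mesh — the points-to-mesh
asymmetry is the protocol's, preserved deliberately); intra-individual
ASD via bis sessions; intrinsic meshing fidelity (own points vs own
mesh); semi-automatic pairwise ASD/Dice/Hausdorff; leave-one-out
consensus comparisons; manual-vs-semi-automatic comparisons (pairwise and
vs the all-expert consensus); Wilcoxon signed-rank tests with Bonferroni
correction for the family of three manual-method contrasts; and the
spatial density/ASD maps with their Spearman rank correlation. Comparison
counts are audited against the manifest — a mismatch is an error, not a
warning.

The regression cohort used by the acceptance tests is scaled down to keep
the suite fast: 4 experts, 6 shared patients, 3 bis, manual 80–160
points, semi-automatic 30–60, Dice voxel 0.46 mm. At these sizes the five
qualitative findings (soft < strict inter-variability; intra < inter for
both methods; soft < strict intrinsic fidelity; consensus ≤ pairwise;
negative density–ASD correlation) are stable and the cohort plus study
run in a few minutes on one core.

## Numerical details and degenerate inputs

* Zero-area faces are dropped on mesh construction (message, not error);
  only Dice requires watertightness, checked by edge-manifold analysis,
  and refuses non-watertight input naming the offending mesh.
* Dice voxelizes both interiors on the common bounding grid by ray-parity
  with a fixed sub-voxel ray offset (exact edge hits are measure-zero for
  generic meshes); at 0.46 mm the nested-sphere closed form is matched
  within 1%.
* Closest-point queries prune faces by a centroid-radius bound seeded
  from the nearest centroid; the result is identical to the exhaustive
  scan (property-tested against an independent brute-force
  implementation) at roughly an order of magnitude less cost.
* Quartiles use linear interpolation (R type 7) throughout; the source
  summaries do not state a convention.
* Procrustes alignment excludes reflections (determinant guard) and
  refuses collinear configurations; scale estimation is off by default
  everywhere except annotation-to-reference registration for the spatial
  maps, where glands of different sizes are normalized onto the mean
  shape.
* Iterative fits after a rigid motion of the input take different
  floating-point paths (closest-face tie-breaks), so exact equivariance
  holds only to ~1e-3 mm; the invariance tests assert equal fit quality
  at that tolerance rather than bitwise equality.

## Known limitations

* Dense correspondence on arbitrary clinical meshes (spherical
  parameterization, functional maps) is out of scope; the consensus and
  SSM assume shared topology, which the package's own reconstructions
  guarantee.
* The deformable surrogate reproduces the *structure* of the clinical
  algorithm (shape prior + B-spline-regularized point attraction), not
  its constants; absolute millimetre magnitudes from synthetic cohorts
  should not be read as predictions for any scanner or platform.
* The Hausdorff distance uses mesh vertices against the opposing full
  surface; with tessellation edges well under 2 mm the induced error is
  far below reported interquartile ranges.
* 95th-percentile Hausdorff, signed distances and surface-Dice variants
  are not implemented (not part of the analysis this package serves).
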