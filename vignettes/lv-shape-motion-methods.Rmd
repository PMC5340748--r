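---
title: "Methods: left-ventricular shape and motion analysis with lvssa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: left-ventricular shape and motion analysis with lvssa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Clinical cardiac MR yields two complementary image sets per subject: a single
high-resolution, isotropic whole-heart (WH) volume acquired during the
mid-diastolic rest period, and a short-axis cine stack — around twenty phases
per cardiac cycle but with coarse (~8 mm) through-plane sampling. Neither set
alone supports 3D analysis of ventricular motion. `lvssa` implements a
framework that combines them: cine-derived motion is propagated onto the WH
volume to produce a synthetic high-resolution volume at every phase, the left
ventricle (LV) is segmented and meshed at each phase, each subject is
summarized by an *anatomical model* — a template mesh plus smooth
deformations parameterized by momenta on a control-point grid — and
population-level analysis is done by PCA on the momenta: separately on
end-diastolic (ED) and end-systolic (ES) shape, and on motion decoupled from
shape by replaying each subject's deformations on a population-average
carrier shape (the SuperTemplate).

Because suitable image data cannot be bundled, the package ships a synthetic
LV cohort generator with full ground truth; every stage of the pipeline is
validated against that ground truth.

# Pipeline stages and their models

## Motion propagation

Per phase *t*, the cine slices sharing a trigger time are stacked along their
common normal and the through-plane gaps filled by linear interpolation
(`assemble_frame()`). Each assembled frame is scored against the WH volume by
the sum of squared intensity differences (SSD) over the voxel overlap; with
`SSD_max` the largest per-subject score, frames with `SSD < 0.5 * SSD_max`
(strictly) are *highly similar*, the rest *poorly similar*
(`classify_frames()`). Synthetic WH frames are generated in cyclic temporal
order starting from the minimum-SSD frame (the phase closest to the WH
acquisition): highly similar frames are registered directly from the WH
volume, poorly similar ones from the previously generated synthetic frame,
so large systolic deformations are reached through a chain of small ones
(`propagate_motion()`).

The registration engine is a diffusion-regularized demons algorithm with the
SSD metric (`register_nonrigid()`), multi-resolution, with both fluid-like
(update) and diffusion-like (field) Gaussian smoothing. An update is accepted
only when it lowers the SSD, which makes the method monotone and gives the
contract `SSD(warp(moving), fixed) <= SSD(moving, fixed)` unconditionally.
The engine is deliberately self-contained and pluggable through
`registration_params()`; any external engine producing a dense displacement
field could be substituted. Fields are stored as millimetre displacements
along world axes on the fixed grid; label maps are carried to each frame with
nearest-neighbour sampling (single-atlas label propagation), intensities with
trilinear sampling.

Per-frame meshes come in two flavours. For validation, each frame's mask is
meshed independently (`extract_mesh()`): a marching-tetrahedra isosurface at
0.5 (six Kuhn tetrahedra per cube; closed, consistently oriented by
construction) followed by Laplacian smoothing whose shrinkage is corrected by
a uniform volume-restoring rescale. For model building, the reference WH mesh
is warped through the numerically inverted per-frame fields
(`propagate_mesh()`), which guarantees an identical vertex set across frames
of one subject and carries the endo/epi vertex labels along.

## Subject anatomical models

A subject model is a template mesh, a control-point grid `c_k`, and one
momenta set `beta_k` per frame. A momenta set deforms space by integrating

    dx/dt = sum_k exp(-|x - c_k(t)|^2 / lambda_v^2) beta_k ,  t in [0, 1]

with forward Euler (`flow()`); control points are advected by the same field.
Momenta are held constant along the flow — a desk-scale simplification of
geodesic shooting (no momentum transport); with the default 10 Euler steps,
step-halving changes final vertices by well under 1% of the displacement.
The data term comparing surfaces is the currents metric
(`currents_distance()`): with triangle centers `c_i` and area-weighted
normals `n_i`,

    ||A - B||^2 = S(A,A) + S(B,B) - 2 S(A,B),
    S(P,Q) = sum_ij exp(-|c_i - c_j|^2 / lambda_w^2) (n_i . n_j),

a correspondence-free pseudo-metric on oriented surfaces. Both kernels are
isotropic Gaussians; `lambda_w` (mm) sets the resolution at which shape
differences are seen, `lambda_v` (mm) the stiffness of admissible
deformations. Defaults are 13 mm and 23 mm (values appropriate for
1.4 mm-resolution clinical data); the reduced-resolution pipeline
configuration narrows the data kernel to 8 mm so the fit can see
differences near its ~1 mm meshing-noise floor. `tune_parameters()` greedily
scans a user grid and scores each candidate by the mean surface distance
between the flowed template and the input shapes — the distance is the
one-directional pointwise minimum from computed to original surface
(`surface_distance()`, point-to-triangle).

`estimate_registration()` minimizes `J(beta) = ||flow(T, beta) - S||^2 +
gamma * sum_kl K_v(c_k, c_l) beta_k . beta_l` by gradient descent with
backtracking; gradients flow through the Euler integration by a hand-written
adjoint pass (validated against finite differences at 1e-8 relative).
`estimate_atlas()` alternates per-shape momenta estimation with a
backtracking gradient update of the template vertices; the total energy is
non-increasing across all sub-steps. The template is initialized as the
vertexwise mean (shapes from the mesh-propagation route share a topology);
the currents data term makes mixed topologies admissible, in which case the
first shape initializes the template. Control points default to a regular
grid over the template bounding box (the 125-point default is a 5x5x5 grid);
their optimization is off by default and available as a flag. The regularity
weight `gamma` defaults to 1.

## Scaling, alignment, and the common space

Each subject model is scaled by `s = (V_ref / V_subject)^(1/3)` about its
template centroid, where `V_subject` is the *template's* endocardial volume
(divergence-theorem volume of the capped endocardial submesh) and `V_ref`
the cohort mean. Subject templates are then co-aligned by generalized
Procrustes analysis on their endocardial surfaces: iterate rigid ICP of every
mesh onto the evolving mean. ICP is nearest-vertex + Kabsch (SVD with
reflection guard), pre-aligned by centroids *and principal axes* — the
principal-axes candidates (all proper sign assignments, plus identity,
scored by nearest-neighbour RMS) pull ICP into its convergence basin when
the initial misalignment exceeds the vertex spacing.

Transforms apply to whole models: vertices and control points as
`x -> s R x + t`, momenta as `beta -> s R beta`, and — a deliberate design
choice — kernel widths as `lambda -> s lambda`. Without the kernel-width
scaling the transform would not commute with the flow; with it,
`flow(T(template), T(beta)) = T(flow(template, beta))` holds to floating
point, which the test suite asserts.

## Shape analysis

ED and ES are defined per subject as the frames of maximal and minimal
endocardial volume (the segmented blood-pool volume trace in the pipeline).
The phase meshes — ideally the subjects' own segmented frame meshes brought
into the common space; alternatively the flowed templates — are pooled into
one phase atlas, and PCA is run on the stacked momenta (`fit_pca()`:
column-mean centering, covariance eigendecomposition with divisor n - 1, at
most n - 1 nonzero modes, deterministic sign convention). Each subject's
*shape vector* holds its projections on the retained modes; modes are
visualized by flowing the phase template along `mean ± 2 sigma * mode`
(`mode_mesh()`) with a per-vertex deformation-magnitude map. The default
mode count reaches 75% cumulative variance, capped at n - 1.

## Motion analysis

The SuperTemplate is the average shape of the aligned subject templates
(atlas route by default; vertexwise mean available when topologies match).
Each subject's per-frame momenta and (transformed) control points are
replayed on the SuperTemplate (`transfer_motion()`), yielding
`n_subjects x n_frames` shapes that differ only by motion. One pooled model
is estimated over this set — with the template *fixed* to the SuperTemplate
by default, which anchors the motion modes to a common reference and halves
the compute (re-estimation is a flag) — followed by PCA. Per-subject
*motion traces* are the frame-ordered projections, with phase expressed as
the fraction of the RR interval (trigger-time normalized). Mode meshes at
±2 sigma carry per-vertex displacement vectors ("arrows") from the template.

## Group statistics

Shape-vector coefficients are summarized per group by median and IQR with
quartiles interpolated at `1 + (n - 1) p` (the convention that exactly
reproduces the recomputable entries of the bundled example tables), boxplot
whiskers at the most extreme points within 1.5 IQR, and compared by an
*exact* two-sided Mann-Whitney U test: U counts pairs with `a > b` (ties
half), and the p-value enumerates all `choose(n + m, n)` group assignments
(feasible up to n + m = 20; the smallest attainable two-sided p at 4 vs 4 is
2/70 ≈ 0.029, so "significance" is nearly out of reach at this sample size —
which is itself a finding the statistics module reproduces).

# The synthetic cohort: what it emulates and what it does not

The phantom wall is a truncated prolate spheroid (epicardial equatorial
radius 33 mm, long axis 96 mm, wall 8 mm, basal truncation keeping 75% of
the long axis), closed by a flat basal cap, with two asymmetries: a *fixed*
mild septal flattening (10% radial, toward -x) shared by all subjects, and a
per-subject lateral *bulge* of variable amplitude. The flattening exists
because a real LV is not a surface of revolution — the septum abuts the
right ventricle — and, operationally, because rigid alignment of a surface
of revolution is rotationally ill-posed: without it, GPA rotations lock onto
incidental asymmetries and alias into the shape modes. The default geometry
gives an end-diastolic volume near 90 mL, inside the 64–151 mL range of the
example cohort table; per-subject anatomical jitter is deliberately small
(radius 0.4 mm, long axis 1 mm, wall 0.2 mm sd) next to the injected bulge
(half-normal, sd 5 mm), because the recovery experiments require a single
dominant injected shape factor at cohort sizes of 4–8.

Motion is separable: radial contraction about the long axis, longitudinal
shortening toward the fixed basal plane, and apex-weighted twist, all driven
by a raised-cosine contraction profile p(s) with systole occupying 35% of
the cycle and p(0) = p(1) = 0 exactly (closed cycle). Amplitudes are jointly
rescaled by a root-solve so the realized ejection fraction matches the
target within the frame discretization (±0.02 at 10 frames); contraction is
capped at 55% so that physiologically impossible EF targets raise an error
rather than collapse the mesh. The patient group differs by a hypokinetic
septal-plus-inferior territory (radial factors 0.05 and 0.4 — a large
infarct-like region, sized so the injected pattern stays recoverable through
the image pipeline's ~1 mm tracking noise) and reduced twist; EF targets are jittered only
slightly (sd 0.012) — consistent with the overlapping group EF ranges of the
example table, and necessary because volume normalization uses the
*template* (time-average) volume, through which EF differences would
otherwise leak into scaled ED size.

Images are rasterized by column ray casting of the closed endo/epicardial
surfaces (background / blood pool / myocardium with distinct means plus
Gaussian noise); cine stacks are resampled on plane lattices aligned with
the volume lattice. Trigger times are uniform over a 1000 ms RR interval.
Slice-misalignment (breath-hold) artifacts are not simulated by default and
no MR physics (bSSFP contrast, banding) is modelled; passing tests therefore
demonstrate the *method's* correctness on geometrically faithful data, not
robustness to acquisition artifacts. The right ventricle and atria are
absent (background label only).

# Numerical choices

* Marching tetrahedra rather than table-based marching cubes: the 6-tet cube
  decomposition has trivially enumerable cases, yields closed oriented
  manifolds, and leaves binary-mask vertices on the half-integer lattice.
* Ray-cast rasterization jitters ray origins by a small irrational offset so
  edge-coincident hits are measure-zero.
* Laplacian smoothing restores the enclosed volume by a uniform rescale
  about the centroid (drift ~ 0 rather than merely bounded).
* Demons: updates capped at one voxel per iteration, candidate accepted only
  on SSD decrease, internal step halved on rejection; divergence therefore
  cannot occur silently.
* Flow adjoint and currents gradient are analytic and finite-difference
  validated; line searches reuse the previous accepted step with 1.5x growth
  and halving on rejection.
* The currents norm of a surface shrinks with the surface, so a partial
  collapse or fold of the deformed template can lower the data term while
  leaving the target: registration rejects candidates whose total area
  drops below 70% of the target's area (unless the step grows the area
  back). Per-subject frame atlases warm-start each frame's momenta from the
  previous frame's solution.
* PCA signs: the largest-magnitude loading of every mode is positive.
  Coefficient signs are otherwise convention-dependent and never compared
  across implementations.
* Exact Mann-Whitney enumerates midrank U over `combn(n + m, n)`;
  two-sided p is `min(1, 2 min(P(U <= u), P(U >= u)))`.

The default problem sizes used by the test-suite and the acceptance script —
a 2 + 2-subject cohort at 4 mm voxels, 10 frames, meshes decimated once at
the diastolic reference to a 6 mm vertex spacing, 64 control points, an
8 mm data kernel — are the package's reduced-resolution study
configuration: small enough to run interactively, large
enough that every recovery experiment (volume-trace correlation, bulge
recovery, motion-based group separation, shape-removal) is non-trivial.

# Design decisions on open points

* **Group separation statistic.** The pooled motion PCA centers the data, so
  two balanced groups with opposite regional patterns sit antipodally about
  the mean: the mean *absolute* mode coefficient is then equal in both
  groups by construction. The separation experiment therefore classifies on
  the per-subject mean *signed* mode-2 coefficient.
* **ED/ES selection** is by extremal endocardial volume, from the segmented
  blood-pool trace in the image pipeline.
* **SSD region**: whole overlap by default; a cardiac ROI mask is a
  parameter, not a default.
* **Surface distance** is one-directional (computed → original), matching
  the quoted usage of the tuning criterion.
* **Processing order** for propagation starts at the minimum-SSD frame and
  proceeds cyclically; ties at the SSD threshold are poorly similar (strict
  inequality).
* **Slice-shift artifacts** are off by default and out of scope for the
  bundled experiments.

# Known limitations

No geodesic momentum transport (momenta constant along flows); no varifold
or normal-cycle metrics (orientation-inconsistent inputs would need them);
vertex-clustering decimation does not guarantee manifoldness (adequate for
the correspondence-free currents term, not for enclosed-volume computation —
volumes are always taken on the undecimated or capped meshes); exact U tests
are limited to n + m <= 20; the demons engine assumes a shared field of view
after resampling and is not contrast-invariant (SSD metric).
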