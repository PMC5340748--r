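# lvssa — statistical shape and motion analysis of the left ventricle

`lvssa` is an R implementation of an end-to-end framework for
three-dimensional analysis of left-ventricular (LV) shape and motion from
cardiac MR data. Clinical protocols acquire a single high-resolution 3D
whole-heart (WH) volume at mid-diastole plus a short-axis cine stack
(~20 phases, coarse through-plane sampling); neither alone supports 3D
motion analysis. The framework combines them:

1. **Motion propagation** — per cardiac phase, cine slices are assembled
   into a 3D frame, scored against the WH volume by the sum of squared
   intensity differences (SSD), and classified against the threshold
   `SSD_th = 0.5 * SSD_max` (strictly below = *highly similar*). A synthetic
   high-resolution volume is generated per phase by demons non-rigid
   registration — directly from the WH volume for highly similar frames,
   chained from the previous synthetic frame otherwise — and the WH
   segmentation is carried to every phase.
2. **Anatomical models** — each subject is summarized by a template mesh
   plus per-frame deformations parameterized by momenta `beta_k` on a
   control-point grid, estimated under the currents surface metric:

       ||A - B||^2 = S(A,A) + S(B,B) - 2 S(A,B),
       S(P,Q) = sum_ij exp(-|c_i - c_j|^2 / lambda_w^2) (n_i . n_j)

   with deformations integrated from
   `dx/dt = sum_k exp(-|x - c_k|^2 / lambda_v^2) beta_k`. The kernel widths
   `lambda_w` (shape resolution) and `lambda_v` (deformation stiffness),
   default 13 mm and 23 mm, are tunable by grid search on the
   template-to-shape surface distance.
3. **Shape analysis** — subject models are scaled by endocardial volume,
   co-aligned by generalized Procrustes analysis, and PCA is run on the
   momenta of end-diastolic and end-systolic atlases; subjects are
   summarized by shape vectors and modes visualized at ±2σ.
4. **Motion analysis** — each subject's deformations are replayed on a
   population-average **SuperTemplate**, removing subject-specific anatomy;
   PCA over the pooled `n_subjects x n_frames` shapes yields motion modes
   and per-subject motion-vector time traces.
5. **Group statistics** — per-mode group medians/IQRs, boxplot data, and an
   exact (full-enumeration) two-sided Mann–Whitney U test suited to very
   small groups.

Because no image data ships with the package, a synthetic LV cohort
generator (`synthetic_cohort_spec()`, `generate_cohort()`) provides
phantom anatomy, cyclic motion with known ejection fraction and regional
hypokinesia, rasterized label/intensity volumes, cine stacks, and full
ground truth, so the entire pipeline is testable offline.

## Worked example

Group statistics on the bundled example cohort (four repaired
aortic-stenosis patients vs four controls, first four ED shape modes):

```r
library(lvssa)
ed <- example_shape_vectors("ED")
median_iqr(ed$mode_1[ed$group == "control"])
#> $median
#> [1] -128
#> $q1
#> [1] -248.5
#> $q3
#> [1] -111.5
#> $iqr
#> [1] 137
group_comparison(ed, ed$group)
#>     mode group_a group_b  U         p
#> 1 mode_1 control      AS  4 0.3428571
#> 2 mode_2 control      AS 13 0.2000000
#> 3 mode_3 control      AS 12 0.3142857
#> 4 mode_4 control      AS  7 0.8857143
```

The control median of −128 and IQR of 137 for mode 1 summarize how tightly
the healthy subjects cluster at the negative extreme of the dominant ED
shape mode; every exact p-value is above 0.05 — at four subjects per group
the smallest attainable two-sided p is 2/70 ≈ 0.029, so shape alone does not
separate the groups.

A reduced-resolution end-to-end run on a synthetic 2+2 cohort
(4 mm voxels, 10 frames; about 10 minutes on one CPU):

```r
res <- run_pipeline(list(out_dir = "run", seed = 1))
round(100 * res$motion$pca$variance_fraction[1], 1)
#> [1] 65.9
```

Motion mode 1 — the global contraction/expansion cycle — dominates the
pooled motion variance; per-subject traces are in `res$motion$traces` and
`run/motion_traces.csv`, and the recovered deformations reproduce the
generator's ground truth (segmented blood-pool volume traces correlate with
the true traces at r > 0.98 in this configuration).

A command-line front end is installed at `inst/cli/lvssa`
(`lvssa {synth,propagate,atlas,stats,all}`).

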