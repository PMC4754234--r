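# striatr

Automated quantification of dopamine-transporter (DaT) SPECT brain volumes
for parkinsonian-syndrome workups: who has reduced, deformed striatal
uptake, how severe is it, and does it track the motor exam?

On a normal DaT scan the striatum is a bright comma over a dim brain; with
dopaminergic degeneration it fades and collapses toward a dot, usually
asymmetrically. Conventional semi-quantitative reading draws manual regions
of interest and reports a specific binding ratio — operator-dependent, and
blind to shape. `striatr` replaces that with a fully automated pipeline:

1. **Rigid spatial normalization** of every volume to a symmetric
   control-group template (6-DOF, normalized correlation, multi-resolution).
2. **Intensity normalization** by alpha-stable histogram matching: each
   image's in-brain histogram is fitted with a stable law (McCulloch
   quantile estimator) and mapped by `Y = a_i X - b_i`, with
   `a_i = γ*/γ_i`, `b_i = a_i μ_i - μ*`, onto the pooled dispersion γ* and
   location μ*.
3. **Unsupervised striatal segmentation**: per hemisphere, a two-component
   Gaussian mixture over 4-D voxel vectors (intensity, x, y, z) fitted by
   EM; the high-uptake component's largest 26-connected part is the
   striatal mask.
4. **Ellipsoid shape modelling**: `(X-U)ᵀ Rᵀ D R (X-U) = 1` fitted to the
   mask surface by minimizing summed squared geometric point-to-surface
   distances.
5. **Features, classification, correlation** — per side:
   * MEU, mean ellipsoid uptake: mean normalized intensity in the fitted
     ellipsoid;
   * DI, dysmorphic index: `1 - Π_i |E_i^S · E_i^T|` over rank-paired unit
     eigenvectors of the subject and template ellipsoids (0 = normal
     orientation, 1 = maximal dysmorphism);
   * SMU, shape-modulated uptake: `MEU · (1 - DI)`;
   * SBR, specific binding ratio: `(C_str - C_occ)/C_occ` against an
     automated occipital reference;

   then a leave-one-out linear SVM on configurable feature sets, and
   Spearman/linear/exponential correlation of SMU with motor scores.

A digital phantom generator (`generate_phantom()`, `generate_cohort()`)
produces DaT-like volumes — two comma-shaped striata over a brain
background, Poisson count noise, Gaussian point-spread blur — with exact
ground truth (masks, orientations, programmed uptake) and linked synthetic
motor scores, so the entire pipeline is testable without patient data.

## Worked example

```r
library(striatr)

coh <- generate_cohort(n_pd = 4, n_hc = 3, seed = 5)
manifest <- tibble::tibble(subject_id = coh$subject_id, group = coh$group,
                           volume = coh$volume, updrs_me = coh$updrs_me,
                           updrs_me_left = coh$updrs_me_left,
                           updrs_me_right = coh$updrs_me_right)
rep <- run_pipeline(list(output_dir = tempdir(), manifest = manifest))

dplyr::select(rep$features, subject_id, group, meu_l, di_l, smu_l, smu_r)
#> # A tibble: 7 × 6
#>   subject_id group meu_l    di_l     smu_l    smu_r
#> 1 S003       PD    1.57  0.238   1.20      1.84
#> 2 S001       PD    0.989 1.000   0.0000870 0.000111
#> 3 S004       PD    1.52  0.292   1.07      1.85
#> 4 S007       HC    2.20  0.00145 2.20      2.20
#> 5 S002       PD    1.73  0.166   1.44      2.01
#> 6 S006       HC    2.20  0.00118 2.19      2.23
#> 7 S005       HC    2.29  0.00270 2.28      2.24

rep$classification
#> <classification_report> linear SVM, leave-one-out CV
#>   correct rate 100.00%  AUC 1.0000  sensitivity 100.00%  specificity 100.00%  (4 PD / 3 HC)
```

Controls sit near MEU ≈ 2.2 with DI below 0.003 (their striata match the
template's orientation); patients lose uptake and gain dysmorphism in
proportion to their programmed damage — subject S001's severely damaged
left striatum (dot-shaped, rotated) collapses to SMU ≈ 0. The SVM on
`[SMU_left, SMU_right]` separates the groups perfectly under leave-one-out
cross-validation. `plot_smu_space(rep$features)`,
`autoplot(rep$classification)` and `autoplot(rep$correlations$mean_smu)`
draw the SMU plane, the decision values and the severity fits;
`tidy()`/`glance()` return the tabular versions.

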