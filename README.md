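# condylovol

Longitudinal CBCT volumetry of the mandibular condyle in temporomandibular
joint (TMJ) osteoarthritis.

Degenerative joint disease resorbs bone from the condylar head (mainly the
anterior-superior joint surface) while depositing new bone around the
resorption site, so the net volume change between two scans understates the
turnover. Given pre- and post-treatment CBCT volumes of one joint,
`condylovol` segments bone by maximum-entropy (Kapur) thresholding — with
the pre-treatment threshold reused at follow-up so both timepoints are
segmented identically — isolates the mandible, rigidly registers the
follow-up scan to the pre-treatment grid, crops a common condylar-head
volume of interest, and decomposes the change by voxel overlap:

```
Vpre  = overlap + dV-          dV- : net decrease — bone resorption
Vpost = overlap + dV+          dV+ : net increase — bone deposition
dV    = Vpost - Vpre = dV+ - dV-   (exactly, by voxel counting)
```

A condylar-neck/ramus *validation* region directly below the head VOI, where
true change is negligible, quantifies residual segmentation/registration
error for every pair. The package also ships a truth-labelled synthetic
condyle phantom generator, a cohort simulator with the study's
erosion/pain/clinical-factor structure, and the staged nonparametric cohort
statistics (Mann-Whitney with exact enumeration for small groups,
Kruskal-Wallis, Spearman, multiple linear regression), with tibble outputs,
`tidy()`/`glance()` methods and `autoplot()` figures. It is intended for
researchers quantifying longitudinal condylar bone change and for validating
such pipelines on synthetic ground truth.

## Worked example

Measure a synthetic joint with a known pose difference, blur and noise:

```r
library(condylovol)

spec <- phantom_spec(pose_offset = c(3, 0, 0, 1.5, 0, 0),  # deg, mm
                     blur_sigma = 0.3, noise_sigma = 45, seed = 42)
pair <- make_phantom_pair(spec)
rec <- run_pair(pair$pre, pair$post, dT_months = 14, config = pipeline_config())
dplyr::select(rec, Vpre, Vpost, overlap, dV, dV_minus, dV_plus,
              validation_delta, validation_total)
#> # A tibble: 1 x 8
#>    Vpre Vpost overlap    dV dV_minus dV_plus validation_delta validation_total
#>   <int> <int>   <int> <int>    <int>   <int>            <int>            <int>
#> 1 55920 55931   55436    11      484     495              105            19404
```

The head lost 484 voxels of bone and gained 495 elsewhere, so the *net*
change (`dV = 11` voxels) is tiny although turnover is not — exactly the
situation the decomposition exists for. The validation region disagrees by
105 of 19404 voxels (0.5%), the built-in accuracy check for the
segmentation-plus-registration chain. (`rec` also carries the threshold, the
recovered pose magnitude, and mm^3 equivalents of every count.)

Simulate a cohort with the reported group structure and run the staged
analysis:

```r
co <- make_cohort_table(cohort_spec(seed = 1))   # 132 condyles, 66 patients
rep <- run_analysis_plan(co)
dplyr::select(tidy(rep)[1:6, ], stage, factor, outcome, n_yes, n_no, p.value)
#> # A tibble: 6 x 6
#>   stage  factor  outcome  n_yes  n_no  p.value
#> 1 stage1 erosion dV          90    42 4.04e- 3
#> 2 stage1 erosion dV_minus    90    42 5.39e-19
#> 3 stage1 erosion dV_plus     90    42 2.92e- 5
#> 4 stage2 pain    dV          65    25 6.52e- 3
#> 5 stage2 pain    dV_minus    65    25 8.76e- 3
#> 6 stage2 pain    dV_plus     65    25 2.27e- 1
```

Stage 1 compares eroded vs non-eroded condyles, stage 2 painful vs pain-free
joints among the eroded ones, stage 3 (not shown) each clinical factor after
excluding patients with bilateral erosion-and-pain, and stage 4 is the
Spearman matrix on that analysis set. p-values are per-test at 0.05 with no
multiplicity correction, matching the study design; the report records how
many tests ran.

See the methods vignette (`vignettes/condylar-volumetry-methods.Rmd`) for
the model, the registration recipe, the phantom's anti-aliased digitization,
and a quantified limitation of threshold-level placement on lesion-edge
measurement.

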