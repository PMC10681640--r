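# iimkit

Semi-quantitative analysis of routine clinical T1-weighted and FLAIR MR
images for dominantly inherited Alzheimer disease cohorts.

T1w and FLAIR voxel intensities sit on an arbitrary scale that differs
between participants, acquisition protocols and scanners, which normally
rules out comparing intensity values across sessions. `iimkit` removes that
scale by *bispectral* normalization: the joint (T1w, FLAIR) intensity
distribution of each session is summarized as a bivariate histogram and
affine-registered, in intensity space, to a normative reference histogram.
The recovered transform

&nbsp;&nbsp;&nbsp;&nbsp; v′ = L·v + b,  v = (T1w, FLAIR),  L ∈ ℝ²ˣ², b ∈ ℝ²

is applied jointly to both images. From the normalized images the package
extracts four regional **image-intensity metrics** (IIMs) over a grey-matter
parcellation (68 cortical + 12 subcortical regions): T1-μ, T1-σ, FLAIR-μ and
FLAIR-σ (population-σ convention). Downstream it provides:

- **Trajectory models.** Per region and metric, linear mixed-effects models
  of the IIM against estimated years to symptom onset (EYO = age − predicted
  onset age; negative while presymptomatic) and mutation-carrier status,
  with the regional thickness/volume covariate absorbing concurrent atrophy:

  - M1 (baseline): `IIM ~ EYO × Mutation + thickness/volume + (1 | family)`
  - M2 (longitudinal): `IIM ~ Time × BaselineEYO × Mutation + Time ×
    thickness/volume + (1 | family) + (1 | subject)`
  - M3/M4 add the corresponding `EYO² × Mutation` terms, compared against
    M1/M2 by likelihood-ratio test on ML fits.

  Interaction p-values are Benjamini–Hochberg-adjusted across regions within
  each metric, and region maps are exported as signed −log₁₀ p scores
  (sign of the interaction coefficient).

- **PET associations.** Partial correlations between regional amyloid/tau
  PET SUVR and each IIM, controlling for regional morphometry, in all
  mutation carriers and separately in symptomatic (global CDR > 0) carriers.

- **Cohort utilities.** EYO computation with the standard onset-age
  precedence (own onset if symptomatic → mutation mean onset → parental
  onset), exclusion of Dutch *APP* E693Q families (blood products distort MR
  signal), and PET-to-MR session matching within tracer-specific windows
  (amyloid 365 d, tau 548 d).

- **Synthetic data.** Because the clinical data such analyses target are
  access-restricted, the package ships a first-class, seeded generator
  layer — cohorts with family structure, paired T1w/FLAIR phantoms with a
  CSF/WM/GM mixture and planted scanner affines, regional morphometry with
  atrophy, and amyloid-early/tau-late SUVR tables — carrying exactly the
  statistical structure the analysis assumes, so every stage is testable
  end to end with known ground truth.

## Worked example

Build a reference atlas from healthy-population intensity samples, simulate
a mutation carrier 5 years before expected onset scanned on a scanner with
an arbitrary intensity scale, normalize the session, and extract regional
metrics (regions 1–2 carry planted disease effects):

```r
library(iimkit)

spec <- phantom_spec(grid_shape = c(24, 24, 24), n_regions = 8)
ref_hists <- lapply(1:4, function(i)
  histogram_from_samples(sample_reference_mixture(30000, spec, seed = i)))
atlas <- build_reference(ref_hists, n_iterations = 2)

scanner <- random_scanner_affine(101)
ph <- simulate_phantom_pair(list(eyo = -5, mutation_status = "carrier"),
                            spec, effect_model(affected_regions = 1:2),
                            seed = 11, scanner_affine = scanner)
norm <- normalize_session(ph$t1, ph$flair, ph$mask, atlas, session_id = "demo")
norm$transform
#> <iaffine2>  v' = L v + b
#>   L = [  1.0156  -0.0430;   0.0896   0.8840]
#>   b = [  10.245    7.987]
round(norm$qc$similarity, 4)
#> [1] 0.9826

iim <- extract_iim(norm$t1, norm$flair, ph$labels, spec$region_table,
                   session_id = "demo")
head(iim[, c("region_id", "n_voxels", "t1_mu", "t1_sigma",
             "flair_mu", "flair_sigma")], 4)
#>   region_id n_voxels    t1_mu  t1_sigma flair_mu flair_sigma
#> 1         1      600 96.21665 14.272661 124.5412    15.64480
#> 2         2      600 97.51808 14.459025 120.0685    15.84195
#> 3         3      600 98.13651  9.988032 136.6752    12.09338
#> 4         4      600 98.61713  9.422684 130.2996    11.47541
```

The recovered transform is the inverse of the planted scanner distortion
(similarity is the normalized histogram correlation at the optimum). The
affected regions 1–2 show the planted signature at EYO −5: raised T1-σ and
FLAIR-σ (≈14–16 versus ≈9–12 in unaffected regions) and depressed FLAIR-μ —
and the normalized means agree with the true pre-scanner means (123.4 and
118.8 for regions 1–2) to within about 1%.

EYO follows the onset-age precedence rule:

```r
compute_eyo(40, symptomatic = TRUE, own_onset_age = 45)           # -5
compute_eyo(50, symptomatic = FALSE, mutation_mean_onset_age = 45) # 5
```

`run_pipeline(pipeline_config(out_dir = "run"))` executes the whole chain —
simulate → normalize → metrics → models → PET associations — and writes
TSV tables, QC records and a manifest into the output directory.

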