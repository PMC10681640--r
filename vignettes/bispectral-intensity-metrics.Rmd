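---
title: "Bispectral intensity normalization and intensity-metric trajectory models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bispectral intensity normalization and intensity-metric trajectory models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

T1-weighted and FLAIR images carry contrast that reflects tissue
microstructure, but their voxel values live on an arbitrary scale: two scans
of the same brain on different scanners (or the same scanner with different
settings) produce intensity distributions related, to good approximation, by
an affine change of scale in each channel plus cross-channel mixing. Any
analysis that compares intensity *values* across sessions must first remove
this nuisance transform.

`iimkit` does so in the joint intensity plane. Each session's in-mask
(T1w, FLAIR) voxel pairs are binned into a bivariate histogram; a 2-D affine
transform of intensity space, `v' = Lv + b`, is then estimated that maps
this histogram onto a normative reference histogram, and applied jointly to
both images. No spatial correspondence is involved — only distribution
shape. After normalization, the mean (μ) and population standard deviation
(σ) of T1w and FLAIR intensities within each of 80 grey-matter regions (68
cortical, 12 subcortical) become comparable across sessions; these four
image-intensity metrics (IIMs) are the package's measurement.

The scientific use of the metrics in a dominantly inherited Alzheimer
disease cohort is to track disease stage: signed estimated years to symptom
onset (EYO = age − predicted onset age, negative while presymptomatic)
orders participants along the disease trajectory, and the contrast of
interest is the interaction between EYO and mutation-carrier status — an
intensity abnormality that grows as carriers approach onset.

## The registration step

The registration cost and optimizer are deliberately simple and fully
documented, since they determine everything downstream:

- **Representation.** Histograms use 256 bins per axis over a fixed frame.
  The reference frame spans the 0.5–99.5 percentile range of the reference
  population's intensities; subject histograms are built on their own robust
  range and out-of-range voxels are clipped into edge bins, so histogram
  mass always equals the in-mask voxel count.
- **Cost.** Candidate transforms push the subject's nonzero histogram bins
  (bin centers weighted by counts) through the affine and re-bin them on
  the reference frame. Both sides are log-compressed (`log1p`) — otherwise
  the dominant WM/GM modes swamp the clinically informative tails —
  Gaussian-smoothed (σ = 2 bins), and compared by negative Pearson
  correlation, which is invariant to the mass rescaling a transform's
  Jacobian induces. Working at the bin-center level rather than on raw
  voxel samples is an exact summary up to within-bin quantization and keeps
  the cost of one evaluation bounded by the bin count rather than the voxel
  count.
- **Optimizer.** Derivative-free Nelder–Mead over the 6-parameter chart
  (two scales, two shears, two offsets around the identity), with a
  deterministic multi-start schedule: identity plus ±20 % axis-wise scale
  perturbations. The multi-start search runs on a 2× downsampled histogram
  (a coarse-to-fine pyramid; the parameter chart is in intensity units, so
  parameters transfer across resolutions unchanged), stops early once the
  normalized correlation reaches 0.99, and the incumbent is then refined
  and simplex-restart-polished at full resolution. Convergence tolerance is
  1e-6 on the cost with a 2000-evaluation budget per start; results are
  flagged non-converged — never silently accepted — if the optimizer fails
  or the final similarity is below 0.2.
- **Reference construction.** The normative atlas is built by three
  register-and-average iterations: initialize with the normalized mean
  histogram, then repeatedly register every member to the current
  reference, average the transformed histograms and renormalize. Members
  whose registration fails are dropped with a warning and recorded.

Under planted-affine simulations (random scanner transforms with scales
0.75–1.35, small shears, offsets ±20 intensity units) this recovers the
inverse transform with an RMSE of about 4 % of parameter scale, and brings
the coefficient of variation of regional means across five simulated
scanners from ~15–20 % down to below 0.5 %. Those two numbers — recomputed
by `scripts/acceptance.R` on every run — are the package's operational
definition of "scanner effect removed".

## The synthetic-data layer

Real data for this analysis are access-restricted, so the generators are
first-class, tested code rather than fixtures:

- **Cohort.** Families of 1–3 siblings share a mutation with a mean onset
  age ~N(47, 5²) years; carriers (configurable fraction, default 0.6)
  develop symptoms at their own onset age = mutation mean + N(0, 3²), after
  which CDR climbs in steps; baseline EYO is uniform on [−25, +10]; visits
  are biennial, annual within 5 years of expected onset; a 3.7 % Dutch
  *APP* E693Q family fraction exercises the exclusion filter; 5 % of
  participants carry mutation-independent mild impairment (persistent
  CDR 0.5).
- **Phantoms.** A rectangular brain mask holds CSF, WM and GM slabs; the GM
  slab is tiled by the labelled regions. Each compartment draws from a
  bivariate Gaussian (within-tissue T1–FLAIR correlation 0.25); the
  three-mode joint histogram this produces is the minimal structure under
  which 2-D histogram registration is identifiable. Region blocks are
  axis-aligned because anatomical realism is irrelevant to the
  correctness being tested, while speed and analytic ground truth are not.
- **Disease effects.** In affected regions (default: the bilateral
  supramarginal, right postcentral and right superior temporal cortices and
  the bilateral caudate, putamen, thalamus and amygdala), carriers' FLAIR-μ
  falls and T1-σ/FLAIR-σ rise with EYO. Two trend shapes exist: a ramp
  switching on at EYO −15 (used for phantoms, where far-presymptomatic
  carriers should look normal) and an exactly linear-in-EYO form (the
  generating model for estimator-calibration simulations, optionally with a
  quadratic term). No published effect sizes exist for these changes; the
  defaults — FLAIR-μ slope −0.8 intensity units/EYO-year, σ slope +0.4,
  residual SD 6, family SD 4, subject SD 3 — were chosen once for
  statistical detectability at cohort sizes of a few hundred and are
  otherwise arbitrary. The quadratic coefficient used by
  quadratic-generator simulations (0.06 units/year²) was set by a power
  analysis against the empirical standard error of the quadratic
  interaction at n = 517.
- **PET and morphometry.** Carrier amyloid SUVR rises sigmoidally from
  about EYO −20 in all cortical regions; tau rises late (from about EYO −5)
  and concentrated in affected regions; non-carriers are flat at SUVR ≈ 1.
  A latent pathology score per subject × affected region (deterministic
  from the seed via per-subject hashed substreams) loads on tau (0.3
  SUVR/unit), weakly on amyloid (0.08), and on the intensity metrics, so
  partial-correlation recovery — including the tau-stronger-than-amyloid
  ordering in symptomatic carriers — is true by construction. Morphometry
  loses thickness/volume at a fractional `atrophy_rate` per EYO-year in
  affected carrier regions from EYO −8. Optional couplings route both SUVR
  and IIMs through morphometry alone, the configuration used to test that
  the covariate genuinely removes atrophy-driven confounding.

What passing these simulations does **not** show: robustness to spatially
varying bias fields, misregistration between T1 and FLAIR, non-Gaussian
tissue mixtures, partial-volume effects at region boundaries, or real
scanner non-linearities. The pipeline assumes brain extraction, bias-field
correction and T1–FLAIR co-registration are done upstream, and the
phantoms honour those assumptions by construction.

## Trajectory models

Per region and metric, with the regional thickness (cortical) or volume
(subcortical) covariate:

- M1 (baseline sessions): `IIM ~ EYO × Mutation + covariate + (1 | family)`
- M2 (all sessions): `IIM ~ Time × BaselineEYO × Mutation + Time ×
  covariate + (1 | family) + (1 | subject)`, with Time = years since the
  subject's first MR and BaselineEYO the EYO at that scan
- M3/M4: the quadratic extensions adding `EYO² × Mutation` (respectively
  `Time × BaselineEYO² × Mutation`)

EYO is already centred at expected onset by definition, so the quadratic
term is the plain square. Estimation choices that were genuinely open:

- **REML for coefficients, ML for likelihood ratios.** Coefficient
  estimates, Satterthwaite degrees of freedom and p-values come from the
  REML fit; each fit also stores an ML refit's log-likelihood, from which
  `compare_linear_quadratic()` forms the nested LRT — the same convention
  `anova()` applies to REML `lmer` fits. The choice was made on calibration
  grounds: in a 2000-replicate null study at family ICC ≈ 0.26, the
  ML-based Wald test rejected at 0.063 while REML rejected at 0.055–0.060;
  the LRT path is unaffected because it always uses the ML likelihoods.
- **Singular fits are not failures.** A family or subject variance
  estimated at exactly zero is a boundary estimate, common under weak
  clustering, and the fixed-effect inference remains valid; such fits are
  flagged (`singular`) but kept in the FDR family. Only optimizer failure
  or an error excludes a region, with the exclusion logged and reported.
- **FDR families.** BH adjustment runs across the 80 regions separately
  within each metric (and tracer, for the PET associations), matching how
  results are reported per metric panel.
- **The quadratic decision rule.** A region is declared to have a quadratic
  trajectory only when (a) the linear model's interaction is
  FDR-significant, (b) the FDR-adjusted ANOVA (LRT) p is below α = 0.05,
  and (c) the quadratic-by-mutation coefficient itself has raw p < 0.05.
  Whether (c) should use raw or adjusted p is ambiguous in the field's
  practice; raw was chosen and is noted here deliberately.
- **Region maps.** Exported scores are −log₁₀(p) × sign(β) for the
  interaction term, with p floored at 1e-300.

Calibration, recomputed by the acceptance script at n = 517 baseline
participants (the printed baseline size of the motivating cohort): type-I
error of the EYO×Mutation test 0.042–0.052 over 500 null replicates;
planted slopes recovered within 2 SE in ≥ 95 % of replicates; the quadratic
rule fires in ~100 % of quadratic-generator replicates and ≤ 6 % of
linear-generator replicates.

## PET partial correlations

`partial_correlation()` computes the correlation of two variables after
linearly removing covariates from both, via the Schur complement of the
covariate block of the joint correlation matrix — algebraically equal to
correlating the two regression residual vectors, but well defined even when
x and y are perfectly collinear. p-values use
`t = r·sqrt((n − 2 − k)/(1 − r²))` on `n − 2 − k` df, two-sided. The
implementation is verified against an explicit residual-regression oracle
to below 1e-10 on 1000 random datasets, and against the closed-form
three-variable case (all pairwise r = 0.5 → partial r = 1/3) to machine
precision.

`run_associations()` takes PET scans already matched to MR sessions,
restricts to carriers (optionally symptomatic carriers, CDR > 0 at the
matched MR visit), keeps one PET scan per subject (the earliest, so rows
are independent across subjects — the deduplication convention is a
documented choice), and adjusts p-values within each metric × tracer
family. Regions with fewer than `min_n` complete pairs are returned with
missing statistics rather than dropped silently.

## Numerical and interface conventions

- σ is the population standard deviation (divide by n); documented and
  fixed so oracle tests are exact.
- Regions with fewer than `min_voxels = 10` usable voxels are flagged
  missing, and missingness propagates to the models rather than becoming
  zeros.
- Out-of-mask voxels carry NA (NaN in floating-point NIfTI output) after
  normalization; they can never contaminate regional statistics.
- Dates are ISO-8601; date arithmetic is in whole days with
  years = days/365.25. PET matching windows default to 365 days (amyloid)
  and 548 days (tau), each PET scan matching its nearest in-window MR
  session with ties broken toward the earlier MR date.
- Participants of unknown mutation status are supported by the EYO
  precedence rule (parental-onset tier) but excluded from model fitting,
  which dichotomizes carrier/non-carrier.
- Visits with missing CDR surface as errors in the symptomatic-subset
  logic rather than being imputed.
- All generators derive per-subject substreams by hashing the subject id
  with the seed, so adding a subject never reshuffles another subject's
  draws.

## Problem sizes

The shipped test-suite and acceptance-script simulations use: 24³–48³
phantom grids (8–80 regions; the block layout puts ≥ 500 voxels in each
region at 48³), 25 000–40 000-sample reference histograms at 256² bins,
cohorts of 120–517 participants, 500 null replicates for type-I
calibration, 100 replicates each for recovery/power, and 1000 random cases
for the numerical oracles. These sizes were chosen so that every
Monte-Carlo bound tested has comfortable sampling margin while a full run
remains a desk-scale computation.

## Known limitations

- The affine intensity model cannot correct non-linear scanner effects or
  spatially varying bias; it assumes those were handled upstream.
- Histogram registration needs overlapping intensity supports and a
  multi-modal joint distribution; a single-tissue image would leave the
  transform poorly identified (the similarity floor flags such cases).
- The trajectory models are linear/quadratic in EYO by design; spline or
  nonlinear-in-parameters trajectories are out of scope.
- Synthetic phantoms validate the estimation machinery, not biological
  claims: effect sizes are constructed, and the tau/amyloid orderings the
  tests assert are planted properties of the generator.
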