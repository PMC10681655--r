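---
title: "Measuring the principal FC gradient: models, reliability, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the principal FC gradient: models, reliability, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement pipeline

`fcgrad` implements a complete analysis chain for the principal functional
connectivity (FC) gradient of the cerebral cortex and its measurement
properties:

1. **Cleaning** (`clean_timeseries()`): nuisance regression, task-signal
   removal with a finite impulse response (FIR) model, temporal filtering,
   and motion censoring are applied in a *single least-squares projection*.
   The filter is realized as regression on sine/cosine columns at the
   scan's discrete frequencies outside the passband, evaluated at the kept
   frame times. Unlike a recursive filter, this projection remains exact
   when frames are censored, and the whole cleaning step is idempotent.
2. **FC assembly** (`assemble_modality()`, `compute_fc()`): resting-state
   FC (rsFC) uses rest scans only; general FC (GFC) pools rest and task
   scans after FIR removal of the evoked signal. Fixed data amounts are
   extracted with an equal-allocation rule: the target frame count is
   split evenly over scans, each contributing its earliest kept frames,
   with any shortfall filled by seeded uniform draws from the remaining
   pool. Edges are Pearson correlations.
3. **Gradients** (`sparsify_rows()`, `affinity_normalized_angle()`,
   `diffusion_embedding()`): per parcel, only the strongest 10% of
   connections are retained (values kept, ties broken toward the lower
   parcel index); profile similarity is the normalized angle
   `1 - arccos(cos_sim)/pi`; the affinity is embedded by a diffusion map —
   eigendecomposition of the `alpha`-normalized random-walk operator
   through its symmetric conjugate, with the trivial constant mode
   dropped and component `k` scaled by `lambda_k / (1 - lambda_k)` at
   diffusion time 0.
4. **Alignment** (`build_group_template()`, `procrustes_align()`): the
   group template is the embedding of the cohort's Fisher-z mean FC, with
   its principal axis oriented so heteromodal parcels sit above unimodal
   ones; individuals are aligned to it by pure orthogonal Procrustes
   rotation (no scaling, no centering), inheriting the orientation.
5. **Range** (`gradient_range()`): mean principal-gradient value over
   heteromodal parcels minus the mean over unimodal parcels — the
   functional "distance" between the sensory and association poles of the
   hierarchy.
6. **Reliability** (`icc_3_1()` and relatives): test–retest reliability is
   ICC(3,1), the two-way mixed-effects, single-measurement, consistency
   intraclass correlation `(BMS - EMS) / (BMS + (k-1) EMS)`. Edge-wise
   ICCs are computed on Fisher-z correlations and averaged per parcel;
   thresholded edge-wise ICCs restrict each parcel's average to the
   strongest 10% of its edges, with the edge set fixed once from the
   grand-mean matrix so that every subject and session shares it.
7. **Associations** (`fit_standardized_ols()`, `bh_fdr()`,
   `regional_association_map()`): regional gradient values and the range
   are regressed on a behavior measure with sex and motion covariates;
   continuous variables are z-scored so coefficients are standardized
   betas; parcel-wise p-values are corrected by Benjamini–Hochberg FDR
   over the parcels, while the range is its own single test outside that
   family.

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| `density` | 0.10 | fraction of strongest connections kept per parcel row |
| `n_components` | 10 | embedding components retained and aligned |
| `alpha` | 0.5 | anisotropic normalization (density-corrected diffusion) |
| `diffusion_time` | 0 | selects the `lambda/(1-lambda)` multi-scale weighting |
| `band` | (0.008, —) Hz | high-pass edge; set an upper edge for band-pass |
| `fir_window_seconds` | 24 | modeled post-onset response window |
| `fdr_q` | 0.05 | FDR threshold over parcels |

The embedding defaults (normalized-angle kernel, `alpha = 0.5`,
`diffusion_time = 0`, 10 components, 10% density) follow the established
defaults of the gradient-mapping literature and are all exposed as
arguments. The variance explained by a component is its eigenvalue
divided by the sum of the retained non-trivial positive eigenvalues, so
the reported proportions always sum to 1 over the retained set; other
conventions (e.g., dividing by the full spectrum) would give smaller
numbers, and comparisons across software should check this convention.
The FIR window default of 24 s covers the bulk of the canonical
hemodynamic response; responses outlasting the window leave a small
residue by design. Frame counts are converted from minutes as
`round(minutes * 60 / TR)`.

## Numerical choices

* Filtering under censoring is regression on the out-of-band spectral
  basis at the original frame times of the *kept* frames, so results
  depend on how many frames are censored, not on where they fall (for
  in-band signal).
* Sparsification ties at the cutoff are broken toward the lower parcel
  index, making the pipeline exactly reproducible across platforms.
* Fisher-z averaging clamps correlations at `1 - 1e-12` in magnitude so
  degenerate inputs stay finite.
* Eigenvector sign is fixed before alignment by making each column's
  largest-magnitude entry positive; after alignment, orientation is
  inherited from the template, never flipped per subject.
* Raw ICCs can be negative and are returned as computed; clip only for
  display. Degenerate (zero-variance) tables return 0 with a warning.
* Procrustes uses the SVD solution `R = U V'` of `X'T`; rank-deficient
  cross-products are aligned anyway with a warning.
* The subject covariance in the generator receives a diagonal jitter of
  `1e-8` only when round-off makes the smallest eigenvalue negative.

# The synthetic test–retest cohort

Real test–retest data of this kind are under managed access, so the
package ships a generator (`synthetic_config()`, `simulate_cohort()`)
that plants the structure the analysis is designed to detect and emulates
the statistical regime of a two-session, multi-scan cohort. Every stage
of the pipeline can therefore be validated against a known ground truth.

## Generative model

Each parcel `i` carries a canonical position `g_i` on a single latent
hierarchy axis; unimodal parcels occupy the low end, heteromodal parcels
the high end. Positions are spaced as `sign(x) |x|^0.85` over a uniform
grid `x` in `[-1, 1]` plus jitter (sd 0.005): slightly denser near the
two poles, emulating how cortical parcels crowd the sensory and
association anchors. A subject's session positions are

    h = g + (delta0 / a_s) * u_s + e_sess

* `u_s` is a fixed per-subject unit-normal vector — stable idiosyncratic
  topography, the *trait* that makes individuals identifiable across
  sessions (`disorder_scale` delta0, default 0.12).
* `e_sess` is session-specific *state* noise with per-parcel sd
  `state_sd * (1 + state_flexibility * (1 - |g_i|/max|g|))` (defaults
  0.05 and 2): the mid-hierarchy transition zone affiliates flexibly
  across sessions while the anchors are stable, which also reproduces the
  empirically low test–retest reliability of mid-gradient parcels.
* `a_s = 1 - kappa_age z(age) + kappa_cog z(cognition) + N(0, trait_sd^2)`
  (truncated at 0.1) is the subject's hierarchy-coherence scale: aging
  raises latent disorder (dedifferentiation), cognition lowers it.

The parcel covariance is the Gaussian latent-distance kernel
`Sigma_ij = exp(-(h_i - h_j)^2 / (2 l^2))` with `latent_length_scale`
l = 0.35, and scan rows are i.i.d. draws from `N(0, Sigma)` plus white
measurement noise (`measurement_noise_sd` 1.25). Task scans add a
condition-locked boxcar convolved with a double-gamma response (amplitude
`0.5 * measurement_noise_sd` on a fixed random 20% of parcels), with the
matching event table attached, so the FIR step has real work to do.
Censoring marks a random 5% of frames by default. All randomness derives
from one master seed through labeled child streams
(`derive_seed()`), so adding subjects never perturbs existing ones.

## Why these defaults

* **Length scale 0.35** (about one-sixth of the hierarchy span): distant
  parcel pairs are then effectively uncorrelated, as in real connectomes
  where most edges are weak. This is what makes the *unthresholded*
  edge-wise mean ICC fall below the gradient's — averaging in the many
  noise-dominated dead edges — while the *thresholded* edge set remains
  competitive.
* **Measurement noise 1.25** (noise variance roughly 60% of the total):
  parcel-level BOLD is noise-dominated, and at this level FC-estimation
  error, which shrinks with scan length, is the binding constraint below
  about 20 minutes. Reliability therefore climbs with data amount, the
  regime the scan-length methodology is designed to expose. With
  optimistic noise the gradient hits its state-noise ceiling within a
  couple of minutes and scan length stops mattering.
* **Disorder acting through `a_s`**: the affinity chain (top-10% ranks,
  then a cosine-based kernel) is invariant to any rescaling of the latent
  positions, so amplitude-style couplings are invisible to the measured
  gradient. What the chain does respond to is the *coherence* of the
  anchor neighborhoods: scattering parcels off their canonical positions
  washes the extremes of the aligned gradient toward the center, reducing
  the range — and the discovery pattern this produces (positive aging
  betas in unimodal cortex, negative in heteromodal) is the planted
  contraction the association analysis should recover.
* **Transition-zone flexibility 2**: besides its empirical motivation,
  this concentrates behavioral effects at the anchors. Without it, the
  unit-norm constraint on eigenvectors pushes mid-gradient coordinates
  slightly outward whenever the extremes flatten, and those "shoulder"
  parcels dilute the sign consistency of the contraction map.

## What the generator does and does not emulate

It emulates: multi-scan two-session designs (rest + task), a planted
sensory-to-association axis generating the FC covariance, stable subject
topography versus session state (so fingerprinting and ICC behave
realistically), censoring, task-evoked contamination, and behavior
variables coupled to hierarchy coherence with sex and motion available as
covariates.

It does not emulate: hemodynamic nonlinearity, realistic motion-spike
spectra (censored positions are random), spatial autocorrelation beyond
the single latent axis, state-specific trait information (so GFC's
advantage over rsFC here comes from data quantity alone), scanner or site
effects, or voxel-level preprocessing. Passing tests on this cohort
therefore validate the *measurement machinery* — recovery, reliability
orderings, calibration, directional behavior effects — not the full
complexity of real fMRI.

# Validation strategy and problem sizes

The test suite validates each statistic against an independent
brute-force oracle (two-way ANOVA sums of squares for ICC(3,1); a dense
non-symmetric eigendecomposition for the diffusion map; definitional
re-implementations of sparsification, the normalized-angle kernel,
Benjamini–Hochberg, and the t statistics), and the pipeline end to end on
simulated cohorts: a 120-parcel, 24-subject, two-session cohort with two
400-frame rest scans and two 200-frame task scans per session at TR = 2 s
for recovery and reliability (template–truth Spearman correlation,
gradient versus edge-wise ICC orderings, a 2.5–20 minute scan-length
sweep), a 200-subject aging-coupled cohort and a 120-subject
cognition-coupled cohort for association recovery, and 2,000-replicate
nulls for type-I calibration. `scripts/acceptance.R` re-runs this battery
from scratch at any seed. These sizes keep the full battery within a few
minutes on one CPU while leaving the qualitative regime (many more edges
than subjects, reliability limited jointly by scan length and state
noise) intact.

# Design decisions on open points

* **Paired versus group comparisons**: two measures computed on the same
  parcels are compared with a paired t-test; unimodal versus heteromodal
  parcels with Welch's t-test.
* **Thresholded edge sets** are defined once from the grand-mean FC over
  all subjects and sessions, not per subject, so the per-edge ICC is
  well-defined (the same edge is compared across everyone).
* **Fixed-amount frame selection** takes the earliest frames of each scan
  deterministically and randomizes only the overflow; whether real
  fixed-amount selections should be contiguous is left open, and the seed
  of the random fill is always recorded.
* **Procrustes without scaling or centering**: scaling would erase
  contraction/expansion of the gradient range — precisely the signal of
  interest — so only rotations/reflections are allowed.
* **Gradient measures as outcomes** and behavior as predictor in the
  association models; with full standardization the betas are symmetric
  in this choice, but the orientation is kept consistent throughout.
* **Group-averaged gradient summaries** can be computed either from the
  template or by averaging aligned individual gradients; the package
  returns both objects so either summary can be formed explicitly, and
  they are not interchangeable numerically.

# Limitations

* The latent hierarchy is one-dimensional; secondary gradients in the
  synthetic data are noise modes, computed only to stabilize alignment.
* ICC point estimates at 24 subjects are noisy (individual parcel ICCs
  swing by ±0.1 across cohort draws); conclusions in the tests rest on
  parcel-averaged or ordered comparisons, which are stable.
* The gradient-range reliability of an uncoupled cohort is near zero by
  construction — without behavioral coupling the generator plants almost
  no between-subject variance in range — so range ICC is meaningfully
  assessed on coupled cohorts.
* Runtime scales with `n_subjects * n_timepoints * n_parcels^2` for
  simulation and `n_parcels^3` per embedding; the defaults run a full
  reliability analysis in well under a minute per cohort.
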