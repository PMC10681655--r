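# fcgrad

Tools for measuring the **principal functional connectivity (FC)
gradient** of the cerebral cortex — the dominant axis of a nonlinear
(diffusion map) embedding of the parcellated connectome, which orders
regions from unimodal sensory-motor cortex to heteromodal association
cortex — and for evaluating how well it can be measured: test–retest
reliability of regional gradient values, edge-wise FC, and the gradient
*range* (the functional distance between the sensory and association
poles), across modalities (resting-state FC vs general FC pooled over
rest and task) and scan lengths, plus mass-univariate associations of
gradient measures with behavior.

It is written for researchers working with parcellated fMRI time series
who want a dependency-light, fully reproducible implementation of this
analysis chain, together with a synthetic test–retest cohort generator
that plants a known cortical hierarchy so every stage can be validated
end to end without access-restricted data.

## The measures

For a parcellated connectome with Pearson FC matrix `R`:

1. keep each parcel's strongest 10% of connections (row-wise, values
   retained);
2. affinity `a_ij = 1 - arccos(cos_sim(row_i, row_j)) / pi`;
3. diffusion map embedding: eigendecomposition of
   `M = D_W^-1 W`, `W = D^-alpha A D^-alpha` (`alpha = 0.5`), component
   `k` scaled by `lambda_k / (1 - lambda_k)`;
4. Procrustes alignment (orthogonal, no scaling) of individual
   embeddings to a group template built from the cohort's Fisher-z mean
   FC;
5. gradient range = mean over heteromodal parcels − mean over unimodal
   parcels of the aligned principal component.

Test–retest reliability is **ICC(3,1)**,
`(BMS − EMS) / (BMS + (k−1) EMS)` from the two-way subject × session
ANOVA; edge-wise ICCs are computed on Fisher-z correlations and averaged
per parcel. Behavior associations are standardized OLS betas with sex
and motion covariates and Benjamini–Hochberg FDR over parcels.

Time-series cleaning (nuisance + FIR task-signal regression + temporal
filtering + censoring) happens in a single least-squares projection, so
task scans contribute "background" connectivity to general FC (GFC) and
filtering stays exact on censored data.

## Worked example

Simulate a small two-session cohort with a planted hierarchy, derive and
align gradients, and compare the reliability of gradient and edge-wise
measures:

```r
library(fcgrad)

cfg <- synthetic_config(n_subjects = 12, seed = 42)
cohort <- simulate_cohort(cfg)
cleaned <- lapply(cohort$scans, clean_timeseries)
by_subj <- split(cleaned, sapply(cleaned, `[[`, "subject_id"))
by_subj <- lapply(by_subj, function(x) split(x, sapply(x, `[[`, "session")))
partition <- partition_table(cohort$truth)

fcs_test <- sapply(names(by_subj), function(s)
  compute_fc(assemble_modality(by_subj[[s]]$test, "rsFC"), "rsFC", 25.3, s, "test"),
  simplify = FALSE)
template <- build_group_template(fcs_test, partition)
template
#> <gradient_set> 120 parcels x 10 components, alpha=0.5, t=0, aligned to group_template
#>   variance explained: 18.3% 16.9% 15.5% 12.9% 10.6% 8.5% 7.0% 4.5% 3.2% 2.6%

cor(template$coordinates[, 1], cohort$truth$true_gradient, method = "spearman")
#> [1] 0.949
```

The template's principal component explains the largest share of
connectome variance and recovers the planted sensory-to-association
ordering almost perfectly (Spearman 0.95). Reliability of regional
measures over the two sessions:

```r
fcs_retest <- sapply(names(by_subj), function(s)
  compute_fc(assemble_modality(by_subj[[s]]$retest, "rsFC"), "rsFC", 25.3, s, "retest"),
  simplify = FALSE)
grads_test   <- lapply(fcs_test,   derive_gradients, template = template)
grads_retest <- lapply(fcs_retest, derive_gradients, template = template)

icc_grad <- gradient_parcel_icc(grads_test, grads_retest)
icc_edge <- edgewise_parcel_icc(fcs_test, fcs_retest)
round(c(gradient = mean(icc_grad), edgewise = mean(icc_edge)), 3)
#> gradient edgewise
#>    0.377    0.299
compare_icc_paired(icc_grad, icc_edge)
#> <comparison_result> paired t = 3.958, p = 0.000129, n = 120, mean diff = 0.0786

gradient_range(grads_test[["sub001"]], partition)$value
#> [1] 0.0119
```

Regional gradient values are reliably more reliable than the average of
a parcel's edges (paired t = 3.96 over 120 parcels) — the gradient pools
information across the whole connectome row, while the edge-wise mean is
dragged down by the many weak, noise-dominated edges. At only 12
subjects and ~25 minutes of data the absolute ICC values are modest;
they rise with scan length (see `scan_length_sweep()`).

`run_pipeline(cohort_dir, out_dir)` chains the full analysis (cleaning →
rsFC/GFC → template → alignment → range → reliability → associations)
over a cohort directory written by `write_cohort()`, with JSON sidecars
recording configuration and seeds; `inst/cli/fcgrad.R` is a thin
command-line wrapper with `simulate` and `run` subcommands.

## Package layout

- `R/synthetic.R` — cohort generator with planted ground truth
- `R/connectivity.R` — cleaning, FIR regressors, data-amount assembly, FC
- `R/gradients.R` — sparsify / affinity / diffusion embedding / Procrustes / range
- `R/reliability.R` — ICC(3,1), parcel-wise reliability, comparisons, sweeps
- `R/associations.R` — standardized OLS, BH-FDR, regional maps
- `R/io.R` — delimited-text formats, manifests, pipeline orchestration
- `vignettes/fc-gradient-reliability.Rmd` — the model, parameter choices,
  and design decisions in detail
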