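# Shared simulated fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# Small cohort for unit tests: cheap but structurally complete.
small_cohort <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- synthetic_config(
      n_parcels = 40L, n_unimodal = 13L, n_subjects = 8L,
      scans = list(
        list(scan_label = "rest1", scan_class = "rest", n_timepoints = 150L),
        list(scan_label = "task1", scan_class = "task", n_timepoints = 120L)),
      seed = 301L)
    .fixture_env$small <- simulate_cohort(cfg)
  }
  .fixture_env$small
}

small_cleaned <- function() {
  if (is.null(.fixture_env$small_cleaned)) {
    .fixture_env$small_cleaned <-
      lapply(small_cohort()$scans, clean_timeseries)
  }
  .fixture_env$small_cleaned
}

# Study-scale cohort at the generator's default conditions (P = 120,
# N = 24, two sessions), used by the end-to-end acceptance checks.
study_cohort <- function() {
  if (is.null(.fixture_env$study)) {
    cfg <- synthetic_config(seed = 20260930L)
    .fixture_env$study <- simulate_cohort(cfg)
  }
  .fixture_env$study
}

study_cleaned_by_subject <- function() {
  if (is.null(.fixture_env$study_by_subj)) {
    cleaned <- lapply(study_cohort()$scans, clean_timeseries)
    .fixture_env$study_by_subj <- fcgrad:::split_scans(cleaned)
  }
  .fixture_env$study_by_subj
}

# Per-subject FC for one session/modality of the study cohort, cached.
study_fcs <- function(session, modality = "rsFC", minutes = "all") {
  key <- paste("fc", session, modality, minutes, sep = "_")
  if (is.null(.fixture_env[[key]])) {
    by_subj <- study_cleaned_by_subject()
    .fixture_env[[key]] <- setNames(lapply(names(by_subj), function(s) {
      ts <- assemble_modality(by_subj[[s]][[session]], modality, minutes,
                              seed = derive_seed(99, s, session, modality))
      compute_fc(ts, modality, NA, s, session)
    }), names(by_subj))
  }
  .fixture_env[[key]]
}

study_template <- function() {
  if (is.null(.fixture_env$template)) {
    .fixture_env$template <- build_group_template(
      study_fcs("test"), partition_table(study_cohort()$truth))
  }
  .fixture_env$template
}
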