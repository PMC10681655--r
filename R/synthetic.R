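#' Configuration for the synthetic test-retest cohort generator
#'
#' The generator plants a sensory-to-association hierarchy gradient `g` over
#' parcels and derives each subject's parcel covariance from a Gaussian
#' latent-distance kernel on the subject's session positions
#' `h = g + (delta0 / a_s) u_s + e`, where `u_s` is a stable per-subject
#' topography vector (trait), `e` is session state noise, and `a_s` is the
#' subject's hierarchy-coherence scale factor. The planted gradient is the
#' dominant smooth axis of FC variation — the structure the diffusion
#' embedding extracts — while the disorder term scatters each subject's
#' parcels off their canonical positions in a stable, subject-specific way:
#' aging lowers `a_s`, raising disorder and washing out the coherence of
#' the sensory/association anchors (dedifferentiation, contracting the
#' measured gradient range); cognition raises `a_s` (expansion).
#'
#' Defaults emulate a compact two-session multi-scan protocol: two rest scans
#' of 400 frames and two task scans of 200 frames at TR = 2 s per session
#' (about 27 min of rest and 13 min of task data per session before
#' censoring), 24 subjects, 120 parcels of which 38 are unimodal (the
#' roughly-one-third unimodal share of standard cortical partitions).
#'
#' @param n_parcels number of parcels P.
#' @param n_unimodal number of unimodal parcels (the rest are heteromodal).
#' @param n_subjects number of subjects.
#' @param scans list of scans acquired per subject per session; each element
#'   is a list with `scan_label`, `scan_class` (`"rest"`/`"task"`), and
#'   `n_timepoints`.
#' @param tr_seconds repetition time, seconds.
#' @param latent_length_scale kernel length scale `l` of the
#'   latent-distance covariance `exp(-(h_i - h_j)^2 / (2 l^2))`; smaller
#'   values decorrelate distant parcels faster.
#' @param measurement_noise_sd sd of i.i.d. measurement noise added to every
#'   sample (signal sd is 1 by construction).
#' @param trait_sd sd of the stable between-subject part of the scale factor
#'   `a_s` (trait variance).
#' @param state_sd baseline sd of the per-session, per-parcel perturbation
#'   of `h` (session state noise), applying at the hierarchy anchors.
#' @param state_flexibility how much larger session-state noise is in the
#'   mid-hierarchy transition zone than at the anchors: parcel i's state sd
#'   is `state_sd * (1 + state_flexibility * (1 - |g_i| / max|g|))`.
#'   Mid-hierarchy regions affiliate flexibly with different networks
#'   across sessions while the sensory and default-mode anchors are stable;
#'   this also gives transition-zone parcels the lowest test-retest
#'   reliability, as observed for real gradient measures.
#' @param aging_coupling `kappa_age >= 0`; contraction of `a_s` with age.
#' @param cognition_coupling `kappa_cog >= 0`; expansion of `a_s` with
#'   cognition.
#' @param disorder_scale baseline latent disorder `delta0`: each subject's
#'   parcels sit at `g + (delta0 / a_s) u_s` with `u_s` a fixed unit-normal
#'   topography vector. Larger values mean more idiosyncratic topography
#'   (stronger subject fingerprint, weaker group recovery).
#' @param censor_fraction fraction of frames marked as censored per scan,
#'   in `[0, 0.5)`.
#' @param task_amplitude amplitude of the condition-locked evoked signal in
#'   task scans, as a multiple of `measurement_noise_sd`.
#' @param task_parcel_fraction fraction of parcels (fixed random subset,
#'   shared by all subjects) receiving the evoked signal.
#' @param seed master integer seed; all randomness derives from it via
#'   [derive_seed()].
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_parcels = 120L,
                             n_unimodal = 38L,
                             n_subjects = 24L,
                             scans = list(
                               list(scan_label = "rest1", scan_class = "rest", n_timepoints = 400L),
                               list(scan_label = "rest2", scan_class = "rest", n_timepoints = 400L),
                               list(scan_label = "task1", scan_class = "task", n_timepoints = 200L),
                               list(scan_label = "task2", scan_class = "task", n_timepoints = 200L)),
                             tr_seconds = 2,
                             latent_length_scale = 0.35,
                             measurement_noise_sd = 1.25,
                             trait_sd = 0.1,
                             state_sd = 0.05,
                             state_flexibility = 2,
                             aging_coupling = 0,
                             cognition_coupling = 0,
                             disorder_scale = 0.12,
                             censor_fraction = 0.05,
                             task_amplitude = 0.5,
                             task_parcel_fraction = 0.2,
                             seed = 1L) {
  cfg <- list(n_parcels = as.integer(n_parcels),
              n_unimodal = as.integer(n_unimodal),
              n_subjects = as.integer(n_subjects),
              scans = scans, tr_seconds = tr_seconds,
              latent_length_scale = latent_length_scale,
              measurement_noise_sd = measurement_noise_sd,
              trait_sd = trait_sd, state_sd = state_sd,
              state_flexibility = state_flexibility,
              aging_coupling = aging_coupling,
              cognition_coupling = cognition_coupling,
              disorder_scale = disorder_scale,
              censor_fraction = censor_fraction,
              task_amplitude = task_amplitude,
              task_parcel_fraction = task_parcel_fraction,
              seed = as.integer(seed))
  if (cfg$n_unimodal >= cfg$n_parcels)
    stop_fc("n_unimodal (%d) must be < n_parcels (%d)",
            cfg$n_unimodal, cfg$n_parcels)
  if (cfg$n_unimodal < 1L) stop_fc("n_unimodal must be >= 1")
  if (cfg$n_subjects < 1L) stop_fc("n_subjects must be >= 1")
  if (length(cfg$scans) < 1L) stop_fc("at least one scan must be configured")
  for (sc in cfg$scans) {
    if (!all(c("scan_label", "scan_class", "n_timepoints") %in% names(sc)))
      stop_fc("each scan needs scan_label, scan_class, n_timepoints")
    if (!sc$scan_class %in% c("rest", "task"))
      stop_fc("scan_class must be rest or task (scan %s)", sc$scan_label)
    if (sc$n_timepoints < 2L)
      stop_fc("scan %s: n_timepoints must be >= 2", sc$scan_label)
  }
  if (anyDuplicated(vapply(cfg$scans, `[[`, "", "scan_label")))
    stop_fc("scan labels must be unique")
  if (cfg$latent_length_scale <= 0) stop_fc("latent_length_scale must be > 0")
  for (nm in c("measurement_noise_sd", "trait_sd", "state_sd"))
    if (cfg[[nm]] < 0) stop_fc("%s must be >= 0", nm)
  if (cfg$aging_coupling < 0 || cfg$cognition_coupling < 0)
    stop_fc("coupling coefficients must be >= 0")
  if (cfg$disorder_scale < 0)
    stop_fc("disorder_scale must be >= 0")
  if (cfg$state_flexibility < 0)
    stop_fc("state_flexibility must be >= 0")
  if (cfg$censor_fraction < 0 || cfg$censor_fraction >= 0.5)
    stop_fc("censor_fraction must be in [0, 0.5)")
  # Reject couplings that would make truncation of a_s at 0.1 non-negligible
  # (> 1% truncated): a_s is approximately N(1, kage^2 + kcog^2 + trait_sd^2).
  sd_comb <- sqrt(cfg$aging_coupling^2 + cfg$cognition_coupling^2 +
                    cfg$trait_sd^2)
  if (sd_comb > 0 && stats::pnorm(0.1, mean = 1, sd = sd_comb) > 0.01)
    stop_fc(paste0("degenerate coupling: Pr(a_s <= 0.1) = %.3f > 1%% at the ",
                   "configured couplings/trait_sd"),
            stats::pnorm(0.1, mean = 1, sd = sd_comb))
  structure(cfg, class = "synthetic_config")
}

#' Draw the planted ground truth for a synthetic cohort
#'
#' Plants the hierarchy gradient `g` (unimodal parcels equally spaced on
#' `[-1, -0.2]`, heteromodal on `[0.2, 1]`, plus small jitter), draws the
#' behavior table (age ~ Uniform(25, 35), cognition ~ Normal(110, 20),
#' sex ~ Bernoulli(0.5), motion ~ Lognormal matching typical mean framewise
#' displacement around 0.15 mm), and computes each subject's scale factor
#' `a_s = 1 - kappa_age * z(age) + kappa_cog * z(cognition) + N(0, trait_sd^2)`,
#' truncated below at 0.1. Each subject also receives a stable topography
#' offset `(disorder_scale / a_s) u_s` (`u_s` unit normal) — the trait-like
#' scattering of parcels off their canonical hierarchy positions — and
#' per-session state perturbations. Every draw uses a labeled child stream
#' of the master seed (see [derive_seed()]).
#'
#' @param config a [synthetic_config()].
#' @return An object of class `synthetic_ground_truth` with elements
#'   `true_gradient`, `parcel_class`, `subject_scale`, `subject_offsets`
#'   (subjects x parcels matrix), `behavior_table`,
#'   `session_perturbations` (subjects x sessions x parcels array),
#'   `task_parcels`, `config`, `seeds_used`.
#' @export
make_ground_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  p <- config$n_parcels
  n_uni <- config$n_unimodal
  n_het <- p - n_uni
  pid <- parcel_ids(p)
  parcel_class <- c(rep("unimodal", n_uni), rep("heteromodal", n_het))

  set.seed(derive_seed(config$seed, "gradient"))
  # Parcels sit on one smooth axis, denser near the two poles (sensory and
  # association anchors) and sparser mid-hierarchy; unimodal parcels take
  # the low end. The pole-dense spacing mirrors how cortical parcels crowd
  # the anchors of the real hierarchy and keeps the planted axis the
  # dominant (non-degenerate) smooth mode of the resulting covariance.
  # Jitter is kept well below the parcel spacing so ordering is recoverable.
  x <- seq(-1, 1, length.out = p)
  g <- sign(x) * abs(x)^0.85 + rnorm(p, 0, 0.005)
  names(g) <- pid

  n <- config$n_subjects
  sid <- sprintf("sub%03d", seq_len(n))
  age <- cog <- sex <- motion <- trait <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(derive_seed(config$seed, "behavior", sid[i]))
    age[i] <- runif(1, 25, 35)
    cog[i] <- rnorm(1, 110, 20)
    sex[i] <- rbinom(1, 1, 0.5)
    motion[i] <- rlnorm(1, log(0.15), 0.25)
    trait[i] <- rnorm(1, 0, config$trait_sd)
  }
  a <- 1 - config$aging_coupling * zscore(age) +
    config$cognition_coupling * zscore(cog) + trait
  a <- pmax(a, 0.1)
  names(a) <- sid

  # stable per-subject topography: parcels scattered off their canonical
  # positions by disorder_scale / a_s (aging -> more disorder)
  offsets <- matrix(0, n, p, dimnames = list(sid, pid))
  for (i in seq_len(n)) {
    set.seed(derive_seed(config$seed, "topography", sid[i]))
    offsets[i, ] <- (config$disorder_scale / a[i]) * rnorm(p)
  }

  # session-state noise is smallest at the hierarchy anchors and largest in
  # the flexible mid-hierarchy transition zone
  state_scale <- config$state_sd *
    (1 + config$state_flexibility * (1 - abs(g) / max(abs(g))))
  pert <- array(0, dim = c(n, 2, p),
                dimnames = list(sid, c("test", "retest"), pid))
  for (i in seq_len(n)) {
    for (sess in c("test", "retest")) {
      set.seed(derive_seed(config$seed, "state", sid[i], sess))
      pert[i, sess, ] <- rnorm(p, 0, 1) * state_scale
    }
  }

  set.seed(derive_seed(config$seed, "task_parcels"))
  task_parcels <- sort(sample.int(p, max(1L, round(config$task_parcel_fraction * p))))

  structure(
    list(true_gradient = g,
         parcel_class = parcel_class,
         subject_scale = a,
         subject_offsets = offsets,
         behavior_table = data.frame(subject_id = sid, age_proxy = age,
                                     cognition_proxy = cog, sex = sex,
                                     motion = motion,
                                     stringsAsFactors = FALSE),
         session_perturbations = pert,
         task_parcels = task_parcels,
         config = config,
         seeds_used = list(master = config$seed,
                           rule = "derive_seed(master, labels...): polynomial-31 hash of '/'-joined labels mod 2^31-1")),
    class = "synthetic_ground_truth")
}

#' Parcel partition table of a synthetic ground truth
#'
#' @param truth a `synthetic_ground_truth`.
#' @return data frame with columns `parcel_id`, `class`
#'   (`unimodal`/`heteromodal`).
#' @export
partition_table <- function(truth) {
  stopifnot(inherits(truth, "synthetic_ground_truth"))
  data.frame(parcel_id = names(truth$true_gradient),
             class = truth$parcel_class, stringsAsFactors = FALSE)
}

#' Latent-distance parcel covariance of one subject and session
#'
#' `Sigma_ij = exp(-(h_i - h_j)^2 / (2 l^2))` — the Gaussian latent-distance
#' kernel evaluated at the subject's session positions
#' `h = g + subject offset + session perturbation` (see
#' [make_ground_truth()]). Parcels close on the (subject-specific) hierarchy
#' axis are strongly correlated; distant parcels decorrelate at length
#' scale `l`. The Gaussian kernel guarantees positive semidefiniteness;
#' eigenvalues are checked and a diagonal jitter of 1e-8 is applied if
#' round-off produces a tiny negative eigenvalue.
#'
#' @param truth a `synthetic_ground_truth`.
#' @param subject_id subject identifier present in the truth.
#' @param session `"test"` or `"retest"`.
#' @return P x P covariance matrix with unit diagonal.
#' @export
subject_covariance <- function(truth, subject_id, session) {
  stopifnot(inherits(truth, "synthetic_ground_truth"))
  if (!subject_id %in% names(truth$subject_scale))
    stop_fc("unknown subject '%s'", subject_id)
  if (!session %in% c("test", "retest"))
    stop_fc("unknown session '%s'", session)
  l <- truth$config$latent_length_scale
  h <- truth$true_gradient +
    truth$subject_offsets[subject_id, ] +
    truth$session_perturbations[subject_id, session, ]
  d <- outer(h, h, `-`)
  sigma <- exp(-d^2 / (2 * l^2))
  ev_min <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8)
    stop_fc("covariance for %s/%s is not PSD (min eigenvalue %.3g)",
            subject_id, session, ev_min)
  if (ev_min < 1e-9)
    sigma <- sigma + diag(1e-8 + max(0, -ev_min), nrow(sigma))
  dimnames(sigma) <- list(names(truth$true_gradient),
                          names(truth$true_gradient))
  sigma
}

# Canonical double-gamma hemodynamic response, sampled at TR resolution and
# peak-normalized. Shape parameters follow the common 6 s peak / 16 s
# undershoot convention.
double_gamma_hrf <- function(tr_seconds, length_seconds = 32) {
  t <- seq(0, length_seconds, by = tr_seconds)
  h <- dgamma(t, shape = 6, rate = 1) - dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

# Deterministic sparse event design for a task scan: one-frame events of a
# single condition every 30 s, starting 20 s in.
make_task_events <- function(n_timepoints, tr_seconds) {
  scan_seconds <- n_timepoints * tr_seconds
  onsets <- seq(20, scan_seconds - 40, by = 30)
  if (length(onsets) == 0) onsets <- min(10, scan_seconds / 2)
  data.frame(onset_seconds = onsets,
             duration_seconds = tr_seconds,
             condition = "A", stringsAsFactors = FALSE)
}

# Evoked time course: boxcar of the events convolved with the double-gamma
# kernel, at frame resolution.
evoked_timecourse <- function(events, n_timepoints, tr_seconds) {
  t_frame <- (seq_len(n_timepoints) - 1) * tr_seconds
  box <- rep(0, n_timepoints)
  for (i in seq_len(nrow(events))) {
    on <- events$onset_seconds[i]
    off <- on + events$duration_seconds[i]
    box[t_frame >= on & t_frame < off] <- 1
  }
  hrf <- double_gamma_hrf(tr_seconds)
  ev <- convolve(box, rev(hrf), type = "open")[seq_len(n_timepoints)]
  ev
}

#' Simulate a synthetic test-retest cohort
#'
#' Draws every scan's rows i.i.d. from `N(0, Sigma_{subject,session})` (the
#' latent-distance covariance of [subject_covariance()]) plus independent
#' measurement noise. Task scans additionally carry a condition-locked
#' boxcar convolved with a double-gamma kernel, added to a fixed random
#' subset of parcels, with the matching event table attached. Censor masks
#' mark `censor_fraction` of frames at random positions. All draws use
#' labeled child streams of the master seed, so cohorts are reproducible and
#' per-subject outputs are independent of cohort composition.
#'
#' @param config a [synthetic_config()].
#' @return list with `scans` (flat list of [parcellated_scan()] across
#'   subject x session x scan) and `truth` (the `synthetic_ground_truth`).
#' @export
simulate_cohort <- function(config) {
  truth <- make_ground_truth(config)
  sid <- names(truth$subject_scale)
  p <- config$n_parcels
  sigma_e <- config$measurement_noise_sd
  scans <- list()
  for (s in sid) {
    for (sess in c("test", "retest")) {
      sigma <- subject_covariance(truth, s, sess)
      cl <- chol(sigma)
      for (sc in config$scans) {
        tp <- sc$n_timepoints
        set.seed(derive_seed(config$seed, "scan", s, sess, sc$scan_label))
        x <- matrix(rnorm(tp * p), tp, p) %*% cl
        if (sigma_e > 0) x <- x + matrix(rnorm(tp * p, 0, sigma_e), tp, p)
        events <- NULL
        if (sc$scan_class == "task") {
          events <- make_task_events(tp, config$tr_seconds)
          ev <- evoked_timecourse(events, tp, config$tr_seconds)
          amp <- config$task_amplitude * sigma_e
          x[, truth$task_parcels] <- x[, truth$task_parcels] +
            amp * matrix(ev, tp, length(truth$task_parcels))
        }
        mask <- rep(TRUE, tp)
        n_cens <- floor(config$censor_fraction * tp)
        if (n_cens > 0) {
          set.seed(derive_seed(config$seed, "censor", s, sess, sc$scan_label))
          mask[sample.int(tp, n_cens)] <- FALSE
        }
        colnames(x) <- names(truth$true_gradient)
        scans[[length(scans) + 1L]] <-
          parcellated_scan(subject_id = s, session = sess,
                           scan_label = sc$scan_label,
                           scan_class = sc$scan_class,
                           data = x, tr_seconds = config$tr_seconds,
                           censor_mask = mask, events = events)
      }
    }
  }
  list(scans = scans, truth = truth)
}
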