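#' Build finite impulse response (FIR) task regressors
#'
#' One indicator column per (condition, lag bin): entry is 1 when the
#' timepoint's acquisition time falls in `[onset + lag*TR, onset + (lag+1)*TR)`
#' for any event of that condition. Lags span `ceil(window/TR)` bins.
#' Regressing these columns out removes any condition-locked response shape
#' up to the window length, leaving "background" connectivity in task scans.
#'
#' @param events data frame with `onset_seconds`, `duration_seconds`,
#'   `condition`; may be `NULL` or empty (returns a 0-column matrix).
#' @param n_timepoints number of frames in the scan.
#' @param tr_seconds repetition time, seconds.
#' @param window_seconds length of the modeled response window, seconds.
#' @return numeric matrix, `n_timepoints` x (conditions x lags), all-zero
#'   columns dropped. Column names are `"<condition>_lag<k>"`.
#' @export
build_fir_regressors <- function(events, n_timepoints, tr_seconds,
                                 window_seconds = 24) {
  if (window_seconds <= 0) stop_fc("window_seconds must be > 0")
  if (is.null(events) || nrow(events) == 0)
    return(matrix(0, n_timepoints, 0))
  scan_seconds <- n_timepoints * tr_seconds
  if (any(events$onset_seconds < 0 | events$onset_seconds >= scan_seconds))
    stop_fc("event onsets must lie within the scan duration")
  n_lags <- ceiling(window_seconds / tr_seconds)
  t_frame <- (seq_len(n_timepoints) - 1) * tr_seconds
  conds <- unique(events$condition)
  cols <- list()
  for (cond in conds) {
    onsets <- events$onset_seconds[events$condition == cond]
    for (lag in seq_len(n_lags) - 1L) {
      col <- rep(0, n_timepoints)
      for (on in onsets) {
        col[t_frame >= on + lag * tr_seconds &
              t_frame < on + (lag + 1) * tr_seconds] <- 1
      }
      cols[[sprintf("%s_lag%d", cond, lag)]] <- col
    }
  }
  m <- do.call(cbind, cols)
  m[, colSums(m != 0) > 0, drop = FALSE]
}

# Sine/cosine columns at the discrete scan frequencies j / (T * TR) lying
# OUTSIDE the passband, evaluated at the original frame times. Regressing
# them out implements filtering as a projection, which stays valid when rows
# are later restricted to uncensored frames.
spectral_basis <- function(n_timepoints, tr_seconds, band) {
  if (is.null(band)) return(matrix(0, n_timepoints, 0))
  low <- band[1]
  high <- if (length(band) >= 2) band[2] else NA_real_
  total <- n_timepoints * tr_seconds
  j <- seq_len(floor(n_timepoints / 2))
  f <- j / total
  out <- (!is.na(low) & f < low) | (!is.na(high) & f > high)
  j <- j[out]
  if (length(j) == 0) return(matrix(0, n_timepoints, 0))
  t_frame <- (seq_len(n_timepoints) - 1) * tr_seconds
  cols <- list()
  for (jj in j) {
    ang <- 2 * pi * jj * t_frame / total
    cols[[sprintf("cos%d", jj)]] <- cos(ang)
    cols[[sprintf("sin%d", jj)]] <- sin(ang)
  }
  m <- do.call(cbind, cols)
  # drop numerically zero columns (e.g., sine at the Nyquist frequency)
  m[, sqrt(colSums(m^2)) > 1e-8, drop = FALSE]
}

#' Clean a parcellated scan in a single projection
#'
#' Builds the design `[nuisance | FIR task regressors (task scans) |
#' out-of-band sine/cosine columns | intercept]`, restricts all rows to
#' uncensored frames, and returns the least-squares residuals of each parcel
#' on that design. Nuisance regression, task-signal removal, temporal
#' filtering and censoring therefore happen in one step, and the filter is
#' exact on the censored grid (it is a regression on the out-of-band basis
#' at kept frame times, not a recursive filter).
#'
#' @param scan a [parcellated_scan()].
#' @param band `c(low_hz, high_hz)`; frequencies below `low_hz` or above
#'   `high_hz` are removed. Use `NA` for an open side (e.g.
#'   `c(0.008, NA)` = high-pass only), or `NULL` for no filtering.
#' @param fir_window_seconds FIR response window (task scans), seconds.
#' @return A cleaned [parcellated_scan()] holding only the kept frames (its
#'   censor mask is all-`TRUE`); attribute `dof_used` records regressor
#'   count, kept frames, and residual degrees of freedom.
#' @export
clean_timeseries <- function(scan, band = c(0.008, NA),
                             fir_window_seconds = 24) {
  stopifnot(inherits(scan, "parcellated_scan"))
  tp <- nrow(scan$data)
  design <- cbind(
    scan$nuisance,
    if (scan$scan_class == "task" && !is.null(scan$events))
      build_fir_regressors(scan$events, tp, scan$tr_seconds,
                           fir_window_seconds),
    spectral_basis(tp, scan$tr_seconds, band),
    intercept = rep(1, tp))
  keep <- scan$censor_mask
  q <- ncol(design)
  if (sum(keep) < q + 10)
    stop_fc(paste0("scan %s/%s/%s: only %d uncensored frames for %d ",
                   "regressors; too few degrees of freedom remaining"),
            scan$subject_id, scan$session, scan$scan_label, sum(keep), q)
  xk <- design[keep, , drop = FALSE]
  qr_x <- qr(xk)
  if (qr_x$rank < ncol(xk))
    stop_fc(paste0("scan %s/%s/%s: design rank-deficient after censoring ",
                   "(rank %d < %d regressors; %d frames kept)"),
            scan$subject_id, scan$session, scan$scan_label,
            qr_x$rank, ncol(xk), sum(keep))
  resid <- qr.resid(qr_x, scan$data[keep, , drop = FALSE])
  colnames(resid) <- colnames(scan$data)
  out <- parcellated_scan(scan$subject_id, scan$session, scan$scan_label,
                          scan$scan_class, resid, scan$tr_seconds,
                          censor_mask = rep(TRUE, nrow(resid)),
                          events = scan$events)
  attr(out, "dof_used") <- list(n_regressors = q, frames_kept = sum(keep),
                                dof_remaining = sum(keep) - q)
  out
}

#' Subsample cleaned scans to a fixed data amount
#'
#' Equal-allocation rule: the target frame count (`round(minutes * 60 / TR)`)
#' is divided equally over scans (floor), each scan contributing its earliest
#' kept frames, capped at its available length; any shortfall is filled by
#' frames drawn uniformly at random (seeded, without replacement) from the
#' remaining pool across all scans. Frames stay in temporal order within each
#' scan and scans are concatenated in input order.
#'
#' @param scans list of cleaned [parcellated_scan()] (censored frames already
#'   removed), sharing one TR and parcel set.
#' @param target_minutes data amount to extract, minutes.
#' @param seed integer seed for the random fill.
#' @return numeric matrix, frames x parcels.
#' @export
subsample_timepoints <- function(scans, target_minutes, seed = 1L) {
  stopifnot(length(scans) >= 1)
  tr <- scans[[1]]$tr_seconds
  if (any(vapply(scans, `[[`, 0, "tr_seconds") != tr))
    stop_fc("scans must share a common TR")
  avail <- vapply(scans, function(s) nrow(s$data), 0L)
  n_target <- round(target_minutes * 60 / tr)
  if (sum(avail) < n_target)
    stop_fc("insufficient data: %.2f minutes available, %.2f requested",
            sum(avail) * tr / 60, target_minutes)
  base <- n_target %/% length(scans)
  contrib <- pmin(base, avail)
  shortfall <- n_target - sum(contrib)
  take <- lapply(seq_along(scans), function(i) seq_len(contrib[i]))
  if (shortfall > 0) {
    pool_scan <- unlist(lapply(seq_along(scans), function(i)
      rep(i, avail[i] - contrib[i])))
    pool_frame <- unlist(lapply(seq_along(scans), function(i)
      if (avail[i] > contrib[i]) (contrib[i] + 1L):avail[i] else integer(0)))
    set.seed(seed)
    pick <- sample.int(length(pool_scan), shortfall)
    for (k in pick) {
      i <- pool_scan[k]
      take[[i]] <- c(take[[i]], pool_frame[k])
    }
  }
  do.call(rbind, lapply(seq_along(scans), function(i)
    scans[[i]]$data[sort(take[[i]]), , drop = FALSE]))
}

#' Assemble the time series for one modality
#'
#' rsFC uses rest scans only; GFC pools rest and task scans (after FIR
#' task-signal removal in [clean_timeseries()]). With `target_minutes =
#' "all"` the kept frames are simply concatenated; otherwise the
#' equal-allocation subsampling of [subsample_timepoints()] is applied.
#'
#' @param scans list of cleaned [parcellated_scan()] for one subject/session.
#' @param modality `"rsFC"` or `"GFC"`.
#' @param target_minutes numeric minutes or `"all"`.
#' @param seed seed for the random fill of [subsample_timepoints()].
#' @return numeric matrix, frames x parcels.
#' @export
assemble_modality <- function(scans, modality = c("rsFC", "GFC"),
                              target_minutes = "all", seed = 1L) {
  modality <- match.arg(modality)
  use <- if (modality == "rsFC")
    Filter(function(s) s$scan_class == "rest", scans) else scans
  if (length(use) == 0)
    stop_fc("no %s scans available for modality %s",
            if (modality == "rsFC") "rest" else "", modality)
  if (identical(target_minutes, "all"))
    return(do.call(rbind, lapply(use, function(s)
      s$data[s$censor_mask, , drop = FALSE])))
  subsample_timepoints(use, target_minutes, seed)
}

#' Construct a connectivity matrix object
#'
#' @param values P x P Pearson correlation matrix.
#' @param modality `"rsFC"` or `"GFC"`.
#' @param minutes_used minutes of data behind the estimate.
#' @param subject_id,session provenance metadata.
#' @return object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(values, modality = "rsFC",
                                minutes_used = NA_real_,
                                subject_id = NA_character_,
                                session = NA_character_) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values))
  if (max(abs(values - t(values))) > 1e-8)
    stop_fc("connectivity matrix must be symmetric")
  values <- (values + t(values)) / 2
  diag(values) <- 1
  if (any(values < -1 - 1e-8 | values > 1 + 1e-8))
    stop_fc("correlations must lie in [-1, 1]")
  values <- pmin(pmax(values, -1), 1)
  structure(list(values = values, modality = modality,
                 minutes_used = minutes_used, subject_id = subject_id,
                 session = session),
            class = "connectivity_matrix")
}

#' Pearson functional connectivity of a time series matrix
#'
#' @param timeseries frames x parcels numeric matrix (at least 3 frames, no
#'   constant column).
#' @param modality,minutes_used,subject_id,session metadata stored on the
#'   result.
#' @return a [connectivity_matrix()].
#' @export
compute_fc <- function(timeseries, modality = "rsFC",
                       minutes_used = NA_real_,
                       subject_id = NA_character_,
                       session = NA_character_) {
  timeseries <- as.matrix(timeseries)
  if (nrow(timeseries) < 3) stop_fc("need at least 3 timepoints")
  sds <- apply(timeseries, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(timeseries)[sds == 0] %||% which(sds == 0)
    stop_fc("constant parcel time series: %s",
            paste(bad, collapse = ", "))
  }
  r <- stats::cor(timeseries)
  connectivity_matrix(r, modality, minutes_used, subject_id, session)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s %s/%s: %d parcels, %.3g min\n",
              x$modality, x$subject_id, x$session, nrow(x$values),
              x$minutes_used))
  invisible(x)
}
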