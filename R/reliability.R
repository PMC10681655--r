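#' Intraclass correlation ICC(3,1)
#'
#' Two-way mixed-effects, single-measurement, consistency ICC: with BMS the
#' between-subjects mean square and EMS the residual mean square of the
#' two-way (subject + session) ANOVA,
#' `ICC = (BMS - EMS) / (BMS + (k - 1) EMS)`. The raw value is returned and
#' may be negative. Because the session main effect is removed, a constant
#' shift between sessions does not lower the ICC (consistency, not absolute
#' agreement).
#'
#' @param table n x k numeric matrix: n subjects (rows) measured in k
#'   sessions (columns); no missing cells, n >= 3, k >= 2.
#' @return scalar ICC(3,1).
#' @export
icc_3_1 <- function(table) {
  x <- as.matrix(table)
  if (anyNA(x)) stop_fc("ICC table contains missing cells")
  n <- nrow(x)
  k <- ncol(x)
  if (n < 3 || k < 2) stop_fc("ICC requires n >= 3 subjects and k >= 2 sessions")
  grand <- mean(x)
  ss_total <- sum((x - grand)^2)
  if (ss_total == 0) {
    warning("zero total variance; ICC undefined, returning 0")
    return(0)
  }
  ss_rows <- k * sum((rowMeans(x) - grand)^2)
  ss_cols <- n * sum((colMeans(x) - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  bms <- ss_rows / (n - 1)
  ems <- ss_err / ((n - 1) * (k - 1))
  denom <- bms + (k - 1) * ems
  if (denom == 0) {
    warning("zero subject and residual variance; ICC undefined, returning 0")
    return(0)
  }
  (bms - ems) / denom
}

# Vectorized ICC(3,1) for k = 2 sessions over many measures at once:
# x1, x2 are n x m matrices (session 1 and 2 values of m measures).
icc31_cols <- function(x1, x2) {
  n <- nrow(x1)
  rm2 <- (x1 + x2) / 2
  g <- (colMeans(x1) + colMeans(x2)) / 2
  ss_rows <- 2 * colSums(sweep(rm2, 2, g)^2)
  ss_cols <- n * ((colMeans(x1) - g)^2 + (colMeans(x2) - g)^2)
  ss_total <- colSums(sweep(x1, 2, g)^2) + colSums(sweep(x2, 2, g)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  bms <- ss_rows / (n - 1)
  ems <- ss_err / (n - 1)
  denom <- bms + ems
  out <- ifelse(denom == 0, 0, (bms - ems) / denom)
  out[ss_total == 0] <- 0
  out
}

# Stack the upper-triangle Fisher-z edges of per-subject FC matrices into an
# n x E matrix; returns also the edge endpoint indices.
edge_z_matrix <- function(fc_list) {
  p <- nrow(fc_list[[1]]$values)
  ut <- upper.tri(matrix(0, p, p))
  ep <- which(ut, arr.ind = TRUE)
  z <- t(vapply(fc_list, function(f) fisher_z(f$values[ut]),
                numeric(sum(ut))))
  list(z = z, endpoints = ep, p = p)
}

check_paired_fcs <- function(test_fcs, retest_fcs) {
  if (length(test_fcs) != length(retest_fcs))
    stop_fc("test and retest lists must have the same length")
  if (length(test_fcs) < 3)
    stop_fc("edge-wise ICC requires at least 3 subjects")
  p <- nrow(test_fcs[[1]]$values)
  ok <- vapply(c(test_fcs, retest_fcs),
               function(f) nrow(f$values) == p, TRUE)
  if (!all(ok)) stop_fc("FC matrices have mixed parcel sets")
}

#' Parcel-wise ICC of edge-wise functional connectivity
#'
#' Computes ICC(3,1) per edge (upper triangle, Fisher-z scale) over subjects
#' by two sessions, then summarizes per parcel as the mean ICC of all P - 1
#' edges incident to that parcel.
#'
#' @param test_fcs,retest_fcs lists of [connectivity_matrix()], one per
#'   subject, in matching order.
#' @return named numeric vector of per-parcel ICCs.
#' @export
edgewise_parcel_icc <- function(test_fcs, retest_fcs) {
  check_paired_fcs(test_fcs, retest_fcs)
  e1 <- edge_z_matrix(test_fcs)
  e2 <- edge_z_matrix(retest_fcs)
  icc <- icc31_cols(e1$z, e2$z)
  p <- e1$p
  out <- vapply(seq_len(p), function(i)
    mean(icc[e1$endpoints[, 1] == i | e1$endpoints[, 2] == i]), 0)
  names(out) <- rownames(test_fcs[[1]]$values)
  out
}

#' Parcel-wise ICC of thresholded edge-wise functional connectivity
#'
#' The retained edge set is defined once, from the Fisher-z grand-mean FC
#' across all subjects and both sessions: per parcel (row), the strongest
#' `ceil(density * (P - 1))` edges, ties broken toward the lower parcel
#' index, as in [sparsify_rows()]. Parcel i's value is the mean ICC over the
#' edges retained in its own row (an edge retained for either endpoint
#' counts for that endpoint's row only).
#'
#' @inheritParams edgewise_parcel_icc
#' @param density proportion of strongest edges kept per parcel.
#' @return named numeric vector of per-parcel ICCs.
#' @export
thresholded_edgewise_parcel_icc <- function(test_fcs, retest_fcs,
                                            density = 0.10) {
  check_paired_fcs(test_fcs, retest_fcs)
  e1 <- edge_z_matrix(test_fcs)
  e2 <- edge_z_matrix(retest_fcs)
  icc <- icc31_cols(e1$z, e2$z)
  p <- e1$p
  iccmat <- matrix(0, p, p)
  iccmat[e1$endpoints] <- icc
  iccmat <- iccmat + t(iccmat)
  grand <- fisher_mean_fc(c(test_fcs, retest_fcs))
  retained <- sparsify_rows(grand, density) != 0
  out <- vapply(seq_len(p), function(i) mean(iccmat[i, retained[i, ]]), 0)
  names(out) <- rownames(test_fcs[[1]]$values)
  out
}

#' Parcel-wise ICC of principal-gradient values
#'
#' ICC(3,1) per parcel on principal-gradient coordinates over subjects by
#' two sessions. All gradient sets must be aligned to a common template.
#'
#' @param test_gradients,retest_gradients lists of aligned [gradient_set()],
#'   one per subject, in matching order.
#' @return named numeric vector of per-parcel ICCs.
#' @export
gradient_parcel_icc <- function(test_gradients, retest_gradients) {
  all_g <- c(test_gradients, retest_gradients)
  if (!all(vapply(all_g, function(g) isTRUE(g$aligned), TRUE)))
    stop_fc("all gradient sets must be aligned to a common template")
  tid <- unique(vapply(all_g, function(g) g$template_id %||% "", ""))
  if (length(tid) > 1)
    stop_fc("gradient sets are aligned to different templates: %s",
            paste(tid, collapse = ", "))
  if (length(test_gradients) != length(retest_gradients))
    stop_fc("test and retest lists must have the same length")
  if (length(test_gradients) < 3) stop_fc("need at least 3 subjects")
  x1 <- t(vapply(test_gradients, function(g) g$coordinates[, 1],
                 numeric(nrow(test_gradients[[1]]$coordinates))))
  x2 <- t(vapply(retest_gradients, function(g) g$coordinates[, 1],
                 numeric(nrow(retest_gradients[[1]]$coordinates))))
  out <- icc31_cols(x1, x2)
  names(out) <- rownames(test_gradients[[1]]$coordinates)
  out
}

#' ICC of the gradient range
#'
#' @param test_ranges,retest_ranges numeric vectors of per-subject gradient
#'   ranges (or lists of `range_value` objects), matching order, n >= 3.
#' @return scalar ICC(3,1).
#' @export
range_icc <- function(test_ranges, retest_ranges) {
  as_num <- function(x) {
    if (is.list(x)) vapply(x, function(r) r$value, 0) else as.numeric(x)
  }
  icc_3_1(cbind(as_num(test_ranges), as_num(retest_ranges)))
}

comparison_result <- function(test_kind, t_statistic, p_value, n,
                              mean_difference) {
  structure(list(test_kind = test_kind, t_statistic = t_statistic,
                 p_value = p_value, n = n,
                 mean_difference = mean_difference),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s t = %.3f, p = %.3g, n = %d, mean diff = %.4f\n",
              x$test_kind, x$t_statistic, x$p_value, x$n, x$mean_difference))
  invisible(x)
}

#' Paired comparison of two per-parcel ICC vectors
#'
#' Two-sided paired t-test of `icc_a - icc_b` across parcels (the two
#' measures are computed on the same parcels, so the test is paired).
#'
#' @param icc_a,icc_b per-parcel ICC vectors of equal length, paired by
#'   parcel.
#' @return a `comparison_result` (fields `t_statistic`, `p_value`, `n`,
#'   `mean_difference`).
#' @export
compare_icc_paired <- function(icc_a, icc_b) {
  if (length(icc_a) != length(icc_b))
    stop_fc("ICC vectors must have equal length")
  d <- icc_a - icc_b
  if (stats::sd(d) <= 1e-10 * max(abs(d), 1e-300)) {
    # constant difference: t degenerates to 0/0 (no difference) or +-Inf
    if (mean(d) == 0)
      return(comparison_result("paired", 0, 1, length(d), 0))
    return(comparison_result("paired", sign(mean(d)) * Inf, 0, length(d),
                             mean(d)))
  }
  tt <- stats::t.test(icc_a, icc_b, paired = TRUE)
  comparison_result("paired", unname(tt$statistic), tt$p.value,
                    length(icc_a), unname(tt$estimate))
}

#' Compare ICCs between unimodal and heteromodal parcels
#'
#' Two-sided Welch two-sample t-test, heteromodal minus unimodal.
#'
#' @param icc named per-parcel ICC vector (names = parcel ids).
#' @param partition data frame `(parcel_id, class)`.
#' @return a `comparison_result`.
#' @export
compare_groups_icc <- function(icc, partition) {
  cls <- partition_classes(partition, names(icc))
  het <- icc[cls == "heteromodal"]
  uni <- icc[cls == "unimodal"]
  if (length(het) < 2 || length(uni) < 2)
    stop_fc("both classes need at least 2 parcels")
  tt <- stats::t.test(het, uni, var.equal = FALSE)
  comparison_result("welch", unname(tt$statistic), tt$p.value,
                    length(icc), mean(het) - mean(uni))
}

# Group a flat list of scans into scans[[subject]][[session]].
split_scans <- function(scans) {
  out <- list()
  for (s in scans) {
    out[[s$subject_id]][[s$session]] <-
      c(out[[s$subject_id]][[s$session]], list(s))
  }
  out
}

# FC + aligned gradients for every subject in one session at one data amount.
session_measures <- function(by_subj, session, modality, minutes, template,
                             partition, density, n_components, alpha,
                             diffusion_time, seed) {
  subjects <- names(by_subj)
  fcs <- list()
  grads <- list()
  ranges <- numeric(0)
  for (s in subjects) {
    scans <- by_subj[[s]][[session]]
    if (is.null(scans)) stop_fc("subject %s has no %s session", s, session)
    ts <- assemble_modality(scans, modality, minutes,
                            seed = derive_seed(seed, "assemble", s, session,
                                               modality, minutes))
    minutes_used <- if (identical(minutes, "all"))
      nrow(ts) * scans[[1]]$tr_seconds / 60 else minutes
    fc <- compute_fc(ts, modality, minutes_used, s, session)
    g <- derive_gradients(fc, template, density, n_components, alpha,
                          diffusion_time)
    fcs[[s]] <- fc
    grads[[s]] <- g
    ranges[s] <- gradient_range(g, partition)$value
  }
  list(fcs = fcs, gradients = grads, ranges = ranges)
}

#' Test-retest reliability across a grid of scan lengths
#'
#' For each target data amount: assemble the modality's time series,
#' compute FC, derive and align gradients for both sessions, then compute
#' all ICC measures (edge-wise, thresholded edge-wise, gradient, range).
#'
#' @param scans flat list of cleaned [parcellated_scan()] covering both
#'   sessions of every subject.
#' @param modality `"rsFC"` or `"GFC"`.
#' @param minutes_grid numeric vector of data amounts (minutes), or the
#'   string `"all"` for a single sweep point using all kept frames.
#' @param template template [gradient_set()] used for alignment.
#' @param partition data frame `(parcel_id, class)`.
#' @param density sparsification / edge-retention density.
#' @param n_components,alpha,diffusion_time embedding parameters.
#' @param seed master seed for the subsampling random fill.
#' @return list with `reliability` (data frame: minutes, measure, parcel_id,
#'   icc) and `range` (data frame: minutes, icc).
#' @export
scan_length_sweep <- function(scans, modality, minutes_grid, template,
                              partition, density = 0.10, n_components = 10,
                              alpha = 0.5, diffusion_time = 0, seed = 1L) {
  by_subj <- split_scans(scans)
  rel_rows <- list()
  rng_rows <- list()
  for (minutes in minutes_grid) {
    m_lab <- if (identical(minutes, "all")) NA_real_ else as.numeric(minutes)
    test <- session_measures(by_subj, "test", modality, minutes, template,
                             partition, density, n_components, alpha,
                             diffusion_time, seed)
    retest <- session_measures(by_subj, "retest", modality, minutes, template,
                               partition, density, n_components, alpha,
                               diffusion_time, seed)
    edge <- edgewise_parcel_icc(test$fcs, retest$fcs)
    thr <- thresholded_edgewise_parcel_icc(test$fcs, retest$fcs, density)
    grad <- gradient_parcel_icc(test$gradients, retest$gradients)
    for (meas in c("edgewise_mean", "thresholded_edgewise_mean", "gradient")) {
      icc <- switch(meas, edgewise_mean = edge,
                    thresholded_edgewise_mean = thr, gradient = grad)
      rel_rows[[length(rel_rows) + 1L]] <-
        data.frame(minutes = m_lab, measure = meas, parcel_id = names(icc),
                   icc = unname(icc), stringsAsFactors = FALSE)
    }
    rng_rows[[length(rng_rows) + 1L]] <-
      data.frame(minutes = m_lab,
                 icc = range_icc(test$ranges, retest$ranges))
  }
  list(reliability = do.call(rbind, rel_rows),
       range = do.call(rbind, rng_rows))
}
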