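#' Standardized OLS association of one outcome with one predictor
#'
#' The outcome, predictor, and continuous covariates are z-scored (binary
#' sex is left as 0/1); the outcome is regressed on
#' `[predictor, covariates, intercept]` by ordinary least squares, and the
#' predictor's standardized coefficient (SD of outcome per SD of predictor)
#' and two-sided t-test p-value are returned.
#'
#' @param outcome numeric per-subject vector.
#' @param predictor numeric per-subject vector.
#' @param covariates optional data frame of per-subject covariates; columns
#'   with more than two distinct values are z-scored, binary columns kept.
#' @return named numeric vector `c(beta_std, p_value)`.
#' @export
fit_standardized_ols <- function(outcome, predictor, covariates = NULL) {
  n <- length(outcome)
  if (length(predictor) != n)
    stop_fc("outcome and predictor lengths differ")
  if (stats::sd(predictor) == 0) stop_fc("predictor has zero variance")
  if (stats::sd(outcome) == 0) stop_fc("outcome has zero variance")
  covs <- NULL
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    covariates <- as.data.frame(covariates)
    covs <- vapply(covariates, function(col) {
      col <- as.numeric(col)
      if (length(unique(col)) > 2) zscore(col) else col
    }, numeric(n))
    covs <- matrix(covs, nrow = n,
                   dimnames = list(NULL, names(covariates)))
  }
  x <- cbind(intercept = 1, predictor = zscore(predictor), covs)
  if (n <= ncol(x) + 2)
    stop_fc("need n > number of regressors + 2 (n = %d, regressors = %d)",
            n, ncol(x))
  if (kappa(x, exact = TRUE) > 1e10)
    stop_fc("collinear design (condition number > 1e10)")
  y <- zscore(outcome)
  qr_x <- qr(x)
  beta <- qr.coef(qr_x, y)
  res <- qr.resid(qr_x, y)
  df <- n - ncol(x)
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(sigma2 * diag(xtx_inv))
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval["predictor"]), df)
  c(beta_std = unname(beta["predictor"]), p_value = unname(p))
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up q-values (`stats::p.adjust(method = "BH")`) and significance
#' flags at the given FDR threshold.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param q FDR threshold.
#' @return list with `q_values` and logical `significant`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop_fc("p-values must lie in [0, 1]")
  qv <- stats::p.adjust(p_values, method = "BH")
  list(q_values = qv, significant = qv < q)
}

#' Parcel-wise association map of behavior with gradient measures
#'
#' Fits [fit_standardized_ols()] per parcel (outcome = the parcel's
#' principal-gradient value, predictor = the chosen behavior measure,
#' covariates = sex and motion), applies Benjamini-Hochberg FDR over the P
#' parcel p-values, and separately fits the gradient range (its own single
#' test, outside the parcel FDR family).
#'
#' @param gradients named list of aligned [gradient_set()], one per subject
#'   (names = subject ids).
#' @param behavior data frame with columns `subject_id`, the predictor
#'   column, `sex`, `motion`.
#' @param predictor name of the behavior column to use (e.g. `"age_proxy"`).
#' @param partition data frame `(parcel_id, class)` for the range outcome.
#' @param fdr_q FDR threshold over parcels.
#' @return data frame with one row per parcel plus a `"RANGE"` row:
#'   `parcel_id`, `predictor`, `beta_std`, `p_value`, `q_fdr`,
#'   `significant`. Attribute `n_used` records the analyzed sample size.
#' @export
regional_association_map <- function(gradients, behavior, predictor,
                                     partition, fdr_q = 0.05) {
  if (!predictor %in% names(behavior))
    stop_fc("behavior table has no column '%s'", predictor)
  common <- intersect(names(gradients), behavior$subject_id)
  dropped <- setdiff(union(names(gradients), behavior$subject_id), common)
  # listwise deletion on the analysis columns
  beh <- behavior[match(common, behavior$subject_id), , drop = FALSE]
  cc <- stats::complete.cases(beh[, c(predictor, "sex", "motion")])
  beh <- beh[cc, , drop = FALSE]
  common <- beh$subject_id
  if (length(dropped) > 0 || any(!cc))
    message(sprintf("associations: %d subject(s) dropped (no overlap or missing behavior)",
                    length(dropped) + sum(!cc)))
  g <- gradients[common]
  if (!all(vapply(g, function(x) isTRUE(x$aligned), TRUE)))
    stop_fc("all gradient sets must be aligned")
  p <- nrow(g[[1]]$coordinates)
  if (length(common) <= 5)
    stop_fc("too few overlapping subjects (%d)", length(common))
  coords <- t(vapply(g, function(x) x$coordinates[, 1], numeric(p)))
  colnames(coords) <- rownames(g[[1]]$coordinates)
  covs <- beh[, c("sex", "motion")]
  pred <- as.numeric(beh[[predictor]])
  fits <- apply(coords, 2, fit_standardized_ols, predictor = pred,
                covariates = covs)
  fdr <- bh_fdr(fits["p_value", ], q = fdr_q)
  out <- data.frame(parcel_id = colnames(coords), predictor = predictor,
                    beta_std = unname(fits["beta_std", ]),
                    p_value = unname(fits["p_value", ]),
                    q_fdr = fdr$q_values, significant = fdr$significant,
                    stringsAsFactors = FALSE)
  ranges <- vapply(g, function(x) gradient_range(x, partition)$value, 0)
  rfit <- fit_standardized_ols(ranges, pred, covs)
  out <- rbind(out, data.frame(parcel_id = "RANGE", predictor = predictor,
                               beta_std = unname(rfit["beta_std"]),
                               p_value = unname(rfit["p_value"]),
                               q_fdr = unname(rfit["p_value"]),
                               significant = rfit["p_value"] < fdr_q,
                               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  attr(out, "n_used") <- length(common)
  out
}
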