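#' Construct a parcellated fMRI scan
#'
#' Container for one scan's parcellated time series: a timepoints x parcels
#' matrix plus repetition time, a censor mask marking frames to keep, an
#' optional task event table, and an optional nuisance regressor matrix.
#'
#' @param subject_id character subject identifier.
#' @param session `"test"` or `"retest"`.
#' @param scan_label character label unique within (subject, session).
#' @param scan_class `"rest"` or `"task"`.
#' @param data numeric matrix, timepoints x parcels; column names are parcel
#'   IDs. No missing values are allowed.
#' @param tr_seconds repetition time in seconds.
#' @param censor_mask logical vector, one entry per timepoint; `TRUE` = keep.
#'   Defaults to keeping every frame.
#' @param events optional data frame with columns `onset_seconds`,
#'   `duration_seconds`, `condition`; only allowed for task scans.
#' @param nuisance optional timepoints x q numeric matrix of nuisance
#'   regressors (motion parameters, tissue signals, ...).
#' @return An object of class `parcellated_scan`.
#' @export
parcellated_scan <- function(subject_id, session, scan_label, scan_class,
                             data, tr_seconds,
                             censor_mask = NULL, events = NULL,
                             nuisance = NULL) {
  data <- as.matrix(data)
  if (anyNA(data)) stop_fc("scan %s/%s/%s: data contains missing values",
                           subject_id, session, scan_label)
  if (!session %in% c("test", "retest"))
    stop_fc("session must be 'test' or 'retest', got '%s'", session)
  if (!scan_class %in% c("rest", "task"))
    stop_fc("scan_class must be 'rest' or 'task', got '%s'", scan_class)
  if (is.null(censor_mask)) censor_mask <- rep(TRUE, nrow(data))
  censor_mask <- as.logical(censor_mask)
  if (length(censor_mask) != nrow(data))
    stop_fc("censor_mask length (%d) != timepoints (%d)",
            length(censor_mask), nrow(data))
  if (!is.null(events)) {
    if (scan_class != "task")
      stop_fc("events are only allowed for task scans (scan %s)", scan_label)
    stopifnot(all(c("onset_seconds", "duration_seconds", "condition") %in%
                    names(events)))
  }
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != nrow(data))
      stop_fc("nuisance rows (%d) != timepoints (%d)",
              nrow(nuisance), nrow(data))
  }
  if (is.null(colnames(data))) colnames(data) <- parcel_ids(ncol(data))
  structure(
    list(subject_id = subject_id, session = session, scan_label = scan_label,
         scan_class = scan_class, data = data, tr_seconds = tr_seconds,
         censor_mask = censor_mask, events = events, nuisance = nuisance),
    class = "parcellated_scan")
}

#' @export
print.parcellated_scan <- function(x, ...) {
  cat(sprintf("<parcellated_scan> %s/%s/%s (%s): %d x %d, TR %.3g s, %d/%d frames kept\n",
              x$subject_id, x$session, x$scan_label, x$scan_class,
              nrow(x$data), ncol(x$data), x$tr_seconds,
              sum(x$censor_mask), length(x$censor_mask)))
  invisible(x)
}
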