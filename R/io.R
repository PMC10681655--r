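#' Write a labeled square matrix as delimited text
#'
#' Tab-separated, header row of parcel IDs and a leading `parcel_id` label
#' column; values carry 15 significant digits so a round-trip preserves at
#' least 12.
#'
#' @param m numeric matrix with row/column names.
#' @param path output path.
#' @export
write_matrix <- function(m, path) {
  m <- as.matrix(m)
  if (is.null(colnames(m))) colnames(m) <- parcel_ids(ncol(m))
  if (is.null(rownames(m))) rownames(m) <- colnames(m)
  df <- data.frame(parcel_id = rownames(m),
                   signif(m, 15), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labeled square matrix from delimited text
#'
#' @param path path written by [write_matrix()] (tolerates Windows line
#'   endings).
#' @return numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_fc("%s: not a labeled matrix", path)
  labels <- as.character(df[[1]])
  if (anyDuplicated(labels))
    stop_fc("%s: duplicate parcel ID '%s'", path,
            labels[duplicated(labels)][1])
  ids <- colnames(df)[-1]
  if (anyDuplicated(ids))
    stop_fc("%s: duplicate parcel ID '%s' in header", path,
            ids[duplicated(ids)][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m) || anyNA(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2,
                                              as.numeric))), arr.ind = TRUE)
    stop_fc("%s: non-numeric cell at row %s, column %s", path,
            if (length(bad)) bad[1, 1] else "?",
            if (length(bad)) ids[bad[1, 2]] else "?")
  }
  rownames(m) <- labels
  m
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

write_sidecar <- function(path, info) {
  jsonlite::write_json(info, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a simulated cohort to a directory
#'
#' Layout: one tab-separated timepoints x parcels matrix per scan, a
#' one-column 0/1 censor mask per scan (1 = keep), tab-separated event
#' tables for task scans, `manifest.tsv`, `behavior.tsv`, `partition.tsv`,
#' and `ground_truth.json`.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "scans"), recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (s in cohort$scans) {
    stem <- sprintf("%s_%s_%s", s$subject_id, s$session, s$scan_label)
    data_path <- file.path("scans", paste0(stem, ".tsv"))
    df <- as.data.frame(signif(s$data, 15))
    colnames(df) <- colnames(s$data)
    write_tsv(df, file.path(dir, data_path))
    mask_path <- file.path("scans", paste0(stem, "_mask.tsv"))
    write_tsv(data.frame(keep = as.integer(s$censor_mask)),
              file.path(dir, mask_path))
    events_path <- ""
    if (!is.null(s$events)) {
      events_path <- file.path("scans", paste0(stem, "_events.tsv"))
      write_tsv(s$events, file.path(dir, events_path))
    }
    rows[[length(rows) + 1L]] <-
      data.frame(subject_id = s$subject_id, session = s$session,
                 scan_label = s$scan_label, scan_class = s$scan_class,
                 tr_seconds = s$tr_seconds, data_path = data_path,
                 mask_path = mask_path, events_path = events_path,
                 stringsAsFactors = FALSE)
  }
  write_tsv(do.call(rbind, rows), file.path(dir, "manifest.tsv"))
  write_tsv(cohort$truth$behavior_table, file.path(dir, "behavior.tsv"))
  write_tsv(partition_table(cohort$truth), file.path(dir, "partition.tsv"))
  truth <- cohort$truth
  jsonlite::write_json(
    list(true_gradient = as.list(truth$true_gradient),
         subject_scale = as.list(truth$subject_scale),
         task_parcels = truth$task_parcels,
         seeds_used = truth$seeds_used,
         config = unclass(truth$config)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' Read and validate a cohort manifest
#'
#' @param path path to `manifest.tsv`; referenced files must exist and
#'   (subject, session, scan_label) must be unique.
#' @return the manifest data frame, with a `root` attribute.
#' @export
read_manifest <- function(path) {
  man <- read_tsv(path)
  need <- c("subject_id", "session", "scan_label", "scan_class",
            "tr_seconds", "data_path", "mask_path", "events_path")
  missing_cols <- setdiff(need, names(man))
  if (length(missing_cols) > 0)
    stop_fc("manifest is missing column(s): %s",
            paste(missing_cols, collapse = ", "))
  key <- paste(man$subject_id, man$session, man$scan_label)
  if (anyDuplicated(key))
    stop_fc("duplicate manifest entry: %s", key[duplicated(key)][1])
  root <- dirname(path)
  for (i in seq_len(nrow(man))) {
    for (col in c("data_path", "mask_path", "events_path")) {
      p <- man[[col]][i]
      if (!is.na(p) && nzchar(p) && !file.exists(file.path(root, p)))
        stop_fc("manifest references missing file: %s", p)
    }
  }
  attr(man, "root") <- root
  man
}

#' Load a cohort directory into parcellated scans
#'
#' @param dir cohort directory written by [write_cohort()] (or any
#'   directory following the same manifest schema).
#' @return list with `scans`, `behavior`, `partition`, `manifest`.
#' @export
read_cohort <- function(dir) {
  man <- read_manifest(file.path(dir, "manifest.tsv"))
  scans <- lapply(seq_len(nrow(man)), function(i) {
    data <- as.matrix(read_tsv(file.path(dir, man$data_path[i])))
    mask <- read_tsv(file.path(dir, man$mask_path[i]))$keep == 1
    events <- NULL
    if (nzchar(man$events_path[i] %||% "") && !is.na(man$events_path[i]))
      events <- read_tsv(file.path(dir, man$events_path[i]))
    parcellated_scan(man$subject_id[i], man$session[i], man$scan_label[i],
                     man$scan_class[i], data, man$tr_seconds[i],
                     censor_mask = mask, events = events)
  })
  behavior <- if (file.exists(file.path(dir, "behavior.tsv")))
    read_tsv(file.path(dir, "behavior.tsv")) else NULL
  partition <- if (file.exists(file.path(dir, "partition.tsv")))
    read_tsv(file.path(dir, "partition.tsv")) else NULL
  list(scans = scans, behavior = behavior, partition = partition,
       manifest = man)
}

#' Run the full gradient-reliability pipeline on a cohort directory
#'
#' Chains cleaning, rsFC/GFC assembly, FC computation, group-template
#' construction (Fisher-z mean of the test-session FC), diffusion embedding,
#' Procrustes alignment, gradient range, test-retest reliability (when a
#' retest session is present), and behavior associations (when a behavior
#' table is present). Every numeric artifact is written with a JSON sidecar
#' recording configuration and seed.
#'
#' @param cohort_dir directory following the [write_cohort()] layout.
#' @param out_dir output directory.
#' @param config named list of pipeline settings; unset entries take the
#'   defaults `list(band = c(0.008, NA), fir_window_seconds = 24, density =
#'   0.10, n_components = 10, alpha = 0.5, diffusion_time = 0, minutes =
#'   "all", fdr_q = 0.05, predictors = c("age_proxy", "cognition_proxy"),
#'   seed = 1)`.
#' @return invisibly, a list with the main in-memory results (`template`,
#'   `gradients`, `reliability`, `associations`, `log`).
#' @export
run_pipeline <- function(cohort_dir, out_dir, config = list()) {
  defaults <- list(band = c(0.008, NA), fir_window_seconds = 24,
                   density = 0.10, n_components = 10, alpha = 0.5,
                   diffusion_time = 0, minutes = "all", fdr_q = 0.05,
                   predictors = c("age_proxy", "cognition_proxy"),
                   seed = 1L)
  cfg <- utils::modifyList(defaults, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
    message(sprintf(...))
  }

  cohort <- read_cohort(cohort_dir)
  n_in <- length(unique(vapply(cohort$scans, `[[`, "", "subject_id")))
  cleaned <- list()
  excluded <- character(0)
  for (s in cohort$scans) {
    res <- tryCatch(clean_timeseries(s, cfg$band, cfg$fir_window_seconds),
                    error = function(e) e)
    if (inherits(res, "error")) {
      excluded <- union(excluded, s$subject_id)
      note("excluding subject %s: %s", s$subject_id, conditionMessage(res))
    } else cleaned[[length(cleaned) + 1L]] <- res
  }
  cleaned <- Filter(function(s) !s$subject_id %in% excluded, cleaned)
  note("cleaning: %d subjects in, %d excluded", n_in, length(excluded))

  by_subj <- split_scans(cleaned)
  sessions_present <- unique(vapply(cleaned, `[[`, "", "session"))
  has_retest <- all(c("test", "retest") %in% sessions_present)

  # the template anchors alignment; build it from test-session rsFC
  test_fcs <- list()
  for (s in names(by_subj)) {
    ts <- assemble_modality(by_subj[[s]][["test"]], "rsFC", cfg$minutes,
                            seed = derive_seed(cfg$seed, "assemble", s,
                                               "test", "rsFC", cfg$minutes))
    test_fcs[[s]] <- compute_fc(ts, "rsFC", NA, s, "test")
  }
  template <- build_group_template(test_fcs, cohort$partition, cfg$density,
                                   cfg$n_components, cfg$alpha,
                                   cfg$diffusion_time)
  tcoord <- template$coordinates
  df_t <- data.frame(parcel_id = rep(rownames(tcoord), ncol(tcoord)),
                     component = rep(seq_len(ncol(tcoord)),
                                     each = nrow(tcoord)),
                     value = as.vector(tcoord))
  write_tsv(df_t, file.path(out_dir, "template_gradients.tsv"))
  write_sidecar(file.path(out_dir, "template_gradients.tsv"),
                list(config = cfg, eigenvalues = template$eigenvalues,
                     variance_explained = template$variance_explained))

  results <- list(template = template, log = NULL)
  for (modality in c("rsFC", "GFC")) {
    meas <- list(test = session_measures(by_subj, "test", modality,
                                         cfg$minutes, template,
                                         cohort$partition, cfg$density,
                                         cfg$n_components, cfg$alpha,
                                         cfg$diffusion_time, cfg$seed))
    if (has_retest)
      meas$retest <- session_measures(by_subj, "retest", modality,
                                      cfg$minutes, template,
                                      cohort$partition, cfg$density,
                                      cfg$n_components, cfg$alpha,
                                      cfg$diffusion_time, cfg$seed)
    for (sess in names(meas)) {
      for (s in names(meas[[sess]]$fcs)) {
        fp <- file.path(out_dir, sprintf("fc_%s_%s_%s.tsv", modality, s, sess))
        write_matrix(meas[[sess]]$fcs[[s]]$values, fp)
        write_sidecar(fp, list(subject = s, session = sess,
                               modality = modality,
                               minutes_used = meas[[sess]]$fcs[[s]]$minutes_used,
                               seed = cfg$seed))
      }
    }
    grad_rows <- do.call(rbind, lapply(names(meas), function(sess) {
      do.call(rbind, lapply(names(meas[[sess]]$gradients), function(s)
        data.frame(subject_id = s, session = sess,
                   parcel_id = rownames(meas[[sess]]$gradients[[s]]$coordinates),
                   value = meas[[sess]]$gradients[[s]]$coordinates[, 1],
                   range = meas[[sess]]$ranges[[s]],
                   stringsAsFactors = FALSE)))
    }))
    fp <- file.path(out_dir, sprintf("gradients_%s.tsv", modality))
    write_tsv(grad_rows, fp)
    write_sidecar(fp, list(modality = modality, config = cfg))

    if (has_retest) {
      edge <- edgewise_parcel_icc(meas$test$fcs, meas$retest$fcs)
      thr <- thresholded_edgewise_parcel_icc(meas$test$fcs, meas$retest$fcs,
                                             cfg$density)
      grad <- gradient_parcel_icc(meas$test$gradients, meas$retest$gradients)
      rel <- rbind(
        data.frame(parcel_id = names(edge), measure = "edgewise_mean",
                   modality = modality, icc = unname(edge)),
        data.frame(parcel_id = names(thr),
                   measure = "thresholded_edgewise_mean",
                   modality = modality, icc = unname(thr)),
        data.frame(parcel_id = names(grad), measure = "gradient",
                   modality = modality, icc = unname(grad)))
      fp <- file.path(out_dir, sprintf("reliability_%s.tsv", modality))
      write_tsv(rel, fp)
      write_sidecar(fp, list(modality = modality, config = cfg))
      rng <- data.frame(modality = modality,
                        icc = range_icc(meas$test$ranges, meas$retest$ranges))
      write_tsv(rng, file.path(out_dir,
                               sprintf("range_icc_%s.tsv", modality)))
      results$reliability[[modality]] <-
        list(parcel = rel, range_icc = rng$icc)
    } else if (modality == "rsFC") {
      note("reliability stage skipped: no retest session in manifest")
    }

    if (!is.null(cohort$behavior)) {
      for (pred in intersect(cfg$predictors, names(cohort$behavior))) {
        assoc <- regional_association_map(meas$test$gradients,
                                          cohort$behavior, pred,
                                          cohort$partition, cfg$fdr_q)
        fp <- file.path(out_dir,
                        sprintf("associations_%s_%s.tsv", modality, pred))
        write_tsv(assoc, fp)
        write_sidecar(fp, list(modality = modality, predictor = pred,
                               n_used = attr(assoc, "n_used"),
                               config = cfg))
        results$associations[[modality]][[pred]] <- assoc
      }
    }
    results$gradients[[modality]] <- meas
  }
  writeLines(log_lines, file.path(out_dir, "pipeline_log.txt"))
  results$log <- log_lines
  invisible(results)
}
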