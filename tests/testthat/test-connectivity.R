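test_that("FIR regressors are lagged 0/1 indicators", {
  ev <- data.frame(onset_seconds = 0, duration_seconds = 2, condition = "A")
  m <- build_fir_regressors(ev, 10, 2, 6)
  expect_equal(dim(m), c(10L, 3L))
  expect_equal(which(m[, 1] == 1), 1L)
  expect_equal(which(m[, 2] == 1), 2L)
  expect_equal(which(m[, 3] == 1), 3L)
  expect_equal(colSums(m), c(A_lag0 = 1, A_lag1 = 1, A_lag2 = 1))

  # overlapping events of one condition stay 0/1 (indicator, not sum)
  ev2 <- data.frame(onset_seconds = c(0, 2), duration_seconds = 2,
                    condition = "A")
  m2 <- build_fir_regressors(ev2, 10, 2, 6)
  expect_true(all(m2 %in% c(0, 1)))

  expect_equal(ncol(build_fir_regressors(NULL, 10, 2, 6)), 0L)
  expect_error(build_fir_regressors(
    data.frame(onset_seconds = 100, duration_seconds = 1, condition = "A"),
    10, 2, 6), "within the scan")
})

test_that("FIR regressors match a brute-force membership scan", {
  set.seed(10)
  for (rep in 1:5) {
    tr <- sample(c(1, 2), 1)
    tp <- 40
    ev <- data.frame(
      onset_seconds = sort(runif(4, 0, tp * tr - 10)),
      duration_seconds = runif(4, 1, 5),
      condition = sample(c("A", "B"), 4, replace = TRUE))
    win <- 12
    m <- build_fir_regressors(ev, tp, tr, win)
    n_lags <- ceiling(win / tr)
    # brute force over every (timepoint, condition, lag) triple
    for (cond in unique(ev$condition)) {
      for (lag in 0:(n_lags - 1)) {
        nm <- sprintf("%s_lag%d", cond, lag)
        expected <- sapply(0:(tp - 1), function(t) {
          any(sapply(ev$onset_seconds[ev$condition == cond], function(on)
            t * tr >= on + lag * tr && t * tr < on + (lag + 1) * tr))
        })
        if (nm %in% colnames(m)) {
          expect_equal(unname(m[, nm]), as.numeric(expected))
        } else {
          expect_true(all(!expected))  # dropped columns were all zero
        }
      }
    }
  }
})

test_that("cleaning with an intercept-only design demeans kept frames", {
  set.seed(2)
  x <- matrix(rnorm(200 * 5), 200, 5)
  mask <- rep(TRUE, 200); mask[sample(200, 20)] <- FALSE
  scan <- parcellated_scan("s1", "test", "rest1", "rest", x, 2,
                          censor_mask = mask)
  out <- clean_timeseries(scan, band = NULL)
  expect_equal(nrow(out$data), 180)
  expect_equal(out$data, scale(x[mask, ], scale = FALSE),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("high-pass cleaning removes slow drift almost exactly", {
  tp <- 250; tr <- 2                       # 500 s scan: 0.004 Hz = bin 2
  t_sec <- (0:(tp - 1)) * tr
  drift <- sin(2 * pi * 0.004 * t_sec)
  x <- matrix(drift, tp, 3)
  scan <- parcellated_scan("s1", "test", "rest1", "rest", x, tr)
  out <- clean_timeseries(scan, band = c(0.008, NA))
  expect_lt(var(out$data[, 1]) / var(x[, 1]), 1e-10)
})

test_that("FIR-spanned task signal is removed to numerical zero", {
  tp <- 100; tr <- 2
  ev <- data.frame(onset_seconds = c(20, 80, 140),
                   duration_seconds = 2, condition = "A")
  fir <- build_fir_regressors(ev, tp, tr, 24)
  set.seed(3)
  x <- fir %*% matrix(rnorm(ncol(fir) * 4), ncol(fir), 4)
  scan <- parcellated_scan("s1", "test", "task1", "task", x, tr,
                          events = ev)
  out <- clean_timeseries(scan, band = NULL)
  expect_lt(max(abs(out$data)), 1e-10)
})

test_that("cleaning is a projection (idempotent on an uncensored scan)", {
  # with no censoring the rebuilt design is identical, so cleaning twice
  # must equal cleaning once
  sc <- small_cohort()$scans[[1]]
  sc$censor_mask[] <- TRUE
  once <- clean_timeseries(sc, band = c(0.008, NA))
  twice <- clean_timeseries(once, band = c(0.008, NA))
  expect_equal(twice$data, once$data, tolerance = 1e-8)
})

test_that("filtering result is invariant to censored-frame placement for in-band noise", {
  # white noise restricted to the passband is orthogonal to the removed
  # basis in expectation; residual variance must not depend on where the
  # censored frames fall
  tp <- 200; tr <- 2
  set.seed(4)
  x <- matrix(rnorm(tp * 6), tp, 6)
  ratios <- sapply(1:6, function(r) {
    set.seed(100 + r)
    mask <- rep(TRUE, tp); mask[sample(tp, 20)] <- FALSE
    scan <- parcellated_scan("s1", "test", "rest1", "rest", x, tr,
                            censor_mask = mask)
    out <- clean_timeseries(scan, band = c(0.008, 0.1))
    mean(apply(out$data, 2, var)) / mean(apply(x[mask, ], 2, var))
  })
  expect_lt(max(ratios) - min(ratios), 0.05)
})

test_that("cleaning fails informatively when censoring leaves too few frames", {
  sc <- small_cohort()$scans[[1]]
  sc$censor_mask[] <- FALSE
  sc$censor_mask[1:5] <- TRUE
  expect_error(clean_timeseries(sc), "degrees of freedom")
})

test_that("equal allocation takes matching frames from every scan", {
  mk <- function(n, label) parcellated_scan("s1", "test", label, "rest",
                                            matrix(seq_len(n * 2), n, 2), 2)
  scans <- lapply(1:8, function(i) mk(150, paste0("r", i)))  # 5 min each
  out <- subsample_timepoints(scans, 16, seed = 1)           # 480 frames
  expect_equal(nrow(out), 480)
  # 60 earliest frames from each scan, in order
  expect_equal(out[1:60, 1], as.numeric(1:60))
  expect_equal(out[61:120, 1], as.numeric(1:60))

  single <- mk(100, "r1")
  expect_equal(subsample_timepoints(list(single), 100 * 2 / 60, seed = 1),
               single$data, ignore_attr = TRUE)
  expect_error(subsample_timepoints(scans, 100, seed = 1), "insufficient")
})

test_that("mixed-length allocation matches the brute-force allocate-then-fill oracle", {
  lens <- c(300, 120, 80, 200, 60, 150, 90, 110)
  mk <- function(n, i) {
    m <- matrix(0, n, 1)
    m[, 1] <- i * 1000 + seq_len(n)    # frame identity encoded in value
    parcellated_scan("s1", "test", paste0("r", i), "rest", m, 2)
  }
  scans <- lapply(seq_along(lens), function(i) mk(lens[i], i))
  for (minutes in c(10, 20, 30)) {
    n_target <- round(minutes * 60 / 2)
    out <- subsample_timepoints(scans, minutes, seed = 9)
    expect_equal(nrow(out), n_target)
    got_per_scan <- table(factor(out[, 1] %/% 1000,
                                 levels = seq_along(lens)))
    want <- oracle_allocation(lens, n_target, seed = 9)
    expect_equal(as.integer(got_per_scan), as.integer(want))
    # deterministic under the same seed
    expect_identical(out, subsample_timepoints(scans, minutes, seed = 9))
  }
})

test_that("modality assembly selects scan classes and concatenates kept frames", {
  cleaned <- small_cleaned()
  sub1 <- Filter(function(s) s$subject_id == "sub001" &&
                   s$session == "test", cleaned)
  rest <- Filter(function(s) s$scan_class == "rest", sub1)
  rs <- assemble_modality(sub1, "rsFC", "all")
  expect_equal(rs, do.call(rbind, lapply(rest, `[[`, "data")),
               ignore_attr = TRUE)
  gf <- assemble_modality(sub1, "GFC", "all")
  expect_equal(nrow(gf), sum(vapply(sub1, function(s) nrow(s$data), 0L)))
  task_only <- Filter(function(s) s$scan_class == "task", sub1)
  expect_error(assemble_modality(task_only, "rsFC"), "no rest")
})

test_that("Pearson FC matches the direct formula and enforces its invariants", {
  x <- matrix(c(1, 2, 4, 3, 5,
                2, 1, 3, 5, 4,
                5, 3, 1, 2, 4), 5, 3)
  fc <- compute_fc(x)
  for (i in 1:3) for (j in 1:3)
    expect_equal(fc$values[i, j],
                 if (i == j) 1 else oracle_pearson(x[, i], x[, j]),
                 tolerance = 1e-12)
  # identical and sign-flipped columns
  y <- cbind(a = x[, 1], b = x[, 1], c = -x[, 1] + 10)
  fc2 <- compute_fc(y)
  expect_equal(fc2$values["a", "b"], 1)
  expect_equal(fc2$values["a", "c"], -1)
  expect_error(compute_fc(cbind(x, k = rep(2, 5))), "constant")
  # invariants on random input
  set.seed(6)
  fc3 <- compute_fc(matrix(rnorm(300), 30, 10))
  expect_equal(fc3$values, t(fc3$values))
  expect_equal(unname(diag(fc3$values)), rep(1, 10))
  expect_true(all(fc3$values >= -1 & fc3$values <= 1))
})

test_that("FC estimation error shrinks with scan length", {
  truth <- small_cohort()$truth
  sigma <- subject_covariance(truth, "sub001", "test")
  cl <- chol(sigma)
  p <- nrow(sigma)
  errs <- sapply(c(100, 400, 1600, 6400), function(tp) {
    set.seed(11)
    x <- matrix(rnorm(tp * p), tp, p) %*% cl
    mean(abs(cor(x) - sigma))
  })
  expect_true(all(diff(errs) <= 0))
})
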