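test_that("row sparsification keeps the strongest edges with the lower-index tie rule", {
  set.seed(21)
  m <- matrix(runif(121), 11, 11); m <- (m + t(m)) / 2; diag(m) <- 1
  s <- sparsify_rows(m, 0.10)
  expect_true(all(rowSums(s != 0) == 1))   # ceil(0.1 * 10) = 1
  expect_equal(unname(diag(s)), rep(0, 11))

  sfull <- sparsify_rows(m, 1)
  expect_equal(unname(sfull), unname(m - diag(diag(m))))

  # brute-force oracle on random matrices, including deliberate ties
  for (seed in 1:8) {
    set.seed(seed)
    a <- matrix(sample(1:5, 64, replace = TRUE) / 5, 8, 8)
    diag(a) <- 1
    expect_equal(sparsify_rows(a, 0.25), oracle_sparsify(a, 0.25))
  }
})

test_that("normalized-angle affinity maps aligned, orthogonal, and opposite profiles to 1, 0.5, 0", {
  s <- rbind(c(1, 2, 0, 0),
             c(1, 2, 0, 0),
             c(0, 0, 3, 0),
             c(-1, -2, 0, 0))
  a <- affinity_normalized_angle(s)
  expect_equal(a$values[1, 2], 1)
  expect_equal(a$values[1, 3], 0.5)
  expect_equal(a$values[1, 4], 0)
  expect_equal(a$values, t(a$values))
  expect_true(all(a$values >= 0 & a$values <= 1))
  expect_error(affinity_normalized_angle(rbind(c(1, 1), c(0, 0))),
               "all-zero")
  # brute-force per-pair oracle
  set.seed(31)
  sp <- sparsify_rows(random_affinity(12, 31), 0.3)
  expect_equal(affinity_normalized_angle(sp)$values, oracle_affinity(sp),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("diffusion embedding separates a two-block affinity and matches the dense oracle", {
  blocks <- matrix(0.1, 6, 6)
  blocks[1:3, 1:3] <- 0.9
  blocks[4:6, 4:6] <- 0.9
  diag(blocks) <- 1
  g <- diffusion_embedding(blocks, n_components = 3)
  pc1 <- g$coordinates[, 1]
  expect_true(all(sign(pc1[1:3]) == sign(pc1[1])))
  expect_true(all(sign(pc1[4:6]) == -sign(pc1[1])))
  o <- oracle_diffusion(blocks, n_components = 3)
  for (j in seq_len(ncol(g$coordinates))) {
    d <- min(max(abs(g$coordinates[, j] - o$coordinates[, j])),
             max(abs(g$coordinates[, j] + o$coordinates[, j])))
    expect_lt(d, 1e-8)
  }
  expect_equal(g$eigenvalues, o$eigenvalues, tolerance = 1e-10)
})

test_that("embedding is equivariant under simultaneous row/column permutation", {
  a <- random_affinity(15, 41)
  g <- diffusion_embedding(a, n_components = 4)
  set.seed(42)
  perm <- sample(15)
  gp <- diffusion_embedding(a[perm, perm], n_components = 4)
  expect_equal(gp$eigenvalues, g$eigenvalues, tolerance = 1e-10)
  for (j in 1:4) {
    d <- min(max(abs(gp$coordinates[, j] - g$coordinates[perm, j])),
             max(abs(gp$coordinates[, j] + g$coordinates[perm, j])))
    expect_lt(d, 1e-8)
  }
})

test_that("alpha = 0, diffusion time 1 reduces to the plain random-walk eigenvectors scaled by lambda", {
  a <- random_affinity(12, 51)
  g <- diffusion_embedding(a, n_components = 5, alpha = 0,
                           diffusion_time = 1)
  o <- oracle_diffusion(a, n_components = 5, alpha = 0, diffusion_time = 1)
  for (j in 1:5) {
    d <- min(max(abs(g$coordinates[, j] - o$coordinates[, j])),
             max(abs(g$coordinates[, j] + o$coordinates[, j])))
    expect_lt(d, 1e-8)
  }
})

test_that("disconnected affinity graphs are rejected with a component count", {
  a <- matrix(0, 6, 6)
  a[1:3, 1:3] <- 0.8
  a[4:6, 4:6] <- 0.8
  diag(a) <- 1
  expect_error(diffusion_embedding(a), "2 components")
})

test_that("embedding spectrum is well-formed", {
  a <- random_affinity(20, 61)
  g <- diffusion_embedding(a, n_components = 8)
  expect_equal(sum(g$variance_explained), 1)
  expect_true(all(g$eigenvalues > 0 & g$eigenvalues <= 1))
  expect_false(is.unsorted(rev(g$eigenvalues)))
  # principal eigenvector orthogonal to the constant under the stationary
  # inner product of the random-walk operator
  d <- rowSums(a)
  w <- a / outer(d^0.5, d^0.5)
  pi_st <- rowSums(w) / sum(rowSums(w))
  expect_lt(abs(sum(pi_st * g$coordinates[, 1])), 1e-8)
})

test_that("group template equals the single-matrix embedding up to partition re-signing", {
  fcs <- study_fcs("test")
  part <- partition_table(study_cohort()$truth)
  single <- build_group_template(fcs[1], part)
  direct <- diffusion_embedding(affinity_normalized_angle(
    sparsify_rows(fcs[[1]]$values, 0.1)))
  expect_equal(abs(single$coordinates[, 1]), abs(direct$coordinates[, 1]),
               tolerance = 1e-10)
  cls <- part$class[match(rownames(single$coordinates), part$parcel_id)]
  pc1 <- single$coordinates[, 1]
  expect_gt(mean(pc1[cls == "heteromodal"]), mean(pc1[cls == "unimodal"]))
  # averaging identical matrices changes nothing
  rep3 <- build_group_template(fcs[c(1, 1, 1)], part)
  expect_equal(rep3$coordinates, single$coordinates, tolerance = 1e-10)
})

test_that("Fisher-z averaging of opposite matrices cancels off-diagonal structure", {
  r <- 0.6
  m1 <- matrix(r, 4, 4); diag(m1) <- 1
  m2 <- matrix(-r, 4, 4); diag(m2) <- 1
  avg <- fcgrad:::fisher_mean_fc(list(m1, m2))
  off <- avg[upper.tri(avg)]
  expect_equal(unname(off), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(diag(avg)), rep(1, 4))
  # and the general case matches direct atanh/tanh arithmetic
  m3 <- matrix(0.3, 4, 4); diag(m3) <- 1
  avg2 <- fcgrad:::fisher_mean_fc(list(m1, m3))
  expect_equal(avg2[1, 2], tanh((atanh(0.6) + atanh(0.3)) / 2))
})

test_that("Procrustes alignment recovers a known orthogonal rotation", {
  tmpl <- study_template()
  selfal <- procrustes_align(tmpl, tmpl)
  expect_equal(selfal$coordinates, tmpl$coordinates, tolerance = 1e-10)
  expect_equal(unname(attr(selfal, "disparity")["after"]), 0,
               tolerance = 1e-8)
  for (seed in c(1, 2, 3)) {
    q <- random_orthogonal(ncol(tmpl$coordinates), seed)
    rotated <- tmpl
    rotated$coordinates <- tmpl$coordinates %*% q
    back <- procrustes_align(rotated, tmpl)
    expect_lt(max(abs(back$coordinates - tmpl$coordinates)), 1e-8)
  }
})

test_that("alignment never increases disparity and pulls noisy embeddings together", {
  tmpl <- study_template()
  fcs <- study_fcs("test")
  g1 <- diffusion_embedding(affinity_normalized_angle(
    sparsify_rows(fcs[[1]]$values, 0.1)))
  g2 <- diffusion_embedding(affinity_normalized_angle(
    sparsify_rows(fcs[[2]]$values, 0.1)))
  a1 <- procrustes_align(g1, tmpl)
  a2 <- procrustes_align(g2, tmpl)
  d1 <- attr(a1, "disparity")
  expect_lte(d1["after"], d1["before"])
  before <- norm(g1$coordinates - g2$coordinates, "F")
  after <- norm(a1$coordinates - a2$coordinates, "F")
  expect_lt(after, before)
})

test_that("gradient range is the heteromodal minus unimodal mean", {
  part <- data.frame(parcel_id = sprintf("p%03d", 1:6),
                     class = c("unimodal", "unimodal", rep("heteromodal", 4)))
  mk <- function(v) {
    co <- matrix(v, ncol = 1, dimnames = list(part$parcel_id, NULL))
    gradient_set(co, 0.5, 1, aligned = TRUE, template_id = "t")
  }
  expect_equal(gradient_range(mk(c(-3, -3, 4, 4, 4, 4)), part)$value, 7)
  expect_equal(gradient_range(mk(rep(2, 6)), part)$value, 0)
  toy <- mk(c(0.1, 0.5, 1.0, 2.0, -1.0, 0.4))
  expect_equal(gradient_range(toy, part)$value,
               mean(c(1, 2, -1, 0.4)) - mean(c(0.1, 0.5)))
  un <- mk(1:6); un$aligned <- FALSE
  expect_error(gradient_range(un, part), "aligned")
})

test_that("template recovers the planted hierarchy and contraction shrinks the measured range", {
  coh <- study_cohort()
  tmpl <- study_template()
  rho <- cor(tmpl$coordinates[, 1], coh$truth$true_gradient,
             method = "spearman")
  expect_gte(abs(rho), 0.9)
  # more latent disorder (lower hierarchy coherence a_s) -> smaller range,
  # through the full measurement chain with fixed seeds
  part <- partition_table(coh$truth)
  truth <- coh$truth
  p <- truth$config$n_parcels
  u <- truth$subject_offsets["sub001", ] *
    truth$subject_scale[["sub001"]] / truth$config$disorder_scale
  ranges <- sapply(c(0.25, 0.5, 1.0), function(a) {
    truth$subject_offsets["sub001", ] <- (truth$config$disorder_scale / a) * u
    sigma <- subject_covariance(truth, "sub001", "test")
    cl <- chol(sigma + 1e-10 * diag(p))
    set.seed(202)
    x <- matrix(rnorm(800 * p), 800, p) %*% cl +
      matrix(rnorm(800 * p, 0, truth$config$measurement_noise_sd), 800, p)
    colnames(x) <- names(truth$true_gradient)
    gradient_range(derive_gradients(compute_fc(x), tmpl), part)$value
  })
  expect_true(all(diff(ranges) > 0))
})
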