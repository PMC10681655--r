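# Independent brute-force oracles. Each re-implements a definition from
# first principles, by a different route than the package, for use as the
# reference in equivalence tests.

# ICC(3,1) from the raw two-way ANOVA definition, with explicit loops over
# cells (no matrix shortcuts).
oracle_icc31 <- function(x) {
  n <- nrow(x)
  k <- ncol(x)
  grand <- sum(x) / (n * k)
  row_means <- sapply(seq_len(n), function(i) sum(x[i, ]) / k)
  col_means <- sapply(seq_len(k), function(j) sum(x[, j]) / n)
  ss_total <- 0
  for (i in seq_len(n)) for (j in seq_len(k))
    ss_total <- ss_total + (x[i, j] - grand)^2
  ss_between_subj <- k * sum((row_means - grand)^2)
  ss_between_sess <- n * sum((col_means - grand)^2)
  ss_resid <- ss_total - ss_between_subj - ss_between_sess
  bms <- ss_between_subj / (n - 1)
  ems <- ss_resid / ((n - 1) * (k - 1))
  (bms - ems) / (bms + (k - 1) * ems)
}

# Dense eigendecomposition of the alpha-normalized random-walk operator
# M = D_W^-1 W, W = D^-a A D^-a, using base eigen() on the NON-symmetric M
# (a different route than the package's symmetric conjugate).
oracle_diffusion <- function(a, n_components = 10, alpha = 0.5,
                             diffusion_time = 0) {
  d <- rowSums(a)
  w <- diag(d^(-alpha)) %*% a %*% diag(d^(-alpha))
  m <- diag(1 / rowSums(w)) %*% w
  e <- eigen(m)
  ord <- order(Re(e$values), decreasing = TRUE)
  lam <- Re(e$values)[ord][-1]
  vec <- Re(e$vectors)[, ord, drop = FALSE][, -1, drop = FALSE]
  k <- min(n_components, sum(lam > 0))
  lam <- lam[seq_len(k)]
  vec <- vec[, seq_len(k), drop = FALSE]
  vec <- sweep(vec, 2, sqrt(colSums(vec^2)), `/`)
  scl <- if (diffusion_time == 0) lam / (1 - lam) else lam^diffusion_time
  coords <- sweep(vec, 2, scl, `*`)
  for (j in seq_len(k)) {
    imax <- which.max(abs(coords[, j]))
    if (coords[imax, j] < 0) coords[, j] <- -coords[, j]
  }
  list(coordinates = coords, eigenvalues = lam)
}

# Row-wise top-density retention by explicit sort-and-cut with the
# lower-index tie rule.
oracle_sparsify <- function(m, density) {
  p <- nrow(m)
  keep_n <- ceiling(density * (p - 1))
  out <- matrix(0, p, p, dimnames = dimnames(m))
  for (i in seq_len(p)) {
    idx <- setdiff(seq_len(p), i)
    ord <- idx[order(-m[i, idx], idx)]
    sel <- ord[seq_len(keep_n)]
    out[i, sel] <- m[i, sel]
  }
  out
}

# Normalized-angle affinity by explicit per-pair cosine computation.
oracle_affinity <- function(s) {
  p <- nrow(s)
  a <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    cs <- sum(s[i, ] * s[j, ]) /
      (sqrt(sum(s[i, ]^2)) * sqrt(sum(s[j, ]^2)))
    a[i, j] <- 1 - acos(max(-1, min(1, cs))) / pi
  }
  diag(a) <- 1
  a
}

# Benjamini-Hochberg step-up from the definition: q_(i) = min_{j >= i}
# m * p_(j) / j, mapped back to input order.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(sapply(i:m, function(j) m * ps[j] / j))
  }
  q[q > 1] <- 1
  out <- numeric(m)
  out[ord] <- q
  out
}

# Paired t from the closed form.
oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), n - 1))
}

# Welch two-sample t from the closed form.
oracle_welch_t <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# Pearson r from the definition.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Equal-allocation-then-random-fill arithmetic, re-implemented.
oracle_allocation <- function(avail, n_target, seed) {
  n_scans <- length(avail)
  base <- floor(n_target / n_scans)
  contrib <- pmin(base, avail)
  shortfall <- n_target - sum(contrib)
  extra <- rep(0L, n_scans)
  if (shortfall > 0) {
    pool_scan <- integer(0)
    for (i in seq_len(n_scans))
      pool_scan <- c(pool_scan, rep(i, avail[i] - contrib[i]))
    set.seed(seed)
    pick <- sample.int(length(pool_scan), shortfall)
    for (k in pick) extra[pool_scan[k]] <- extra[pool_scan[k]] + 1L
  }
  contrib + extra
}

# Random symmetric affinity-like matrix (unit diagonal, entries in [0, 1])
# with a connected positive graph.
random_affinity <- function(p, seed) {
  set.seed(seed)
  a <- matrix(runif(p * p, 0.05, 1), p, p)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}

random_orthogonal <- function(k, seed) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(k * k), k, k)))
}
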