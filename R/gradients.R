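#' Row-wise sparsification of a connectivity matrix
#'
#' Per row, the `ceil(density * (P - 1))` largest off-diagonal values are
#' retained (values kept, not binarized) and everything else, including the
#' diagonal, is set to zero. Ties at the cutoff are broken in favor of the
#' lower parcel index, so the operation is deterministic. The result is in
#' general non-symmetric.
#'
#' @param fc a [connectivity_matrix()] or plain square matrix.
#' @param density proportion of off-diagonal entries to keep per row,
#'   in (0, 1].
#' @return P x P numeric matrix.
#' @export
sparsify_rows <- function(fc, density = 0.10) {
  m <- if (inherits(fc, "connectivity_matrix")) fc$values else as.matrix(fc)
  p <- nrow(m)
  if (density <= 0 || density > 1) stop_fc("density must be in (0, 1]")
  keep_n <- ceiling(density * (p - 1))
  out <- matrix(0, p, p, dimnames = dimnames(m))
  for (i in seq_len(p)) {
    vals <- m[i, ]
    vals[i] <- -Inf                      # never keep the diagonal
    ord <- order(vals, decreasing = TRUE)  # ties -> lower index first
    keep <- ord[seq_len(keep_n)]
    out[i, keep] <- m[i, keep]
  }
  out
}

#' Normalized-angle affinity between connectivity profiles
#'
#' `a_ij = 1 - arccos(cos_sim(row_i, row_j)) / pi`, the cosine angle between
#' the (sparsified) connectivity profiles of parcels i and j rescaled to
#' `[0, 1]`. Identical profiles give 1, orthogonal profiles 0.5, opposite
#' profiles 0.
#'
#' @param sparse P x P matrix (typically from [sparsify_rows()]); no
#'   all-zero row allowed.
#' @param density_used optional bookkeeping: the sparsification density that
#'   produced `sparse`.
#' @return object of class `affinity_matrix` with fields `values`,
#'   `kernel_name`, `density_used`.
#' @export
affinity_normalized_angle <- function(sparse, density_used = NA_real_) {
  sparse <- as.matrix(sparse)
  nrm <- sqrt(rowSums(sparse^2))
  if (any(nrm == 0)) {
    bad <- rownames(sparse)[nrm == 0] %||% which(nrm == 0)
    stop_fc("all-zero connectivity profile for parcel(s): %s",
            paste(bad, collapse = ", "))
  }
  cosm <- (sparse %*% t(sparse)) / outer(nrm, nrm)
  cosm <- pmin(pmax(cosm, -1), 1)
  a <- 1 - acos(cosm) / pi
  a <- (a + t(a)) / 2
  diag(a) <- 1
  structure(list(values = a, kernel_name = "normalized_angle",
                 density_used = density_used),
            class = "affinity_matrix")
}

# Number of connected components of the graph with edges where the affinity
# is strictly positive (simple BFS; P is small).
graph_components <- function(a) {
  p <- nrow(a)
  adj <- a > 0
  diag(adj) <- FALSE
  comp <- integer(p)
  n_comp <- 0L
  for (start in seq_len(p)) {
    if (comp[start] != 0L) next
    n_comp <- n_comp + 1L
    queue <- start
    comp[start] <- n_comp
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- n_comp
      queue <- c(queue, nb)
    }
  }
  n_comp
}

#' Construct a gradient set
#'
#' Low-level constructor; most users obtain gradient sets from
#' [diffusion_embedding()] or [build_group_template()].
#'
#' @param coordinates P x k matrix of gradient values (column 1 = principal).
#' @param eigenvalues k non-trivial eigenvalues, non-increasing.
#' @param variance_explained k proportions summing to 1.
#' @param alpha anisotropic normalization exponent.
#' @param diffusion_time diffusion time t (0 = the `lambda/(1-lambda)` scaling).
#' @param aligned logical; whether coordinates are aligned to a template.
#' @param template_id optional identifier of the alignment template.
#' @return object of class `gradient_set`.
#' @export
gradient_set <- function(coordinates, eigenvalues, variance_explained,
                         alpha = 0.5, diffusion_time = 0, aligned = FALSE,
                         template_id = NULL) {
  coordinates <- as.matrix(coordinates)
  stopifnot(ncol(coordinates) == length(eigenvalues),
            length(eigenvalues) == length(variance_explained))
  if (is.unsorted(rev(eigenvalues))) stop_fc("eigenvalues must be non-increasing")
  structure(list(coordinates = coordinates, eigenvalues = eigenvalues,
                 variance_explained = variance_explained, alpha = alpha,
                 diffusion_time = diffusion_time, aligned = aligned,
                 template_id = template_id),
            class = "gradient_set")
}

#' @export
print.gradient_set <- function(x, ...) {
  cat(sprintf("<gradient_set> %d parcels x %d components, alpha=%.2g, t=%.2g, %s\n",
              nrow(x$coordinates), ncol(x$coordinates), x$alpha,
              x$diffusion_time,
              if (x$aligned) paste0("aligned to ", x$template_id %||% "template")
              else "unaligned"))
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = " "), "\n")
  invisible(x)
}

#' Diffusion map embedding of an affinity matrix
#'
#' Forms the anisotropic kernel `W = D^-alpha A D^-alpha` (D = diagonal of
#' row sums of A), the random-walk operator `M = D_W^-1 W`, and
#' eigendecomposes M through its symmetric conjugate
#' `S = D_W^-1/2 W D_W^-1/2`. The trivial constant eigenvector
#' (eigenvalue 1) is dropped; component k is the unit-norm eigenvector
#' `psi_k` scaled by `lambda_k / (1 - lambda_k)` when `diffusion_time = 0`,
#' else by `lambda_k^t`. Before alignment, each column's sign is fixed so
#' its largest-magnitude entry is positive. Variance explained is
#' `lambda_k / sum(lambda_j)` over the retained non-trivial positive
#' eigenvalues.
#'
#' @param affinity an [affinity_normalized_angle()] result (or plain
#'   symmetric non-negative matrix with unit diagonal).
#' @param n_components number of non-trivial components to retain.
#' @param alpha anisotropic normalization exponent (0.5 = density-corrected
#'   Laplace-Beltrami normalization).
#' @param diffusion_time diffusion time t; 0 selects the
#'   `lambda/(1-lambda)` multi-scale scaling.
#' @return a [gradient_set()].
#' @export
diffusion_embedding <- function(affinity, n_components = 10, alpha = 0.5,
                                diffusion_time = 0) {
  a <- if (inherits(affinity, "affinity_matrix")) affinity$values
       else as.matrix(affinity)
  p <- nrow(a)
  nc <- graph_components(a)
  if (nc > 1)
    stop_fc("affinity graph is disconnected (%d components); sparsification too aggressive", nc)
  d <- rowSums(a)
  w <- a / outer(d^alpha, d^alpha)
  dw <- rowSums(w)
  s <- w / outer(sqrt(dw), sqrt(dw))
  s <- (s + t(s)) / 2
  es <- eigen(s, symmetric = TRUE)
  lam <- es$values
  # eigenvectors of M = D_W^-1 W from the symmetric conjugate, unit-norm
  psi <- es$vectors / sqrt(dw)
  psi <- sweep(psi, 2, sqrt(colSums(psi^2)), `/`)
  # drop the trivial lambda ~= 1 constant eigenvector (index 1 after sorting)
  lam <- lam[-1]
  psi <- psi[, -1, drop = FALSE]
  k <- min(n_components, sum(lam > 0))
  lam_k <- lam[seq_len(k)]
  psi_k <- psi[, seq_len(k), drop = FALSE]
  scale_k <- if (diffusion_time == 0) lam_k / (1 - lam_k) else lam_k^diffusion_time
  coords <- sweep(psi_k, 2, scale_k, `*`)
  # sign convention: largest-magnitude entry of each column positive
  for (j in seq_len(k)) {
    imax <- which.max(abs(coords[, j]))
    if (coords[imax, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(a)
  gradient_set(coords, lam_k, lam_k / sum(lam_k), alpha = alpha,
               diffusion_time = diffusion_time, aligned = FALSE)
}

# Fisher-z average of connectivity matrices: z-transform off-diagonal
# entries, average element-wise, back-transform; diagonal restored to 1.
fisher_mean_fc <- function(fc_list) {
  vals <- lapply(fc_list, function(f)
    if (inherits(f, "connectivity_matrix")) f$values else as.matrix(f))
  p <- nrow(vals[[1]])
  if (any(vapply(vals, nrow, 0L) != p))
    stop_fc("connectivity matrices have mixed parcel sets")
  nm <- lapply(vals, rownames)
  if (!all(vapply(nm, identical, TRUE, nm[[1]])))
    stop_fc("connectivity matrices have mixed parcel labels")
  zsum <- Reduce(`+`, lapply(vals, function(v) {
    z <- fisher_z(v)
    diag(z) <- 0
    z
  }))
  m <- tanh(zsum / length(vals))
  diag(m) <- 1
  dimnames(m) <- dimnames(vals[[1]])
  m
}

#' Build the group-level gradient template
#'
#' Fisher-z averages the cohort's connectivity matrices, then runs the
#' sparsify -> normalized-angle affinity -> diffusion embedding chain. The
#' template's principal gradient is re-signed so that its mean over
#' heteromodal parcels exceeds its mean over unimodal parcels, anchoring the
#' orientation of the whole study: individual gradients inherit it through
#' Procrustes alignment.
#'
#' @param fc_matrices list of [connectivity_matrix()] on a common parcel set.
#' @param partition data frame `(parcel_id, class)` with classes `unimodal`
#'   and `heteromodal`, used to anchor the sign.
#' @param density sparsification density.
#' @param n_components components to retain.
#' @param alpha,diffusion_time embedding parameters.
#' @return a [gradient_set()] with `aligned = TRUE` and
#'   `template_id = "group_template"`.
#' @export
build_group_template <- function(fc_matrices, partition, density = 0.10,
                                 n_components = 10, alpha = 0.5,
                                 diffusion_time = 0) {
  stopifnot(length(fc_matrices) >= 1)
  m <- fisher_mean_fc(fc_matrices)
  g <- diffusion_embedding(
    affinity_normalized_angle(sparsify_rows(m, density), density),
    n_components = n_components, alpha = alpha,
    diffusion_time = diffusion_time)
  cls <- partition_classes(partition, rownames(g$coordinates) %||%
                             parcel_ids(nrow(g$coordinates)))
  pc1 <- g$coordinates[, 1]
  if (mean(pc1[cls == "heteromodal"]) < mean(pc1[cls == "unimodal"]))
    g$coordinates[, 1] <- -pc1
  g$aligned <- TRUE
  g$template_id <- "group_template"
  g
}

# Resolve a partition data frame into a class vector ordered like parcel
# ids; validates full single coverage and both classes non-empty.
partition_classes <- function(partition, ids) {
  stopifnot(all(c("parcel_id", "class") %in% names(partition)))
  if (anyDuplicated(partition$parcel_id))
    stop_fc("partition labels a parcel more than once")
  idx <- match(ids, partition$parcel_id)
  if (anyNA(idx))
    stop_fc("partition is missing parcels: %s",
            paste(ids[is.na(idx)][1:min(5, sum(is.na(idx)))], collapse = ", "))
  cls <- partition$class[idx]
  if (!all(cls %in% c("unimodal", "heteromodal")))
    stop_fc("partition classes must be 'unimodal' or 'heteromodal'")
  if (length(unique(cls)) < 2) stop_fc("both partition classes must be non-empty")
  cls
}

#' Procrustes alignment of an individual gradient set to a template
#'
#' Finds the orthogonal matrix R (rotations and reflections; no scaling, no
#' centering) minimizing `||X R - T||_F` via the SVD of `X' T` (`R = U V'`),
#' and applies it to the individual coordinates. Eigenvalues and variance
#' explained are carried through unchanged; the Frobenius disparity to the
#' template before and after alignment is stored in the `disparity`
#' attribute.
#'
#' @param individual unaligned [gradient_set()].
#' @param template template [gradient_set()] with the same P and k.
#' @return the aligned [gradient_set()].
#' @export
procrustes_align <- function(individual, template) {
  x <- individual$coordinates
  tm <- template$coordinates
  if (!all(dim(x) == dim(tm)))
    stop_fc("individual (%d x %d) and template (%d x %d) dimensions differ",
            nrow(x), ncol(x), nrow(tm), ncol(tm))
  sv <- svd(crossprod(x, tm))
  if (min(sv$d) < 1e-12 * max(sv$d))
    warning("rank-deficient cross-product in Procrustes alignment; solution may be unstable")
  r <- sv$u %*% t(sv$v)
  aligned <- x %*% r
  dimnames(aligned) <- dimnames(x)
  out <- individual
  out$coordinates <- aligned
  out$aligned <- TRUE
  out$template_id <- template$template_id %||% "template"
  attr(out, "disparity") <- c(before = norm(x - tm, "F"),
                              after = norm(aligned - tm, "F"))
  out
}

#' Range of the principal gradient
#'
#' Mean principal-gradient value over heteromodal parcels minus the mean
#' over unimodal parcels; larger values indicate a more expanded cortical
#' hierarchy. Only defined for aligned gradients (the value is otherwise not
#' comparable across individuals).
#'
#' @param aligned an aligned [gradient_set()].
#' @param partition data frame `(parcel_id, class)`.
#' @return object of class `range_value`: list with `value`,
#'   `mean_unimodal`, `mean_heteromodal`.
#' @export
gradient_range <- function(aligned, partition) {
  if (!isTRUE(aligned$aligned))
    stop_fc("gradient_range requires an aligned gradient set")
  ids <- rownames(aligned$coordinates) %||% parcel_ids(nrow(aligned$coordinates))
  cls <- partition_classes(partition, ids)
  pc1 <- aligned$coordinates[, 1]
  mu <- mean(pc1[cls == "unimodal"])
  mh <- mean(pc1[cls == "heteromodal"])
  structure(list(value = mh - mu, mean_unimodal = mu, mean_heteromodal = mh),
            class = "range_value")
}

#' Full per-subject gradient derivation
#'
#' Convenience chain: sparsify -> normalized-angle affinity -> diffusion
#' embedding -> Procrustes alignment to a template.
#'
#' @param fc a [connectivity_matrix()].
#' @param template template [gradient_set()].
#' @param density sparsification density.
#' @param n_components,alpha,diffusion_time embedding parameters.
#' @return aligned [gradient_set()].
#' @export
derive_gradients <- function(fc, template, density = 0.10,
                             n_components = 10, alpha = 0.5,
                             diffusion_time = 0) {
  g <- diffusion_embedding(
    affinity_normalized_angle(sparsify_rows(fc, density), density),
    n_components = n_components, alpha = alpha,
    diffusion_time = diffusion_time)
  procrustes_align(g, template)
}
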