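#' Estimate the voxel noise covariance from GLM residuals
#'
#' Run-wise sample covariances of the (per-run centred) residuals are
#' averaged and shrunk toward their diagonal,
#' `Sigma = (1 - lambda) * S + lambda * diag(S)`, which down-weights
#' correlated noise across voxels while preserving voxel variances and
#' guaranteeing positive definiteness for any `lambda > 0`. With
#' `lambda = NULL` the shrinkage intensity is chosen by the analytic
#' optimal-shrinkage formula (Schafer-Strimmer, diagonal target) from the
#' pooled residual samples.
#'
#' @param residuals Samples x voxels matrix, or a list of such matrices (one
#'   per run).
#' @param lambda Shrinkage intensity in `[0, 1]`, or `NULL` for analytic.
#' @return A `noise_cov` object: `sigma`, `lambda`, `dof`.
#' @export
estimate_noise_cov <- function(residuals, lambda = NULL) {
  if (!is.list(residuals)) residuals <- list(residuals)
  residuals <- lapply(residuals, as.matrix)
  if (any(vapply(residuals, nrow, 1L) < 2L)) {
    abort("need at least 2 residual samples per run")
  }
  centred <- lapply(residuals, function(r) sweep(r, 2L, colMeans(r)))
  covs <- lapply(centred, function(r) crossprod(r) / (nrow(r) - 1L))
  S <- Reduce(`+`, covs) / length(covs)
  v <- diag(S)
  if (any(v <= 0)) {
    abort(paste("zero-variance voxel(s) in residuals:",
                paste(which(v <= 0), collapse = ", ")))
  }
  if (is.null(lambda)) lambda <- shrinkage_lambda(do.call(rbind, centred))
  sigma <- (1 - lambda) * S + lambda * diag(v, nrow(S))
  structure(list(sigma = sigma, lambda = lambda,
                 dof = sum(vapply(residuals, nrow, 1L)) - length(residuals)),
            class = "noise_cov")
}

# analytic optimal shrinkage toward the diagonal target (off-diagonal
# entries shrunk, variances kept): lambda* = sum Var(s_ij) / sum s_ij^2
# over i != j, clipped to [0, 1]; X must be column-centred
shrinkage_lambda <- function(X) {
  n <- nrow(X)
  if (n < 3L) return(1)
  M <- crossprod(X) / n              # mean of w_kij = x_ki x_kj
  A <- crossprod(X^2)                # sum_k w_kij^2
  var_s <- n / (n - 1)^3 * (A - n * M^2)
  s <- (n / (n - 1)) * M
  off <- !diag(TRUE, ncol(X))
  denom <- sum(s[off]^2)
  if (denom <= 0) return(1)
  min(1, max(0, sum(var_s[off]) / denom))
}

#' Multivariate noise normalisation of beta patterns
#'
#' Right-multiplies every pattern by `Sigma^{-1/2}` (symmetric inverse square
#' root via eigendecomposition), so that after whitening the residual noise
#' is approximately isotropic and Euclidean distances between patterns are
#' Mahalanobis distances in the original space.
#'
#' @param betas Run x condition x voxel array, or pattern matrix with voxels
#'   as columns.
#' @param cov A `noise_cov` (or a plain covariance matrix).
#' @return The whitened array/matrix, same shape as the input.
#' @export
whiten_patterns <- function(betas, cov) {
  sigma <- if (inherits(cov, "noise_cov")) cov$sigma else as.matrix(cov)
  W <- matrix_inv_sqrt(sigma)
  if (is.array(betas) && length(dim(betas)) == 3L) {
    d <- dim(betas)
    flat <- matrix(betas, d[1L] * d[2L], d[3L]) %*% W
    array(flat, d, dimnames = dimnames(betas))
  } else {
    as.matrix(betas) %*% W
  }
}

#' Cross-validated Mahalanobis (crossnobis) distances
#'
#' For every condition pair (j, k), the squared Mahalanobis distance is
#' estimated by crossing independent runs: with whitened per-run patterns
#' `b^(m)`, the estimate is the mean over all ordered run pairs (m, n),
#' m != n, of `(b_j^(m) - b_k^(m)) . (b_j^(n) - b_k^(n)) / P`, where `P` is
#' the voxel count. Because the two difference vectors come from independent
#' runs, run-specific noise does not bias the product: the estimator has an
#' interpretable zero and may legitimately go negative. Distances are
#' normalised per voxel so values are comparable across searchlight sizes.
#'
#' @param betas Whitened run x condition x voxel array (runs >= 2).
#' @param conditions Condition tibble matching the array's condition order.
#' @return An `rdm_data` tibble: the [condition_pairs()] table with a
#'   `distance` column (attributes `conditions`, `n_runs`, `n_voxels`).
#' @export
crossnobis_distances <- function(betas, conditions) {
  d <- dim(betas)
  if (is.null(d) || length(d) != 3L) abort("betas must be a 3-d array")
  M <- d[1L]
  if (M < 2L) abort("crossnobis needs at least 2 runs")
  stopifnot(d[2L] == nrow(conditions))
  pairs <- condition_pairs(conditions)
  dist <- crossnobis_vector(betas, pairs$i, pairs$j)
  out <- dplyr::mutate(pairs, distance = dist)
  structure(out, class = c("rdm_data", class(pairs)),
            conditions = conditions, n_runs = M, n_voxels = d[3L])
}

# vectorised core shared by the R path; the searchlight uses the C++ twin
crossnobis_vector <- function(betas, pi, pj) {
  d <- dim(betas)
  M <- d[1L]; P <- d[3L]
  deltas <- lapply(seq_len(M), function(m) {
    bm <- matrix(betas[m, , ], d[2L], P)
    bm[pi, , drop = FALSE] - bm[pj, , drop = FALSE]
  })
  acc <- 0
  for (m in 1:(M - 1L)) {
    for (n in (m + 1L):M) {
      acc <- acc + rowSums(deltas[[m]] * deltas[[n]])
    }
  }
  2 * acc / (M * (M - 1L)) / P
}

#' Average RDMs elementwise
#'
#' @param rdms List of `rdm_data` objects with identical pair manifests.
#' @return An `rdm_data` with the elementwise mean distance.
#' @export
average_rdms <- function(rdms) {
  stopifnot(length(rdms) >= 1L)
  ref <- rdms[[1L]]
  for (r in rdms[-1L]) {
    if (!identical(r$cond_i, ref$cond_i) || !identical(r$cond_j, ref$cond_j)) {
      abort("RDM pair manifests do not match")
    }
  }
  out <- ref
  out$distance <- rowMeans(vapply(rdms, function(r) r$distance,
                                  numeric(nrow(ref))))
  out
}

#' Export an empirical RDM as a pair table
#'
#' Long-format serialisation: `condition_i`, `condition_j`, `distance`.
#'
#' @param rdm An `rdm_data`.
#' @param path Output path (tab-separated text).
#' @export
write_rdm_pairs <- function(rdm, path) {
  readr::write_tsv(
    tibble::tibble(condition_i = rdm$cond_i, condition_j = rdm$cond_j,
                   distance = rdm$distance),
    path
  )
  invisible(path)
}
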