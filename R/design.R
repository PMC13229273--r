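#' Build the first-level design matrix for one run
#'
#' Constructs the task design matrix of a run from its trial table. Events
#' are modelled at the stimulus onset (trial onset + stimulus delay) with
#' their presentation duration, convolved with the canonical double-gamma HRF
#' on a 0.1 s microtime grid, and sampled at the acquisition midpoints of the
#' sparse sequence (`index * TR + acquisition_time / 2`).
#'
#' Regressors, in order: 32 condition regressors (each comprising that
#' condition's 4 stimulus trials: 2 exemplars x 2 repetitions), one target
#' regressor per stimulus type, one decision-cue regressor, one button-press
#' regressor — 36 task regressors — then any motion regressors and the
#' session-mean (intercept) column. Null trials are unmodelled and constitute
#' the implicit baseline.
#'
#' @param run A `run_sequence` tibble.
#' @param spec Paradigm spec (defaults to the run's own).
#' @param motion Optional samples x 6 matrix of motion parameters.
#' @param n_extra_volumes Additional volumes acquired after the last trial.
#' @param hrf Optional list of [hrf_double_gamma()] parameters.
#' @param button_delay Seconds from decision-cue onset to the modelled button
#'   press.
#' @return A `design_matrix` object: list with the matrix `X` (named
#'   columns), `partition` labels, `sample_times`, and `TR`.
#' @export
build_design_matrix <- function(run, spec = attr(run, "spec"), motion = NULL,
                                n_extra_volumes = 5L, hrf = list(),
                                button_delay = 0.7) {
  TR <- spec$trial_duration
  n <- spec$n_total + n_extra_volumes
  sample_times <- (seq_len(n) - 1L) * TR + spec$acquisition_time / 2
  run_end <- n * TR
  stim_onset <- run$onset + spec$stimulus_delay
  if (any(stim_onset + ifelse(is.na(run$duration), 0, run$duration) > run_end)) {
    abort("event extends beyond the run duration")
  }

  conds <- enumerate_conditions(spec)
  cols <- list(); part <- character()
  add <- function(name, label, onsets, durations) {
    cols[[name]] <<- convolve_events(onsets, durations, sample_times, hrf = hrf)
    part <<- c(part, label)
  }
  is_stim <- run$kind == "stimulus"
  for (cc in conds$condition) {
    rows <- is_stim & !is.na(run$condition) & run$condition == cc
    if (sum(rows) == 0L) abort(paste("condition has no stimulus trials:", cc))
    add(cc, "condition", stim_onset[rows], run$duration[rows])
  }
  for (tt in spec$stimulus_types) {
    rows <- run$kind == "target" & run$stimulus_type == tt
    add(paste0("target_", tt), "target_by_type",
        stim_onset[rows], run$duration[rows])
  }
  dec <- run$kind == "decision"
  add("decision_cue", "decision_cue", stim_onset[dec], run$duration[dec])
  add("button", "button", stim_onset[dec] + button_delay, rep(0, sum(dec)))

  X <- do.call(cbind, cols)
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    stopifnot(nrow(motion) == n)
    colnames(motion) <- paste0("motion", seq_len(ncol(motion)))
    X <- cbind(X, motion)
    part <- c(part, rep("motion", ncol(motion)))
  }
  X <- cbind(X, session_mean = 1)
  part <- c(part, "session_mean")

  structure(list(X = X, partition = part, sample_times = sample_times,
                 TR = TR, n_samples = n),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("<design_matrix>", x$n_samples, "samples x", ncol(x$X), "regressors (",
      sum(x$partition == "condition"), "condition )\n")
  invisible(x)
}

#' Discrete-cosine high-pass filtering
#'
#' `dct_basis()` returns the unit-norm discrete cosine drift regressors with
#' periods longer than `cutoff` seconds (`k = 1 .. floor(2 n TR / cutoff)`).
#' `highpass_filter()` projects that basis out of a data or design matrix
#' (residual-forming projection), which is equivalent to including the basis
#' as nuisance columns. The constant (DC) component is not in the basis, so
#' an intercept column passes through unchanged.
#'
#' @param n Number of samples.
#' @param TR Sampling interval in seconds.
#' @param cutoff High-pass cutoff period in seconds (default 350 s).
#' @return `dct_basis()`: an `n x K` matrix (possibly zero columns);
#'   `highpass_filter()`: the filtered matrix.
#' @export
dct_basis <- function(n, TR, cutoff = 350) {
  if (cutoff <= 2 * TR) abort("high-pass cutoff must exceed 2 * TR")
  K <- floor(2 * n * TR / cutoff)
  if (K < 1L) return(matrix(0, n, 0L))
  t <- seq_len(n) - 1L
  B <- vapply(seq_len(K),
              function(k) cos(pi * (2 * t + 1) * k / (2 * n)),
              numeric(n))
  sweep(B, 2L, sqrt(colSums(B^2)), "/")
}

#' @rdname dct_basis
#' @param x Matrix (samples x columns) or vector to filter.
#' @export
highpass_filter <- function(x, TR, cutoff = 350) {
  x <- as.matrix(x)
  B <- dct_basis(nrow(x), TR, cutoff)
  if (ncol(B) == 0L) return(x)
  x - B %*% crossprod(B, x)
}

#' Fit the first-level GLM with high-pass filtering and AR(1) prewhitening
#'
#' Both design and data are high-pass filtered by projecting out the
#' discrete-cosine drift basis. With `ar1 = "estimate"`, a single lag-1
#' autocorrelation coefficient is estimated from the ordinary-least-squares
#' residuals, pooled over voxels (Cochrane-Orcutt style, one iteration), both
#' sides are prewhitened with the AR(1) inverse square-root operator, and the
#' coefficients are re-estimated. Residuals of the final fit and their
#' effective degrees of freedom (samples minus design rank minus drift
#' regressors) feed the noise-covariance estimate downstream.
#'
#' @param design A `design_matrix` from [build_design_matrix()].
#' @param data Samples x voxels data matrix.
#' @param ar1 `"estimate"` or `"off"`.
#' @param cutoff High-pass cutoff in seconds; `NULL` disables filtering.
#' @return A `glm_fit` object: `betas` (regressor x voxel), `residuals`
#'   (sample x voxel), `dof`, `rho`, `partition`.
#' @export
fit_glm <- function(design, data, ar1 = c("estimate", "off"), cutoff = 350) {
  ar1 <- match.arg(ar1)
  data <- as.matrix(data)
  X <- design$X
  stopifnot(nrow(data) == nrow(X))
  K <- 0L
  if (!is.null(cutoff)) {
    B <- dct_basis(nrow(X), design$TR, cutoff)
    K <- ncol(B)
    if (K > 0L) {
      X <- X - B %*% crossprod(B, X)
      # the intercept is orthogonal to the drift basis; restore it exactly
      X[, design$partition == "session_mean"] <- 1
      data <- data - B %*% crossprod(B, data)
    }
  }
  check_rank(X)
  fit <- lm.fit(X, data)
  rho <- 0
  if (ar1 == "estimate") {
    r <- as.matrix(fit$residuals)
    rho <- sum(r[-1L, ] * r[-nrow(r), ]) / sum(r * r)
    W_first <- sqrt(1 - rho^2)
    whiten1 <- function(m) {
      out <- rbind(m[1L, , drop = FALSE] * W_first,
                   m[-1L, , drop = FALSE] - rho * m[-nrow(m), , drop = FALSE])
      out
    }
    X <- whiten1(X)
    data <- whiten1(data)
    check_rank(X)
    fit <- lm.fit(X, data)
  }
  betas <- as.matrix(fit$coefficients)
  rownames(betas) <- colnames(design$X)
  structure(list(betas = betas,
                 residuals = as.matrix(fit$residuals),
                 dof = nrow(X) - fit$rank - K,
                 rho = rho,
                 partition = design$partition),
            class = "glm_fit")
}

check_rank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]]
    abort(paste("design matrix is rank deficient; collinear columns:",
                paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Extract the condition beta patterns of a fitted run
#'
#' @param fit A `glm_fit`.
#' @return Condition x voxel matrix of beta weights (32 rows, canonical
#'   condition order).
#' @export
condition_betas <- function(fit) {
  fit$betas[fit$partition == "condition", , drop = FALSE]
}

#' Export a design matrix as tab-separated text
#'
#' @param design A `design_matrix`.
#' @param path Output path.
#' @export
write_design_matrix <- function(design, path) {
  df <- tibble::as_tibble(design$X, .name_repair = "minimal")
  df <- dplyr::mutate(df, time = design$sample_times, .before = 1L)
  readr::write_tsv(df, path)
  invisible(path)
}
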