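#' Volume geometry for synthetic data
#'
#' A desk-scale volumetric grid: dimensions, isotropic voxel size, and an
#' analysis mask. The default 20^3 grid at 3 mm exercises every volumetric
#' code path (searchlights, clusters, NIfTI export) without a full-brain
#' grid.
#'
#' @param dim Integer vector of 3 grid dimensions.
#' @param voxel_size Isotropic voxel size in mm.
#' @param mask Logical array of `dim`, or `NULL` for all voxels in-mask.
#' @return A `volume_geometry` object.
#' @export
volume_geometry <- function(dim = c(20L, 20L, 20L), voxel_size = 3,
                            mask = NULL) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 1L))
  if (is.null(mask)) mask <- array(TRUE, dim)
  stopifnot(identical(dim(mask), dim), sum(mask) > 0L)
  structure(list(dim = dim, voxel_size = voxel_size, mask = mask,
                 mask_idx = which(mask),
                 n_voxels = sum(mask)),
            class = "volume_geometry")
}

#' @export
print.volume_geometry <- function(x, ...) {
  cat("<volume_geometry>", paste(x$dim, collapse = " x "), "voxels @",
      x$voxel_size, "mm;", x$n_voxels, "in mask\n")
  invisible(x)
}

# grid coordinates (voxel units) of the in-mask voxels, V x 3
voxel_coords <- function(geometry) {
  arrayInd(geometry$mask_idx, geometry$dim)
}

#' Effect specification: planted representational structure
#'
#' Describes the true condition patterns planted in a spherical ROI. Within
#' the ROI, the pattern of condition `c` is a weighted sum of
#' standard-normal basis patterns drawn once per subject:
#' `w_shared_phon` x the sum of the three positional phoneme patterns
#' (shared across stimulus types — abstract phonology),
#' `w_modality_phon` x modality-specific phoneme patterns,
#' `w_lexical` x a word-identity pattern, and `w_form` x a form pattern.
#' Weights are pattern standard deviations in units of the noise sd.
#' Outside the ROI all true patterns are zero.
#'
#' The default `w_shared_phon` was calibrated by pilot simulation, jointly
#' with the default between-subject effect-scale sd, so that a 12-subject
#' cohort reliably yields a suprathreshold conjunction cluster at the
#' planted region while group-level model-fit t statistics stay within an
#' order of magnitude of values typical for this kind of study. The
#' detection statistic (mean within-type distance) is intrinsically less
#' sensitive than the rank-based model fits, so fits saturate at larger t
#' than the detection map.
#'
#' @param center ROI centre in voxel coordinates (`NULL` = grid centre).
#' @param radius ROI radius in voxels.
#' @param w_shared_phon,w_modality_phon,w_lexical,w_form Component weights
#'   (>= 0).
#' @return An `effect_spec` object.
#' @export
effect_spec <- function(center = NULL, radius = 3,
                        w_shared_phon = 0.05, w_modality_phon = 0,
                        w_lexical = 0, w_form = 0) {
  w <- c(w_shared_phon, w_modality_phon, w_lexical, w_form)
  stopifnot(all(w >= 0), radius > 0)
  structure(list(center = center, radius = radius,
                 w_shared_phon = w_shared_phon,
                 w_modality_phon = w_modality_phon,
                 w_lexical = w_lexical, w_form = w_form),
            class = "effect_spec")
}

#' Noise specification for synthetic BOLD data
#'
#' @param sd Temporal noise standard deviation (signal units).
#' @param ar1 Lag-1 autocorrelation of the temporal noise, in `[0, 1)`.
#' @param fwhm Spatial smoothing FWHM of the noise, in mm (kernel normalised
#'   to preserve marginal variance, so smoothing adds spatial correlation
#'   without changing voxel-wise sd).
#' @param low_rank_n,low_rank_sd Optional low-rank component: number of
#'   shared spatial modes and their sd, inflating the voxel covariance.
#' @param beta_noise_sd Noise sd of beta-level patterns relative to `sd`,
#'   used when cohorts are generated directly at the beta level.
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(sd = 1, ar1 = 0.3, fwhm = 6,
                       low_rank_n = 0L, low_rank_sd = 0,
                       beta_noise_sd = 0.5) {
  stopifnot(sd > 0, ar1 >= 0, ar1 < 1, fwhm >= 0)
  structure(list(sd = sd, ar1 = ar1, fwhm = fwhm,
                 low_rank_n = as.integer(low_rank_n),
                 low_rank_sd = low_rank_sd,
                 beta_noise_sd = beta_noise_sd),
            class = "noise_spec")
}

roi_indices <- function(geometry, effect) {
  center <- effect$center %||% ceiling(geometry$dim / 2)
  xyz <- voxel_coords(geometry)
  d2 <- (xyz[, 1L] - center[1L])^2 + (xyz[, 2L] - center[2L])^2 +
    (xyz[, 3L] - center[3L])^2
  roi <- which(d2 <= effect$radius^2)
  if (length(roi) == 0L) abort("effect ROI lies outside the analysis mask")
  roi
}

#' Plant true condition patterns
#'
#' Draws the basis patterns from `seed` and composes the true pattern of
#' every condition inside the effect ROI (see [effect_spec()] for the
#' generative form). Same-word conditions in different stimulus types get
#' identical shared-phonology contributions, so the true across-modality
#' distance of a word to itself is zero in a shared-phonology-only
#' configuration.
#'
#' @param geometry A [volume_geometry()].
#' @param conditions Condition tibble.
#' @param effect An [effect_spec()].
#' @param seed Integer pattern seed.
#' @return Condition x voxel matrix (attribute `roi`: in-mask ROI indices).
#' @export
plant_condition_patterns <- function(geometry, conditions, effect, seed = 1L) {
  roi <- roi_indices(geometry, effect)
  nv <- length(roi)
  words <- word_set()
  phon_labels <- unique(c(words$initial, words$vowel, words$final))
  types <- unique(conditions$stimulus_type)
  with_seed(seed, {
    B <- matrix(rnorm(length(phon_labels) * nv), length(phon_labels), nv,
                dimnames = list(phon_labels, NULL))
    B_mod <- lapply(setNames(types, types), function(tt) {
      matrix(rnorm(length(phon_labels) * nv), length(phon_labels), nv,
             dimnames = list(phon_labels, NULL))
    })
    L <- matrix(rnorm(8L * nv), 8L, nv, dimnames = list(words$word, NULL))
    Fm <- matrix(rnorm(2L * nv), 2L, nv, dimnames = list(c("A", "B"), NULL))
  })
  out <- matrix(0, nrow(conditions), geometry$n_voxels)
  rownames(out) <- conditions$condition
  for (k in seq_len(nrow(conditions))) {
    w <- conditions$word[k]
    ph <- c(words$initial[words$word == w], words$vowel[words$word == w],
            words$final[words$word == w])
    pat <- effect$w_shared_phon * colSums(B[ph, , drop = FALSE]) +
      effect$w_modality_phon *
        colSums(B_mod[[conditions$stimulus_type[k]]][ph, , drop = FALSE]) +
      effect$w_lexical * L[w, ] +
      effect$w_form * Fm[conditions$form[k], ]
    out[k, roi] <- pat
  }
  attr(out, "roi") <- roi
  out
}

# -- noise fields ------------------------------------------------------------

gaussian_kernel <- function(fwhm_mm, voxel_size) {
  if (fwhm_mm <= 0) return(1)
  sd_vox <- fwhm_mm / voxel_size / (2 * sqrt(2 * log(2)))
  m <- max(1L, ceiling(3 * sd_vox))
  w <- dnorm(-m:m, sd = sd_vox)
  w / sqrt(sum(w^2))  # unit L2 norm: preserves white-noise variance
}

# smooth each row of `mat` (samples x full-grid voxels) along one axis
smooth_axis <- function(mat, dims, axis, w) {
  if (length(w) == 1L) return(mat * w)
  V <- prod(dims)
  coord <- arrayInd(seq_len(V), dims)
  out <- matrix(0, nrow(mat), V)
  m <- (length(w) - 1L) / 2L
  for (k in seq_along(w)) {
    off <- k - m - 1L
    src_a <- coord[, axis] - off
    valid <- src_a >= 1L & src_a <= dims[axis]
    src <- coord
    src[, axis] <- src_a
    src_idx <- (src[, 3L] - 1L) * dims[1L] * dims[2L] +
      (src[, 2L] - 1L) * dims[1L] + src[, 1L]
    out[, valid] <- out[, valid] + w[k] * mat[, src_idx[valid], drop = FALSE]
  }
  out
}

smooth_field <- function(mat, geometry, fwhm_mm) {
  w <- gaussian_kernel(fwhm_mm, geometry$voxel_size)
  if (length(w) == 1L) return(mat)
  for (axis in 1:3) mat <- smooth_axis(mat, geometry$dim, axis, w)
  mat
}

# n_samples x n_voxels (in-mask) correlated noise; temporal AR(1) optional
noise_samples <- function(n_samples, geometry, noise, temporal = TRUE) {
  Vfull <- prod(geometry$dim)
  innov_sd <- if (temporal && noise$ar1 > 0) {
    noise$sd * sqrt(1 - noise$ar1^2)
  } else noise$sd
  e <- matrix(rnorm(n_samples * Vfull, sd = innov_sd), n_samples, Vfull)
  if (temporal && noise$ar1 > 0) {
    e <- apply(e, 2L, function(x) {
      as.numeric(stats::filter(x, noise$ar1, method = "recursive"))
    })
  }
  e <- smooth_field(e, geometry, noise$fwhm)
  if (noise$low_rank_n > 0L && noise$low_rank_sd > 0) {
    load <- matrix(rnorm(Vfull * noise$low_rank_n), noise$low_rank_n, Vfull)
    fac <- matrix(rnorm(n_samples * noise$low_rank_n, sd = noise$low_rank_sd),
                  n_samples, noise$low_rank_n)
    e <- e + fac %*% (load / sqrt(noise$low_rank_n))
  }
  e[, geometry$mask_idx, drop = FALSE]
}

# -- timeseries --------------------------------------------------------------

#' Simulate a 4D run from planted patterns
#'
#' Every stimulus and target trial contributes its condition's true pattern
#' scaled by the canonical HRF evaluated at the sparse acquisition midpoints.
#' Additive noise is AR(1) in time per voxel, spatially smoothed, with an
#' optional shared low-rank component; a slow drift (sum of low-frequency
#' cosines) and simulated motion parameters (smooth random walks, pure
#' nuisance — they do not corrupt the data) are included to exercise the
#' filtering and nuisance-regression paths.
#'
#' @param patterns Condition x voxel matrix from [plant_condition_patterns()].
#' @param run A `run_sequence`.
#' @param geometry The [volume_geometry()].
#' @param noise A [noise_spec()]; `NULL` for noiseless data.
#' @param spec Paradigm spec.
#' @param hrf HRF parameter list (see [hrf_double_gamma()]).
#' @param seed Integer seed.
#' @param n_extra_volumes Trailing volumes after the last trial.
#' @param drift_sd Amplitude sd of the cosine drift (0 disables).
#' @param n_drift Number of drift cosines (random periods 400-800 s).
#' @return List with `data` (samples x in-mask voxels), `motion`
#'   (samples x 6), and the `design_matrix` used for the signal.
#' @export
simulate_timeseries <- function(patterns, run, geometry, noise = noise_spec(),
                                spec = attr(run, "spec"), hrf = list(),
                                seed = 1L, n_extra_volumes = 5L,
                                drift_sd = 1, n_drift = 3L) {
  design <- build_design_matrix(run, spec, hrf = hrf,
                                n_extra_volumes = n_extra_volumes)
  Xc <- design$X[, design$partition == "condition", drop = FALSE]
  # target trials present stimuli too: add their events onto the condition
  # response so the signal reflects everything shown
  tgt <- run[run$kind == "target", ]
  if (nrow(tgt) > 0L) {
    for (cc in unique(tgt$condition)) {
      rows <- tgt$condition == cc
      Xc[, cc] <- Xc[, cc] +
        convolve_events(tgt$onset[rows] + spec$stimulus_delay,
                        tgt$duration[rows], design$sample_times, hrf = hrf)
    }
  }
  signal <- Xc %*% patterns[colnames(Xc), , drop = FALSE]
  n <- nrow(signal)
  with_seed(seed, {
    drift <- 0
    if (drift_sd > 0 && n_drift > 0L) {
      tsec <- design$sample_times
      drift <- rowSums(vapply(seq_len(n_drift), function(k) {
        period <- runif(1L, 400, 800)
        drift_sd * rnorm(1L) * cos(2 * pi * tsec / period)
      }, numeric(n)))
    }
    e <- if (is.null(noise)) 0 else noise_samples(n, geometry, noise)
    motion <- apply(matrix(rnorm(n * 6L, sd = 0.02), n, 6L), 2L, cumsum)
  })
  list(data = signal + e + drift, motion = motion, design = design)
}

# -- cohorts -----------------------------------------------------------------

#' Linear model linking reading scores to effect scale
#'
#' Reading score of subject `s` is `intercept + slope * g_s + e_s` with
#' `e_s ~ N(0, resid_sd^2)`, where `g_s` is the subject's effect scale. The
#' convenience parameterisation fixes the population correlation `rho`
#' between reading and effect scale, and the marginal mean/sd of the reading
#' test (defaults follow the hearing group's reading test: mean 34, sd 4).
#'
#' @param rho Population correlation between effect scale and reading.
#' @param mean,sd Marginal mean and sd of the reading score.
#' @param effect_base,effect_sd Mean and sd of the effect-scale distribution.
#' @return A `reading_model` list with `intercept`, `slope`, `resid_sd`.
#' @export
reading_model <- function(rho = 0.5, mean = 34, sd = 4,
                          effect_base = 1, effect_sd = 0.15) {
  stopifnot(abs(rho) <= 1)
  slope <- if (effect_sd > 0) rho * sd / effect_sd else 0
  structure(list(intercept = mean - slope * effect_base, slope = slope,
                 resid_sd = sd * sqrt(1 - rho^2), rho = rho,
                 effect_base = effect_base, effect_sd = effect_sd),
            class = "reading_model")
}

#' Generate a synthetic cohort
#'
#' Simulates `n_subjects` independent subjects. Each subject gets: an effect
#' scale `g_s` from a truncated normal (positive), multiplying the
#' shared-phonology weight only; a reading score from the [reading_model()];
#' basis patterns drawn independently per subject (group inference is at the
#' subject level, not the pattern level); and either
#'
#' * `mode = "betas"`: per-run condition patterns observed with correlated
#'   beta-level noise, plus matched synthetic residual samples carrying the
#'   same spatial covariance (for noise normalisation), or
#' * `mode = "timeseries"`: a full 4-run session simulated as 4D timeseries
#'   and passed through [fit_glm()], with betas and residuals taken from the
#'   fit.
#'
#' @param spec Paradigm spec.
#' @param geometry Volume geometry.
#' @param effect Effect spec (the subject's `w_shared_phon` is scaled by
#'   `g_s`).
#' @param noise Noise spec.
#' @param n_subjects Number of subjects (>= 3).
#' @param effect_sd Between-subject sd of the effect scale.
#' @param reading A [reading_model()].
#' @param mode `"betas"` or `"timeseries"`.
#' @param seed Cohort seed.
#' @param n_resid Residual samples per run in beta mode.
#' @return A `cohort` object: `subjects` (list of per-subject records with
#'   `betas` (run x condition x voxel), `residuals` (list per run),
#'   `effect_scale`, `reading`), a `manifest` tibble, and the generating
#'   specs.
#' @export
generate_cohort <- function(spec = paradigm_spec(),
                            geometry = volume_geometry(),
                            effect = effect_spec(),
                            noise = noise_spec(),
                            n_subjects = 12L,
                            effect_sd = 0.15,
                            reading = reading_model(effect_sd = effect_sd),
                            mode = c("betas", "timeseries"),
                            seed = 1L,
                            n_resid = 60L) {
  mode <- match.arg(mode)
  stopifnot(n_subjects >= 3L)
  conditions <- enumerate_conditions(spec)
  seeds <- derive_seeds(seed, 2L * n_subjects + 1L)
  scales <- with_seed(seeds[1L], {
    vapply(seq_len(n_subjects), function(s) {
      repeat {
        g <- rnorm(1L, reading$effect_base, effect_sd)
        if (g > 0) return(g)
      }
    }, numeric(1))
  })
  reading_scores <- with_seed(seeds[1L] %% 2147483646L + 1L, {
    reading$intercept + reading$slope * scales +
      rnorm(n_subjects, 0, reading$resid_sd)
  })
  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    eff_s <- effect
    eff_s$w_shared_phon <- effect$w_shared_phon * scales[s]
    pat_seed <- seeds[2L * s]
    sim_seed <- seeds[2L * s + 1L]
    patterns <- plant_condition_patterns(geometry, conditions, eff_s, pat_seed)
    subjects[[s]] <- if (mode == "betas") {
      simulate_subject_betas(patterns, spec, geometry, noise, sim_seed, n_resid)
    } else {
      simulate_subject_timeseries(patterns, spec, geometry, noise, sim_seed)
    }
    subjects[[s]]$effect_scale <- scales[s]
    subjects[[s]]$reading <- reading_scores[s]
    subjects[[s]]$seed <- sim_seed
  }
  manifest <- tibble::tibble(
    subject = seq_len(n_subjects),
    effect_scale = scales,
    reading = reading_scores,
    seed = vapply(subjects, function(x) x$seed, numeric(1))
  )
  structure(list(subjects = subjects, manifest = manifest,
                 conditions = conditions, geometry = geometry, spec = spec,
                 effect = effect, noise = noise, mode = mode,
                 seed = as.integer(seed)),
            class = "cohort")
}

simulate_subject_betas <- function(patterns, spec, geometry, noise, seed,
                                   n_resid) {
  M <- spec$n_runs
  C <- nrow(patterns)
  V <- geometry$n_voxels
  with_seed(seed, {
    beta_noise <- noise_samples(M * C, geometry, noise, temporal = FALSE) *
      noise$beta_noise_sd
    betas <- array(0, c(M, C, V))
    for (m in seq_len(M)) {
      betas[m, , ] <- patterns + beta_noise[(m - 1L) * C + seq_len(C), ]
    }
    residuals <- lapply(seq_len(M), function(m) {
      noise_samples(n_resid, geometry, noise, temporal = FALSE)
    })
  })
  list(betas = betas, residuals = residuals, dof = n_resid - 1L)
}

simulate_subject_timeseries <- function(patterns, spec, geometry, noise,
                                        seed) {
  seeds <- derive_seeds(seed, spec$n_runs + 1L)
  session <- generate_session(spec, seed = seeds[1L])
  C <- nrow(patterns)
  V <- geometry$n_voxels
  betas <- array(0, c(spec$n_runs, C, V))
  residuals <- vector("list", spec$n_runs)
  dof <- NA_integer_
  for (m in seq_len(spec$n_runs)) {
    sim <- simulate_timeseries(patterns, session[[m]], geometry, noise,
                               spec = spec, seed = seeds[m + 1L])
    design <- build_design_matrix(session[[m]], spec, motion = sim$motion)
    fit <- fit_glm(design, sim$data)
    betas[m, , ] <- condition_betas(fit)
    residuals[[m]] <- fit$residuals
    dof <- fit$dof
  }
  list(betas = betas, residuals = residuals, dof = dof)
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort>", length(x$subjects), "subjects,", x$spec$group, "group,",
      "mode:", x$mode, "\n")
  print(x$manifest, n = 5)
  invisible(x)
}

#' Write the cohort manifest as tab-separated text
#'
#' @param cohort A `cohort`.
#' @param path Output path.
#' @export
write_cohort_manifest <- function(cohort, path) {
  readr::write_tsv(cohort$manifest, path)
  invisible(path)
}
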