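spec <- paradigm_spec()
conds <- enumerate_conditions(spec)

test_that("planted patterns follow the generative formula", {
  geom <- volume_geometry(c(5L, 5L, 5L))
  eff0 <- effect_spec(center = c(3, 3, 3), radius = 1,
                      w_shared_phon = 0, w_modality_phon = 0,
                      w_lexical = 0, w_form = 0)
  expect_true(all(plant_condition_patterns(geom, conds, eff0, 1L) == 0))

  eff <- effect_spec(center = c(3, 3, 3), radius = 1, w_shared_phon = 1)
  p1 <- plant_condition_patterns(geom, conds, eff, 5L)
  p2 <- plant_condition_patterns(geom, conds, eff, 5L)
  expect_identical(p1, p2)  # deterministic in the pattern seed
  roi <- attr(p1, "roi")
  expect_true(all(p1[, -roi] == 0))
  # across-modality distance of the same word is exactly zero
  expect_equal(p1["beam.visual_speech.A", ], p1["beam.auditory_speech.A", ])
  # independent seeds give uncorrelated patterns
  p3 <- plant_condition_patterns(geom, conds, eff, 6L)
  expect_lt(abs(cor(as.numeric(p1[, roi]), as.numeric(p3[, roi]))), 0.15)
  bad <- effect_spec(center = c(50, 50, 50), radius = 1)
  expect_error(plant_condition_patterns(geom, conds, bad, 1L), "ROI")
})

test_that("expected squared pattern distance is 2 w^2 (3 - shared) x ROI size", {
  geom <- volume_geometry(c(5L, 5L, 5L))
  eff <- effect_spec(center = c(3, 3, 3), radius = 1, w_shared_phon = 0.7)
  nroi <- length(roi_indices_for_test(geom, eff))
  pairs <- list(c("beam.visual_speech.A", "beat.visual_speech.A"),   # 2 shared
                c("beam.visual_speech.A", "rule.visual_speech.A"),   # 0 shared
                c("beam.visual_speech.A", "boom.auditory_speech.B")) # 2 shared
  shared <- c(2L, 0L, 2L)
  n_draws <- 1200L
  d2 <- matrix(0, n_draws, length(pairs))
  for (k in seq_len(n_draws)) {
    p <- plant_condition_patterns(geom, conds, eff, seed = k)
    for (j in seq_along(pairs)) {
      d2[k, j] <- sum((p[pairs[[j]][1L], ] - p[pairs[[j]][2L], ])^2)
    }
  }
  expected <- 2 * 0.7^2 * (3 - shared) * nroi
  expect_equal(colMeans(d2), expected, tolerance = 0.08)
})

test_that("true geometry matches the models maximally, with the lexical dissociation", {
  # expected squared distances, computed analytically from the formula
  pairs <- condition_pairs(conds)
  shared <- shared_phoneme_count(pairs$word_i, pairs$word_j)
  across <- partition_mask(conds, "across_type")

  # shared-phonology-only configuration
  d_shared <- 2 * (3 - shared)  # up to a constant factor
  sp <- shared_phonemes_model(conds)
  tau <- kendall_tau_a(sp$value[across], d_shared[across])
  # agreement is maximal given the tie structure: no discordant pairs, and
  # tau-b (which rescales away ties) is exactly 1
  expect_equal(tau, kendall_tau_a(sp$value[across], sp$value[across]))
  expect_equal(cor(sp$value[across], d_shared[across], method = "kendall"), 1)

  # lexical-only configuration: flat distances among different words
  d_lex <- 2 * as.integer(pairs$word_i != pairs$word_j)
  lex <- lexical_model(conds)
  expect_equal(cor(lex$value[across], d_lex[across], method = "kendall"), 1)
  sub <- sublexical_model(conds)
  sel <- sub$included & across
  expect_equal(kendall_tau_a(sub$value[sel], d_lex[sel]), 0)
})

test_that("the canonical HRF peaks where specified", {
  tgrid <- seq(0, 30, by = 0.1)
  h <- hrf_double_gamma(tgrid)
  expect_equal(tgrid[which.max(h)], 6, tolerance = 0.05)
  expect_equal(max(h), 1)
  expect_true(all(h[tgrid < 0.2] < 0.01))
  # an isolated brief event sampled densely peaks near 6 s post-onset
  resp <- convolve_events(onsets = 10, durations = 0.1,
                          sample_times = seq(0, 40, by = 0.1))
  expect_equal(seq(0, 40, by = 0.1)[which.max(resp)] - 10, 6,
               tolerance = 0.2)
})

test_that("temporal noise has the requested AR(1) autocorrelation", {
  geom <- volume_geometry(c(1L, 1L, 1L))
  x <- withr::with_seed(8L, {
    noise_samples_for_test(1e5L, geom, noise_spec(ar1 = 0.3, fwhm = 0))
  })
  r1 <- cor(x[-1L], x[-length(x)])
  expect_equal(r1, 0.3, tolerance = 0.02)
})

test_that("noiseless, driftless simulation of zero patterns is flat", {
  geom <- volume_geometry(c(4L, 4L, 4L))
  run <- generate_run_sequence(spec, 1L, seed = 2L)
  pat <- matrix(0, 32L, geom$n_voxels,
                dimnames = list(conds$condition, NULL))
  sim <- simulate_timeseries(pat, run, geom, noise = NULL, spec = spec,
                             seed = 1L, drift_sd = 0)
  expect_true(all(sim$data == 0))
  expect_equal(dim(sim$motion), c(175L, 6L))
})

test_that("cohort generation is bit-identical under the same seed", {
  geom <- volume_geometry(c(4L, 4L, 4L))
  eff <- effect_spec(center = c(2, 2, 2), radius = 1)
  a <- generate_cohort(spec, geom, eff, noise_spec(), n_subjects = 3L,
                       seed = 9L, n_resid = 10L)
  b <- generate_cohort(spec, geom, eff, noise_spec(), n_subjects = 3L,
                       seed = 9L, n_resid = 10L)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$subjects[[2L]]$betas, b$subjects[[2L]]$betas)
  c <- generate_cohort(spec, geom, eff, noise_spec(), n_subjects = 3L,
                       seed = 10L, n_resid = 10L)
  expect_false(identical(a$subjects[[1L]]$betas, c$subjects[[1L]]$betas))
})

test_that("reading scores follow the stated linear model", {
  # null case: zero slope decouples reading from effect scale
  rm0 <- reading_model(rho = 0)
  expect_equal(rm0$slope, 0)
  # oracle: direct bivariate simulation without the fMRI layer
  rm5 <- reading_model(rho = 0.5, effect_sd = 0.15)
  rs <- withr::with_seed(21L, replicate(400L, {
    g <- rnorm(25L, 1, 0.15)
    read <- rm5$intercept + rm5$slope * g + rnorm(25L, 0, rm5$resid_sd)
    cor(g, read)
  }))
  expect_equal(mean(rs), 0.5, tolerance = 0.05)
  # a generated cohort manifest reproduces the same law
  geom <- volume_geometry(c(3L, 3L, 3L))
  eff <- effect_spec(center = c(2, 2, 2), radius = 1)
  r_obs <- sapply(1:8, function(s) {
    coh <- generate_cohort(spec, geom, eff, noise_spec(fwhm = 0),
                           n_subjects = 25L, seed = s, n_resid = 5L,
                           reading = rm5)
    cor(coh$manifest$effect_scale, coh$manifest$reading)
  })
  expect_equal(mean(r_obs), 0.5, tolerance = 0.12)
})

test_that("timeseries mode recovers planted structure through the GLM", {
  geom <- volume_geometry(c(6L, 6L, 6L))
  eff <- effect_spec(center = c(3, 3, 3), radius = 2, w_shared_phon = 0.4)
  coh <- generate_cohort(spec, geom, eff, noise_spec(fwhm = 3),
                         n_subjects = 3L, mode = "timeseries", seed = 14L)
  sub <- coh$subjects[[1L]]
  expect_equal(dim(sub$betas), c(4L, 32L, geom$n_voxels))
  roi <- roi_indices_for_test(geom, eff)
  nc <- estimate_noise_cov(lapply(sub$residuals, function(r) r[, roi]))
  wb <- whiten_patterns(sub$betas[, , roi], nc)
  rdm <- crossnobis_distances(wb, conds)
  within <- partition_mask(conds, "within_type_any")
  fit <- rdm_model_fit(rdm, shared_phonemes_model(conds), within)
  expect_gt(fit$tau, 0.3)
})
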