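label_clusters_for_test <- function(idx, dims) {
  phonorsa:::cpp_label_clusters(as.integer(idx), as.integer(dims))
}

test_that("sphere membership matches brute-force enumeration", {
  geom <- volume_geometry(c(7L, 7L, 7L))
  # sub-voxel radius: the centre only
  tiny <- sphere_indices(c(4L, 4L, 4L), searchlight_spec(0.5, "voxels"),
                         geom)
  xyz <- phonorsa:::voxel_coords(geom)
  expect_equal(xyz[tiny, , drop = FALSE],
               matrix(c(4L, 4L, 4L), 1L), ignore_attr = TRUE)
  # radius 2: brute force over the bounding cube
  sp <- sphere_indices(c(4L, 4L, 4L), searchlight_spec(2, "voxels"), geom)
  brute <- 0L
  for (x in 1:7) for (y in 1:7) for (z in 1:7) {
    if ((x - 4)^2 + (y - 4)^2 + (z - 4)^2 <= 4) brute <- brute + 1L
  }
  expect_equal(length(sp), brute)
  # an edge centre keeps only in-mask members
  edge <- sphere_indices(c(1L, 1L, 1L), searchlight_spec(2, "voxels"), geom)
  expect_true(all(xyz[edge, ] >= 1L))
  expect_lt(length(edge), brute)
  # mm radius converts through the voxel size
  expect_equal(length(sphere_indices(c(4L, 4L, 4L),
                                     searchlight_spec(6, "mm"), geom)),
               length(sp))
  mask <- array(TRUE, c(7L, 7L, 7L)); mask[1L] <- FALSE
  geom2 <- volume_geometry(c(7L, 7L, 7L), mask = mask)
  expect_error(sphere_indices(c(1L, 1L, 1L), searchlight_spec(2, "voxels"),
                              geom2), "not in the mask")
})

test_that("build_spheres covers all centres and respects min_voxels", {
  geom <- volume_geometry(c(5L, 5L, 5L))
  sph <- build_spheres(geom, searchlight_spec(1, "voxels"))
  expect_length(sph$spheres, 125L)
  # centre sphere = 6-neighbourhood + centre
  mid <- which(sph$center_idx == 3L + (3L - 1L) * 5L + (3L - 1L) * 25L)
  expect_equal(length(sph$spheres[[mid]]), 7L)
  # a huge min_voxels leaves nothing
  sph2 <- build_spheres(geom, searchlight_spec(1, "voxels",
                                               min_voxels = 100L))
  expect_length(sph2$spheres, 0L)
  expect_length(sph2$skipped, 125L)
})

test_that("26-connectivity joins voxels sharing only a corner", {
  dims <- c(4L, 4L, 4L)
  at <- function(x, y, z) x + 4L * ((y - 1L) + 4L * (z - 1L))
  corner <- c(at(1, 1, 1), at(2, 2, 2))   # share one corner
  expect_equal(label_clusters_for_test(corner, dims), c(1L, 1L))
  apart <- c(at(1, 1, 1), at(3, 3, 3))
  expect_equal(sort(unique(label_clusters_for_test(apart, dims))), 1:2)
  chain <- c(at(1, 1, 1), at(2, 2, 2), at(3, 3, 3))
  expect_equal(unique(label_clusters_for_test(chain, dims)), 1L)
})

test_that("C++ searchlight equals the R crossnobis path exactly", {
  st <- tiny_setup(dim = 6, radius = 1)
  eff <- effect_spec(center = st$center, radius = 2, w_shared_phon = 0.3)
  coh <- generate_cohort(st$spec, st$geometry, eff, noise_spec(),
                         n_subjects = 3L, seed = 4L, n_resid = 20L)
  sub <- coh$subjects[[1L]]
  rdms <- searchlight_rdms(sub, st$spheres, st$conditions)
  for (ci in c(1L, 50L, 120L)) {
    vox <- st$spheres$spheres[[ci]]
    nc <- estimate_noise_cov(lapply(sub$residuals, function(r) r[, vox]))
    wb <- whiten_patterns(sub$betas[, , vox], nc)
    ref <- crossnobis_distances(wb, st$conditions)
    expect_equal(rdms[ci, ], ref$distance, tolerance = 1e-10)
  }
  # centre iteration order does not change values
  sub_rdms <- searchlight_rdms(sub, st$spheres, st$conditions,
                               centers = c(120L, 1L, 50L))
  expect_equal(sub_rdms[2L, ], rdms[1L, ])
  expect_equal(sub_rdms[1L, ], rdms[120L, ])
})

test_that("within-type maps light up the planted region and not the far field", {
  st <- tiny_setup(dim = 8, radius = 2)
  eff <- effect_spec(center = st$center, radius = 2, w_shared_phon = 0.3)
  coh <- generate_cohort(st$spec, st$geometry, eff, noise_spec(),
                         n_subjects = 4L, seed = 5L)
  maps <- cohort_type_maps(coh, st$spheres)
  lin <- st$center[1L] + 8L * ((st$center[2L] - 1L) + 8L * (st$center[3L] - 1L))
  ctr <- which(st$spheres$center_idx == lin)
  far <- which(st$spheres$center_idx == 1L)
  for (tt in names(maps)) {
    expect_gt(mean(maps[[tt]][, ctr]), 0.5)
    expect_lt(abs(mean(maps[[tt]][, far])), 0.15)
  }
  # both maps are defined on identical centre sets
  expect_equal(dim(maps[[1L]]), dim(maps[[2L]]))
})

test_that("conjunction clustering finds a crafted single-voxel signal", {
  geom <- volume_geometry(c(5L, 5L, 5L))
  sph <- build_spheres(geom, searchlight_spec(1, "voxels"))
  n_sub <- 12L
  mk <- function(seed) {
    withr::with_seed(seed, {
      m <- matrix(rnorm(n_sub * 125L, 0, 0.1), n_sub, 125L)
      m[, 63L] <- m[, 63L] + 1  # centre voxel carries signal in every subject
      m
    })
  }
  maps <- list(a = mk(6L), b = mk(7L))
  cl <- conjunction_group_map(maps, sph, seed = 8L)
  expect_equal(nrow(cl$cluster_table), 1L)
  expect_equal(cl$cluster_table$size, 1L)
  expect_equal(cl$cluster_table$peak_x, 3L)
  expect_true(cl$cluster_table$keep)
  expect_equal(cl$n_perm, 2^12)
  expect_equal(which(cl$labels == 1L), 63L)
  # too few subjects errs / warns
  expect_error(conjunction_group_map(list(a = maps$a[1:2, ],
                                          b = maps$b[1:2, ]), sph),
               "at least 3")
  expect_warning(conjunction_group_map(list(a = maps$a[1:6, ],
                                            b = maps$b[1:6, ]), sph),
                 "coarse")
})

test_that("model-fit searchlight is maximal on model-true patterns", {
  # patterns whose squared distances realise the model exactly: one-hot
  # phoneme coding per position (8 dims tiled over the volume), so
  # ||p_i - p_j||^2 = 2 x (number of differing positions)
  st <- tiny_setup(dim = 5, radius = 10)  # every sphere spans the volume
  words <- word_set()
  emb <- cbind(
    stats::model.matrix(~ 0 + initial, words),
    stats::model.matrix(~ 0 + vowel, words),
    stats::model.matrix(~ 0 + final, words)
  ) * 10
  V <- st$geometry$n_voxels
  dims8 <- ((seq_len(V) - 1L) %% 8L) + 1L
  pat <- t(vapply(seq_len(32L), function(k) {
    w <- match(st$conditions$word[k], words$word)
    emb[w, dims8]
  }, numeric(V)))
  betas <- array(0, c(4L, 32L, V))
  for (m in 1:4) betas[m, , ] <- pat   # identical across runs: noiseless
  sub <- list(betas = betas,
              residuals = withr::with_seed(10L, {
                lapply(1:4, function(m) matrix(rnorm(500L * V), 500L))
              }))
  model <- shared_phonemes_model(st$conditions)
  across <- partition_mask(st$conditions, "across_type")
  z <- model_fit_searchlight(sub, st$spheres, model, mask = across)
  # maximal achievable tau-a given the model's tie structure, everywhere
  tau_max <- kendall_tau_a(model$value[across], model$value[across])
  expect_equal(unique(round(z, 10)), fisher_z(tau_max), tolerance = 1e-8)
  # degenerate masks are rejected
  same_word <- model$word_i == model$word_j
  expect_error(model_fit_searchlight(sub, st$spheres,
                                     lexical_model(st$conditions),
                                     mask = same_word),
               "constant")
  expect_error(model_fit_searchlight(sub, st$spheres, model,
                                     mask = rep(FALSE, nrow(model))),
               "fewer than 3")
})

test_that("statistic maps round-trip through NIfTI", {
  st <- tiny_setup(dim = 5, radius = 1)
  vals <- seq_len(length(st$spheres$spheres)) / 10
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_stat_map(vals, st$spheres, path)
  back <- as.array(RNifti::readNifti(path))
  expect_equal(dim(back), c(5L, 5L, 5L))
  expect_equal(back[st$spheres$center_idx], vals, tolerance = 1e-6)
})
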