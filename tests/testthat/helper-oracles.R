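# independent oracles and small fixtures used across the suite; all oracles
# are literal/brute-force implementations kept separate from the package's
# vectorised code paths

# positional transcription table written out by hand (not via word_set())
oracle_transcriptions <- function() {
  list(
    beam = c("b", "i:", "m"), beat = c("b", "i:", "t"),
    boom = c("b", "u:", "m"), boot = c("b", "u:", "t"),
    real = c("r", "i:", "l"), reef = c("r", "i:", "f"),
    rule = c("r", "u:", "l"), roof = c("r", "u:", "f")
  )
}

oracle_shared_count <- function(w1, w2) {
  tr <- oracle_transcriptions()
  sum(tr[[w1]] == tr[[w2]])
}

# literal fold-pair loop over ordered run pairs
oracle_crossnobis <- function(betas, i, j) {
  M <- dim(betas)[1L]
  P <- dim(betas)[3L]
  acc <- 0
  cnt <- 0
  for (m in seq_len(M)) {
    for (n in seq_len(M)) {
      if (m == n) next
      dm <- betas[m, i, ] - betas[m, j, ]
      dn <- betas[n, i, ] - betas[n, j, ]
      acc <- acc + sum(dm * dn)
      cnt <- cnt + 1L
    }
  }
  acc / cnt / P
}

# O(n^2) double loop, ties counted as neither concordant nor discordant
oracle_tau_a <- function(x, y) {
  n <- length(x)
  cd <- 0
  for (a in 1:(n - 1L)) {
    for (b in (a + 1L):n) {
      sx <- sign(x[a] - x[b])
      sy <- sign(y[a] - y[b])
      cd <- cd + sx * sy
    }
  }
  cd / (n * (n - 1) / 2)
}

# tiny standard cohort setup shared by searchlight-level tests
tiny_setup <- function(dim = 10, radius = 2) {
  spec <- paradigm_spec()
  geometry <- volume_geometry(rep(dim, 3L))
  center <- rep(ceiling(dim / 2), 3L)
  spheres <- build_spheres(geometry, searchlight_spec(radius, "voxels"))
  list(spec = spec, geometry = geometry, center = center, spheres = spheres,
       conditions = enumerate_conditions(spec))
}

# per-subject within-type distance maps stacked into subject x centre
# matrices, one per stimulus type
cohort_type_maps <- function(cohort, spheres) {
  types <- cohort$spec$stimulus_types
  maps <- stats::setNames(vector("list", length(types)), types)
  for (s in seq_along(cohort$subjects)) {
    wm <- within_type_distance_maps(cohort$subjects[[s]], spheres,
                                    cohort$conditions, types)
    for (tt in types) maps[[tt]] <- rbind(maps[[tt]], wm[, tt])
  }
  maps
}

# run searchlight + conjunction + two-step for one cohort; returns NULL when
# no cluster survives
cohort_two_step <- function(cohort, spheres, seed = 1L) {
  maps <- cohort_type_maps(cohort, spheres)
  cl <- conjunction_group_map(maps, spheres, seed = seed)
  keep <- cl$cluster_table[cl$cluster_table$keep, ]
  if (nrow(keep) == 0L) return(NULL)
  cr <- cluster_average_rdms(cohort, cl, spheres)
  list(clusters = cl, fits = run_two_step(cr, cohort$conditions),
       rdms = cr)
}

# does any surviving cluster contain the planted centre?
cluster_hits_roi <- function(clusters, spheres, center) {
  tbl <- clusters$cluster_table
  keep <- tbl$cluster[tbl$keep]
  if (length(keep) == 0L) return(FALSE)
  dims <- spheres$geometry$dim
  lin <- center[1L] + dims[1L] * ((center[2L] - 1L) +
                                    dims[2L] * (center[3L] - 1L))
  pos <- which(spheres$center_idx == lin)
  length(pos) == 1L && clusters$labels[pos] %in% keep
}

# thin accessors for internal helpers exercised directly in tests
roi_indices_for_test <- function(geometry, effect) {
  phonorsa:::roi_indices(geometry, effect)
}
noise_samples_for_test <- function(n, geometry, noise, temporal = TRUE) {
  phonorsa:::noise_samples(n, geometry, noise, temporal)
}
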