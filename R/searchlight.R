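#' Searchlight specification
#'
#' @param radius Sphere radius; by default in mm (9 mm, i.e. about 3 voxels
#'   at 3 mm isotropic — the radius is a free mapping parameter and is
#'   exposed here).
#' @param units `"mm"` or `"voxels"`.
#' @param min_voxels Minimum in-mask voxels for a sphere to be analysed;
#'   centres with fewer are skipped (recorded, not erred).
#' @return A `searchlight_spec` object.
#' @export
searchlight_spec <- function(radius = 9, units = c("mm", "voxels"),
                             min_voxels = 2L) {
  units <- match.arg(units)
  stopifnot(radius > 0, min_voxels >= 2L)
  structure(list(radius = radius, units = units,
                 min_voxels = as.integer(min_voxels)),
            class = "searchlight_spec")
}

radius_in_voxels <- function(spec, geometry) {
  if (spec$units == "mm") spec$radius / geometry$voxel_size else spec$radius
}

#' In-mask voxels of a single searchlight sphere
#'
#' All in-mask voxels whose centre-to-centre Euclidean distance from `center`
#' is at most the searchlight radius.
#'
#' @param center Voxel coordinates (length-3 integer vector); must be
#'   in-mask.
#' @param spec A [searchlight_spec()].
#' @param geometry A [volume_geometry()].
#' @return Integer indices into the in-mask voxel ordering.
#' @export
sphere_indices <- function(center, spec, geometry) {
  r <- radius_in_voxels(spec, geometry)
  xyz <- voxel_coords(geometry)
  d2 <- (xyz[, 1L] - center[1L])^2 + (xyz[, 2L] - center[2L])^2 +
    (xyz[, 3L] - center[3L])^2
  lin <- center[1L] + geometry$dim[1L] *
    ((center[2L] - 1L) + geometry$dim[2L] * (center[3L] - 1L))
  if (!geometry$mask[lin]) abort("sphere centre is not in the mask")
  which(d2 <= r^2)
}

#' Precompute all searchlight spheres
#'
#' Enumerates a sphere around every in-mask voxel; centres whose sphere holds
#' fewer than `spec$min_voxels` in-mask members are skipped and listed in the
#' `skipped` element.
#'
#' @inheritParams sphere_indices
#' @return A `searchlight_spheres` object: per-centre member lists plus the
#'   centre bookkeeping (mask positions and full-grid linear indices).
#' @export
build_spheres <- function(geometry, spec = searchlight_spec()) {
  r <- radius_in_voxels(spec, geometry)
  m <- floor(r)
  offs <- as.matrix(expand.grid(dx = -m:m, dy = -m:m, dz = -m:m))
  offs <- offs[rowSums(offs^2) <= r^2, , drop = FALSE]
  xyz <- voxel_coords(geometry)
  V <- geometry$n_voxels
  # full-grid linear index -> in-mask position lookup
  lookup <- integer(prod(geometry$dim))
  lookup[geometry$mask_idx] <- seq_len(V)
  members <- matrix(0L, V, nrow(offs))
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(xyz, 2L, offs[k, ], `+`)
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= geometry$dim[1L] &
      nb[, 2L] >= 1L & nb[, 2L] <= geometry$dim[2L] &
      nb[, 3L] >= 1L & nb[, 3L] <= geometry$dim[3L]
    lin <- (nb[, 3L] - 1L) * geometry$dim[1L] * geometry$dim[2L] +
      (nb[, 2L] - 1L) * geometry$dim[1L] + nb[, 1L]
    pos <- integer(V)
    pos[ok] <- lookup[lin[ok]]
    members[, k] <- pos
  }
  sph <- lapply(seq_len(V), function(v) {
    x <- members[v, ]
    sort(x[x > 0L])
  })
  sizes <- lengths(sph)
  keep <- sizes >= spec$min_voxels
  structure(list(spheres = sph[keep],
                 center_pos = which(keep),
                 center_idx = geometry$mask_idx[keep],
                 skipped = which(!keep),
                 geometry = geometry, spec = spec),
            class = "searchlight_spheres")
}

#' @export
print.searchlight_spheres <- function(x, ...) {
  cat("<searchlight_spheres>", length(x$spheres), "centres, radius",
      x$spec$radius, x$spec$units, "(", length(x$skipped), "skipped )\n")
  invisible(x)
}

#' Per-centre crossnobis RDMs for one subject
#'
#' Runs the compiled searchlight core: at every centre, the local noise
#' covariance is estimated from that sphere's residuals (shrunk toward its
#' diagonal), patterns are whitened locally, and the crossnobis distances of
#' all condition pairs are computed.
#'
#' @param subject A subject record from [generate_cohort()] (`betas` array +
#'   `residuals` list), or any list with those elements.
#' @param spheres A `searchlight_spheres` object.
#' @param conditions Condition tibble matching the beta array.
#' @param lambda Shrinkage intensity, `NULL` for analytic per sphere.
#' @param centers Optional subset of centre positions (indices into the
#'   sphere list) to evaluate.
#' @return Matrix centres x pairs of crossnobis distances.
#' @export
searchlight_rdms <- function(subject, spheres, conditions, lambda = NULL,
                             centers = NULL) {
  d <- dim(subject$betas)
  M <- d[1L]; C <- d[2L]
  # run-major flat layout: row (m - 1) * C + c
  flat <- matrix(0, M * C, d[3L])
  for (m in seq_len(M)) {
    flat[(m - 1L) * C + seq_len(C), ] <- subject$betas[m, , ]
  }
  resid <- do.call(rbind, subject$residuals)
  resid_run <- rep(seq_len(M), vapply(subject$residuals, nrow, 1L))
  pairs <- condition_pairs(conditions)
  sph <- spheres$spheres
  if (!is.null(centers)) sph <- sph[centers]
  cpp_searchlight_rdms(flat, M, C, resid, as.integer(resid_run), sph,
                       pairs$i, pairs$j, lambda %||% -1)
}

#' Mean within-stimulus-type distance maps per subject
#'
#' For every searchlight centre, the mean crossnobis distance over the
#' within-type pair subset of each stimulus type — the statistic used to
#' locate regions carrying reliable pattern information of each type.
#'
#' @inheritParams searchlight_rdms
#' @param types Stimulus types (defaults to the two types in `conditions`).
#' @return Matrix centres x types.
#' @export
within_type_distance_maps <- function(subject, spheres, conditions,
                                      types = unique(conditions$stimulus_type),
                                      lambda = NULL) {
  rdms <- searchlight_rdms(subject, spheres, conditions, lambda)
  masks <- vapply(types, function(tt) {
    m <- partition_mask(conditions, "within_type", type = tt)
    m / sum(m)
  }, numeric(choose(nrow(conditions), 2L)))
  out <- rdms %*% masks
  colnames(out) <- types
  out
}

#' Conjunction group map and cluster-level inference
#'
#' Takes the per-subject within-type distance maps of both stimulus types,
#' computes a one-sample t across subjects per type at every centre, and
#' forms the conjunction statistic (the minimum of the two t values):
#' information must be reliably nonzero *within both stimulus types*.
#' Centres where both t values exceed the one-tailed `peak_p` threshold are
#' grouped into 26-connectivity clusters. Cluster-level p-values come from a
#' subject sign-flip permutation (the same flip applied to both type maps;
#' all `2^n` flips when feasible, otherwise `max_perm` random flips) using
#' the maximal-cluster-size null, and are FDR-corrected (Benjamini-Hochberg)
#' across clusters at `cluster_q`.
#'
#' @param maps List of two subjects x centres matrices (one per stimulus
#'   type).
#' @param spheres The `searchlight_spheres` the maps were computed on.
#' @param peak_p One-tailed voxel-level threshold (default 0.001).
#' @param cluster_q Cluster-level FDR threshold (default 0.05).
#' @param max_perm Cap on the number of sign flips (default 10000).
#' @param seed Seed for random flips (unused when flips are exhaustive).
#' @return A `searchlight_clusters` object: `cluster_table` tibble (size,
#'   peak statistic and coordinates, permutation p, FDR q, `keep`),
#'   per-centre cluster `labels` (0 = none), the two t maps and the
#'   conjunction map.
#' @export
conjunction_group_map <- function(maps, spheres, peak_p = 0.001,
                                  cluster_q = 0.05, max_perm = 10000L,
                                  seed = 1L) {
  stopifnot(length(maps) == 2L)
  n <- nrow(maps[[1L]])
  if (n < 3L) abort("need at least 3 subjects for group inference")
  if (n < 8L) {
    warn("fewer than 8 subjects: sign-flip permutation resolution is coarse")
  }
  df <- n - 1L
  thr <- qt(1 - peak_p, df)
  tmaps <- vapply(maps, map_t_stats, numeric(ncol(maps[[1L]])))
  conj <- pmin(tmaps[, 1L], tmaps[, 2L])
  supra <- which(conj > thr)

  labels <- integer(length(conj))
  tbl <- tibble::tibble(cluster = integer(), size = integer(),
                        peak_stat = numeric(), peak_x = integer(),
                        peak_y = integer(), peak_z = integer(),
                        peak_x_mm = numeric(), peak_y_mm = numeric(),
                        peak_z_mm = numeric(),
                        p_perm = numeric(), q_fdr = numeric(),
                        keep = logical())
  n_perm_used <- 0L
  if (length(supra) > 0L) {
    lab <- cpp_label_clusters(as.integer(spheres$center_idx[supra]),
                              as.integer(spheres$geometry$dim))
    labels[supra] <- lab
    sizes <- tabulate(lab)
    null_max <- perm_max_cluster_sizes(maps, spheres, thr,
                                       max_perm = max_perm, seed = seed)
    n_perm_used <- length(null_max)
    p_perm <- vapply(sizes, function(s) mean(null_max >= s), numeric(1))
    q <- p.adjust(p_perm, "BH")
    peaks <- vapply(seq_along(sizes), function(k) {
      members <- supra[lab == k]
      members[which.max(conj[members])]
    }, integer(1))
    pk_xyz <- arrayInd(spheres$center_idx[peaks], spheres$geometry$dim)
    vs <- spheres$geometry$voxel_size
    tbl <- tibble::tibble(
      cluster = seq_along(sizes), size = sizes,
      peak_stat = conj[peaks],
      peak_x = pk_xyz[, 1L], peak_y = pk_xyz[, 2L], peak_z = pk_xyz[, 3L],
      peak_x_mm = (pk_xyz[, 1L] - 1L) * vs,
      peak_y_mm = (pk_xyz[, 2L] - 1L) * vs,
      peak_z_mm = (pk_xyz[, 3L] - 1L) * vs,
      p_perm = p_perm, q_fdr = q, keep = q < cluster_q
    )
  }
  structure(list(cluster_table = tbl, labels = labels,
                 t_maps = tmaps, conjunction = conj, threshold = thr,
                 spheres = spheres, peak_p = peak_p, cluster_q = cluster_q,
                 n_subjects = n, n_perm = n_perm_used),
            class = "searchlight_clusters")
}

#' @export
print.searchlight_clusters <- function(x, ...) {
  cat("<searchlight_clusters>", nrow(x$cluster_table), "cluster(s) at",
      "conjunction t >", round(x$threshold, 2), "|", sum(x$cluster_table$keep),
      "surviving FDR q <", x$cluster_q, "\n")
  if (nrow(x$cluster_table)) print(x$cluster_table)
  invisible(x)
}

map_t_stats <- function(Y) {
  n <- nrow(Y)
  mu <- colMeans(Y)
  v <- (colSums(Y^2) - n * mu^2) / (n - 1L)
  mu / sqrt(v / n)
}

sign_flip_matrix <- function(n, max_perm, seed) {
  if (2^n <= max_perm) {
    flips <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    dimnames(flips) <- NULL
    flips
  } else {
    with_seed(seed, {
      flips <- matrix(sample(c(1, -1), (max_perm - 1L) * n, replace = TRUE),
                      max_perm - 1L, n)
      rbind(rep(1, n), flips)
    })
  }
}

perm_max_cluster_sizes <- function(maps, spheres, thr, max_perm, seed,
                                   block = 256L) {
  n <- nrow(maps[[1L]])
  flips <- sign_flip_matrix(n, max_perm, seed)
  ss <- lapply(maps, function(Y) colSums(Y^2))  # invariant under flips
  out <- numeric(nrow(flips))
  dims <- as.integer(spheres$geometry$dim)
  idx_full <- as.integer(spheres$center_idx)
  for (start in seq(1L, nrow(flips), by = block)) {
    rows <- start:min(start + block - 1L, nrow(flips))
    tperm <- lapply(seq_along(maps), function(j) {
      mu <- (flips[rows, , drop = FALSE] %*% maps[[j]]) / n
      v <- sweep(-n * mu^2, 2L, ss[[j]], `+`) / (n - 1L)
      mu / sqrt(v / n)
    })
    conj <- pmin(tperm[[1L]], tperm[[2L]])
    for (r in seq_along(rows)) {
      supra <- which(conj[r, ] > thr)
      out[rows[r]] <- if (length(supra) == 0L) 0 else {
        max(tabulate(cpp_label_clusters(idx_full[supra], dims)))
      }
    }
  }
  out
}

#' Direct model-fit searchlight for one subject
#'
#' At every centre, Kendall tau-a between the masked empirical crossnobis
#' distances and a theoretical model's predictions, Fisher-z transformed —
#' the single-step alternative to the two-step procedure, used to test a
#' model voxel-wise.
#'
#' @inheritParams searchlight_rdms
#' @param model A `model_rdm`.
#' @param mask Optional extra pair mask (e.g. a [partition_mask()]),
#'   intersected with the model's own evaluation mask.
#' @return Numeric vector of Fisher-z model fits, one per centre.
#' @export
model_fit_searchlight <- function(subject, spheres, model,
                                  mask = NULL, lambda = NULL) {
  conditions <- attr(model, "conditions")
  sel <- model$included & (mask %||% TRUE)
  if (sum(sel) < 3L) abort("fewer than 3 masked pairs for the model fit")
  pred <- model$value[sel]
  if (length(unique(pred)) < 2L) {
    abort("model predictions are constant on the masked pairs: tau undefined")
  }
  rdms <- searchlight_rdms(subject, spheres, conditions, lambda)
  vapply(seq_len(nrow(rdms)), function(ci) {
    fisher_z(kendall_tau_a(pred, rdms[ci, sel]))
  }, numeric(1))
}

#' Cluster-averaged RDMs per subject
#'
#' For each surviving (or all) clusters, averages the per-centre crossnobis
#' RDMs over the cluster's member centres, separately per subject — the
#' region-level distances used by the second, model-testing step.
#'
#' @param cohort A `cohort`.
#' @param clusters A `searchlight_clusters` result.
#' @param spheres The spheres used for the searchlight.
#' @param which_clusters Cluster ids (default: those with `keep == TRUE`).
#' @param lambda Shrinkage intensity (`NULL` analytic).
#' @return Named list (one element per cluster) of subjects x pairs
#'   matrices.
#' @export
cluster_average_rdms <- function(cohort, clusters, spheres,
                                 which_clusters = NULL, lambda = NULL) {
  tbl <- clusters$cluster_table
  ids <- which_clusters %||% tbl$cluster[tbl$keep]
  if (length(ids) == 0L) return(list())
  members <- lapply(ids, function(k) which(clusters$labels == k))
  out <- lapply(ids, function(k) NULL)
  names(out) <- paste0("cluster_", ids)
  all_centers <- sort(unique(unlist(members)))
  for (s in seq_along(cohort$subjects)) {
    rdms <- searchlight_rdms(cohort$subjects[[s]], spheres,
                             cohort$conditions, lambda,
                             centers = all_centers)
    for (g in seq_along(ids)) {
      rows <- match(members[[g]], all_centers)
      avg <- colMeans(rdms[rows, , drop = FALSE])
      out[[g]] <- rbind(out[[g]], avg)
    }
  }
  out
}

#' Materialise a per-centre statistic as a 3-D volume
#'
#' @param values Numeric vector aligned with the sphere centres.
#' @param spheres The `searchlight_spheres` object.
#' @return 3-D array with `NA` outside the evaluated centres.
#' @export
stat_map_volume <- function(values, spheres) {
  vol <- array(NA_real_, spheres$geometry$dim)
  vol[spheres$center_idx] <- values
  vol
}
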