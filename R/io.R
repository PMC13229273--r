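#' Write a per-voxel statistic map as NIfTI
#'
#' @param values Per-centre statistic vector (aligned with `spheres`), or a
#'   3-D array matching the geometry.
#' @param spheres A `searchlight_spheres` (or a [volume_geometry()] when
#'   `values` is already a 3-D array).
#' @param path Output `.nii` / `.nii.gz` path.
#' @return The path, invisibly.
#' @export
write_stat_map <- function(values, spheres, path) {
  if (inherits(spheres, "searchlight_spheres")) {
    vol <- stat_map_volume(values, spheres)
    vs <- spheres$geometry$voxel_size
  } else {
    vol <- values
    vs <- spheres$voxel_size
  }
  img <- RNifti::asNifti(vol, pixdim = rep(vs, 3L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read per-run beta volumes and residuals from NIfTI files
#'
#' Entry point for externally estimated first-level results: one 4-D volume
#' per run whose 4th dimension holds the condition betas in the order of the
#' condition manifest, plus one 4-D residual volume per run. Voxels are
#' restricted to the supplied mask.
#'
#' @param beta_paths Character vector of per-run beta 4-D NIfTI files.
#' @param residual_paths Per-run residual 4-D NIfTI files.
#' @param conditions Condition manifest tibble (canonical order).
#' @param geometry A [volume_geometry()]; its mask selects the voxels.
#' @return A subject record (`betas` array run x condition x voxel,
#'   `residuals` list) usable anywhere a simulated subject is.
#' @export
read_beta_set <- function(beta_paths, residual_paths, conditions, geometry) {
  stopifnot(length(beta_paths) == length(residual_paths))
  M <- length(beta_paths)
  C <- nrow(conditions)
  V <- geometry$n_voxels
  betas <- array(NA_real_, c(M, C, V))
  residuals <- vector("list", M)
  for (m in seq_len(M)) {
    b <- as.array(RNifti::readNifti(beta_paths[m]))
    if (!identical(dim(b)[1:3], geometry$dim) || dim(b)[4L] != C) {
      abort("beta volume dimensions do not match geometry/manifest")
    }
    flat <- matrix(b, prod(geometry$dim), C)
    betas[m, , ] <- t(flat[geometry$mask_idx, , drop = FALSE])
    r <- as.array(RNifti::readNifti(residual_paths[m]))
    residuals[[m]] <- t(matrix(r, prod(geometry$dim),
                               dim(r)[4L])[geometry$mask_idx, , drop = FALSE])
  }
  list(betas = betas, residuals = residuals)
}

#' Serialise a paradigm spec as a human-readable key-value file
#'
#' @param spec A [paradigm_spec()].
#' @param path Output path.
#' @export
write_paradigm_spec <- function(spec, path) {
  flat <- unlist(spec)
  writeLines(paste(names(flat), flat, sep = " = "), path)
  invisible(path)
}
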