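#' Pipeline configuration
#'
#' Bundles every stage's parameters for an end-to-end synthetic-cohort run:
#' paradigm, geometry, planted effect, noise, searchlight and the inference
#' thresholds. All randomness derives from the single `seed`.
#'
#' @param group Participant group (`"hearing"` or `"deaf"`).
#' @param n_subjects Cohort size.
#' @param spec,geometry,effect,noise,searchlight Component specifications
#'   (defaults are the package defaults).
#' @param mode Cohort generation mode (see [generate_cohort()]).
#' @param peak_p,cluster_q,alpha Voxel threshold, cluster FDR threshold and
#'   two-step significance level.
#' @param max_perm Sign-flip cap for cluster inference.
#' @param reading A [reading_model()].
#' @param effect_sd Between-subject effect-scale sd.
#' @param seed Master seed.
#' @param write_nifti Write statistic maps as NIfTI in [run_pipeline()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(group = "hearing", n_subjects = 12L,
                            spec = paradigm_spec(group),
                            geometry = volume_geometry(),
                            effect = effect_spec(),
                            noise = noise_spec(),
                            searchlight = searchlight_spec(),
                            mode = "betas",
                            peak_p = 0.001, cluster_q = 0.05, alpha = 0.05,
                            max_perm = 10000L,
                            effect_sd = 0.15,
                            reading = reading_model(effect_sd = effect_sd),
                            seed = 1L,
                            write_nifti = FALSE) {
  stopifnot(peak_p > 0, peak_p < 1, cluster_q > 0, cluster_q < 1,
            alpha > 0, alpha < 1)
  structure(list(group = group, n_subjects = as.integer(n_subjects),
                 spec = spec, geometry = geometry, effect = effect,
                 noise = noise, searchlight = searchlight, mode = mode,
                 peak_p = peak_p, cluster_q = cluster_q, alpha = alpha,
                 max_perm = as.integer(max_perm), effect_sd = effect_sd,
                 reading = reading, seed = as.integer(seed),
                 write_nifti = write_nifti),
            class = "pipeline_config")
}

#' Run the full pipeline: simulate, estimate, map, test, report
#'
#' Executes the stages in order — cohort simulation, searchlight crossnobis
#' mapping, conjunction cluster inference, the conditional two-step model
#' tests, brain-behaviour correlation in the clusters with a significant
#' across-type Sublexical fit (falling back to surviving clusters for the
#' Shared Phonemes correlate), and MDS of the group-average RDM in the
#' best cluster. Outputs (tab-separated tables and, optionally, NIfTI maps)
#' are written to `out_dir` with a provenance log recording the config hash
#' and seed. Deterministic: the same config and seed reproduce every output
#' byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips all
#'   file output.
#' @return A `phonorsa_result` bundle: the cohort manifest, cluster object,
#'   two-step fit, correlation table and MDS coordinates.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stage <- "setup"
  result <- tryCatch({
    seeds <- derive_seeds(config$seed, 3L)
    conditions <- enumerate_conditions(config$spec)

    stage <- "simulate"
    cohort <- generate_cohort(
      spec = config$spec, geometry = config$geometry,
      effect = config$effect, noise = config$noise,
      n_subjects = config$n_subjects, effect_sd = config$effect_sd,
      reading = config$reading, mode = config$mode, seed = seeds[1L]
    )

    stage <- "searchlight"
    spheres <- build_spheres(config$geometry, config$searchlight)
    types <- config$spec$stimulus_types
    maps <- lapply(types, function(tt) NULL)
    names(maps) <- types
    for (s in seq_along(cohort$subjects)) {
      wm <- within_type_distance_maps(cohort$subjects[[s]], spheres,
                                      conditions, types)
      for (tt in types) maps[[tt]] <- rbind(maps[[tt]], wm[, tt])
    }

    stage <- "clusters"
    clusters <- conjunction_group_map(maps, spheres,
                                      peak_p = config$peak_p,
                                      cluster_q = config$cluster_q,
                                      max_perm = config$max_perm,
                                      seed = seeds[2L])

    stage <- "two_step"
    fits <- NULL
    corr <- NULL
    mds <- NULL
    keep <- clusters$cluster_table$cluster[clusters$cluster_table$keep]
    if (length(keep)) {
      cl_rdms <- cluster_average_rdms(cohort, clusters, spheres,
                                      which_clusters = keep)
      fits <- run_two_step(cl_rdms, conditions, alpha = config$alpha)

      stage <- "behaviour"
      ft <- fits$table
      sig_sub <- ft$cluster[ft$model == "sublexical" & ft$step == 3L &
                              ft$significant]
      corr_clusters <- if (length(sig_sub)) sig_sub else names(cl_rdms)
      sp <- shared_phonemes_model(conditions)
      across <- partition_mask(conditions, "across_type")
      corr <- dplyr::bind_rows(lapply(corr_clusters, function(cl) {
        z <- apply(cl_rdms[[cl]], 1L, function(dd) {
          rdm_model_fit(dd, sp, across)$z
        })
        out <- brain_behavior_corr(z, cohort$manifest$reading)
        dplyr::mutate(tibble::as_tibble(unclass(out)), cluster = cl,
                      .before = 1L)
      }))

      stage <- "mds"
      best <- names(cl_rdms)[1L]
      rdm <- crossnobis_template(conditions, colMeans(cl_rdms[[best]]))
      suppressWarnings(mds <- classical_mds(rdm))
    }

    stage <- "report"
    if (!is.null(out_dir)) {
      write_outputs(out_dir, config, cohort, clusters, fits, corr, mds,
                    spheres)
    }
    structure(list(manifest = cohort$manifest, clusters = clusters,
                   fits = fits, behaviour = corr, mds = mds,
                   conditions = conditions, config = config),
              class = "phonorsa_result")
  }, error = function(e) {
    abort(paste0("pipeline failed at stage '", stage, "': ",
                 conditionMessage(e)))
  })
  result
}

# wrap a raw distance vector in an rdm_data skeleton
crossnobis_template <- function(conditions, distances) {
  pairs <- condition_pairs(conditions)
  out <- dplyr::mutate(pairs, distance = distances)
  structure(out, class = c("rdm_data", class(pairs)),
            conditions = conditions, n_runs = NA_integer_,
            n_voxels = NA_integer_)
}

write_outputs <- function(out_dir, config, cohort, clusters, fits, corr, mds,
                          spheres) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_cohort_manifest(cohort, p("cohort_manifest.tsv"))
  readr::write_tsv(clusters$cluster_table, p("cluster_table.tsv"))
  if (!is.null(fits)) readr::write_tsv(fits$table, p("model_fits.tsv"))
  if (!is.null(corr)) readr::write_tsv(corr, p("brain_behaviour.tsv"))
  if (!is.null(mds)) {
    readr::write_tsv(tibble::as_tibble(mds), p("mds_coords.tsv"))
    ggplot2::ggsave(p("mds_plot.pdf"),
                    autoplot(mds, conditions = cohort$conditions),
                    width = 6, height = 5)
  }
  if (!is.null(fits)) {
    ggplot2::ggsave(p("model_fits.pdf"), autoplot(fits),
                    width = 7, height = 4)
  }
  if (isTRUE(config$write_nifti)) {
    write_stat_map(clusters$conjunction, spheres, p("conjunction_t.nii.gz"))
    write_stat_map(as.numeric(clusters$labels), spheres, p("clusters.nii.gz"))
  }
  writeLines(c(
    paste("phonorsa", as.character(utils::packageVersion("phonorsa"))),
    paste("config_hash", rlang::hash(config)),
    paste("seed", config$seed),
    paste("group", config$group),
    paste("n_subjects", config$n_subjects),
    paste("mode", config$mode),
    paste("stages", "simulate searchlight clusters two_step behaviour mds report")
  ), p("provenance.txt"))
  invisible(out_dir)
}

#' @export
print.phonorsa_result <- function(x, ...) {
  cat("<phonorsa_result>", x$config$group, "group,",
      nrow(x$manifest), "subjects\n")
  print(x$clusters)
  if (!is.null(x$fits)) print(glance(x$fits))
  invisible(x)
}
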