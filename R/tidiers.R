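#' @export
tidy.two_step_fit <- function(x, ...) x$table

#' @export
glance.two_step_fit <- function(x, ...) {
  tibble::tibble(
    n_clusters = dplyr::n_distinct(x$table$cluster),
    n_tests = nrow(x$table),
    n_significant = sum(x$table$significant),
    alpha = x$alpha
  )
}

#' @export
tidy.searchlight_clusters <- function(x, ...) x$cluster_table

#' @export
glance.searchlight_clusters <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x$cluster_table),
    n_surviving = sum(x$cluster_table$keep),
    threshold_t = x$threshold,
    n_subjects = x$n_subjects,
    n_perm = x$n_perm
  )
}

#' @export
tidy.behavior_correlation <- function(x, ...) tibble::as_tibble(unclass(x))

# -- plotting ----------------------------------------------------------------

rdm_plot_df <- function(x) {
  m <- rdm_matrix(x)
  labs <- rownames(m)
  tibble::tibble(
    cond_i = factor(rep(labs, times = ncol(m)), levels = labs),
    cond_j = factor(rep(labs, each = nrow(m)), levels = rev(labs)),
    value = as.numeric(m)
  )
}

#' Heatmap of a theoretical or empirical RDM
#'
#' @param object A `model_rdm` or `rdm_data`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.model_rdm <- function(object, ...) {
  df <- rdm_plot_df(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$cond_i, .data$cond_j,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, fill = "dissimilarity",
                  title = attr(object, "model")) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1, vjust = 0.5))
}

#' @export
autoplot.rdm_data <- function(object, ...) {
  p <- autoplot.model_rdm(object, ...)
  p + ggplot2::labs(fill = "crossnobis", title = "empirical RDM")
}

#' Forest-style plot of two-step model fits
#'
#' Mean Fisher-z fit per cluster, model and distance partition, with the
#' significance flag after Bonferroni correction.
#'
#' @param object A `two_step_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.two_step_fit <- function(object, ...) {
  df <- object$table
  ggplot2::ggplot(df, ggplot2::aes(.data$mean_z, .data$cluster,
                                   colour = .data$partition,
                                   shape = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = "mean Fisher-z model fit", y = NULL) +
    ggplot2::theme_minimal(base_size = 9)
}

#' MDS plot of the representational space
#'
#' @param object An `mds_coords` tibble from [classical_mds()].
#' @param conditions Optional condition tibble to colour by word and shape
#'   by stimulus type.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mds_coords <- function(object, conditions = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(conditions)) {
    df <- dplyr::left_join(df, conditions, by = "condition")
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2,
                                          colour = .data$word,
                                          shape = .data$stimulus_type))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2))
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "MDS dimension 1", y = "MDS dimension 2") +
    ggplot2::theme_minimal(base_size = 9)
}
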