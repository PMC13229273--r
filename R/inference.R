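#' Kendall tau-a rank correlation
#'
#' The tau-a variant: `(concordant - discordant) / (n (n - 1) / 2)`. Pairs
#' tied in either vector count as neither concordant nor discordant but stay
#' in the denominator, which is the appropriate variant when a model RDM
#' predicts tied ranks (a model predicting ties is penalised for them rather
#' than rescaled). This differs from `cor(..., method = "kendall")`, which
#' computes tau-b.
#'
#' @param x,y Numeric vectors of equal length (n >= 2).
#' @return Tau-a in `[-1, 1]`.
#' @export
#' @examples
#' kendall_tau_a(c(1, 2, 3, 4), c(1, 2, 3, 4))  #  1
#' kendall_tau_a(c(1, 1, 2), c(1, 2, 3))        #  2/3: one tied pair
kendall_tau_a <- function(x, y) {
  n <- length(x)
  if (length(y) != n) abort("x and y must have equal length")
  if (n < 2L) abort("need at least 2 observations")
  sx <- sign(outer(x, x, `-`))
  sy <- sign(outer(y, y, `-`))
  cd <- sum((sx * sy)[upper.tri(sx)])
  cd / (n * (n - 1L) / 2)
}

#' Fisher z transform
#'
#' `atanh(r)`, variance-stabilising correlation coefficients for group-level
#' testing. Coefficients at exactly +-1 are clamped inward by a machine
#' epsilon with a warning.
#'
#' @param r Correlation(s) in `[-1, 1]`.
#' @return Fisher z value(s).
#' @export
fisher_z <- function(r) {
  eps <- sqrt(.Machine$double.eps)
  if (any(abs(r) >= 1)) {
    warn("correlation at +-1 clamped before Fisher z transform")
    r <- pmin(pmax(r, -1 + eps), 1 - eps)
  }
  atanh(r)
}

#' One-sample and paired t-tests with Cohen's d_z
#'
#' Thin, tibble-returning layers over [stats::t.test()] that additionally
#' report the within-subject effect size `d_z = mean / sd = t / sqrt(n)`.
#' Model fits are predicted positive, so the default for the one-sample test
#' is one-tailed (greater than zero); paired comparisons between models are
#' two-tailed.
#'
#' @param x Numeric vector (one-sample) or first paired sample.
#' @param tail `"one"` (greater) or `"two"`.
#' @param mu Null value.
#' @return One-row tibble: `estimate`, `t`, `df`, `p`, `d_z`, `n`, `tail`.
#' @export
one_sample_t <- function(x, tail = c("one", "two"), mu = 0) {
  tail <- match.arg(tail)
  if (length(x) < 2L) abort("need at least 2 observations")
  if (sd(x) == 0) abort("zero variance: t statistic undefined")
  ht <- t.test(x, mu = mu,
               alternative = if (tail == "one") "greater" else "two.sided")
  n <- length(x)
  tibble::tibble(estimate = unname(ht$estimate), t = unname(ht$statistic),
                 df = unname(ht$parameter), p = ht$p.value,
                 d_z = unname(ht$statistic) / sqrt(n), n = n, tail = tail)
}

#' @rdname one_sample_t
#' @param y Second paired sample.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) abort("paired samples must have equal length")
  d <- x - y
  if (all(d == 0)) {
    # identical samples: no difference, by convention t = 0, p = 1
    return(tibble::tibble(estimate = 0, t = 0, df = length(d) - 1L, p = 1,
                          d_z = 0, n = length(d), tail = "two"))
  }
  one_sample_t(d, tail = "two")
}

#' Fit a theoretical model to empirical distances (one subject)
#'
#' Kendall tau-a between a model's predictions and the empirical crossnobis
#' distances on the selected pair subset, plus its Fisher z.
#'
#' @param distances Numeric vector over the canonical pair list, or an
#'   `rdm_data` object.
#' @param model A `model_rdm`.
#' @param mask Optional extra [partition_mask()] intersected with the
#'   model's evaluation mask.
#' @return One-row tibble with `model`, `n_pairs`, `tau`, `z`.
#' @export
rdm_model_fit <- function(distances, model, mask = NULL) {
  if (inherits(distances, "rdm_data")) distances <- distances$distance
  sel <- model$included & (mask %||% TRUE)
  if (sum(sel) < 3L) abort("fewer than 3 pairs selected for the model fit")
  pred <- model$value[sel]
  if (length(unique(pred)) < 2L) {
    abort("model predictions are constant on the masked pairs")
  }
  tau <- kendall_tau_a(pred, distances[sel])
  tibble::tibble(model = attr(model, "model"), n_pairs = sum(sel),
                 tau = tau, z = fisher_z(tau))
}

# group-level one-tailed test of per-subject Fisher z fits
group_model_test <- function(z_by_subject) {
  one_sample_t(z_by_subject, tail = "one")
}

#' The conditional two-step model-testing procedure
#'
#' Runs the gated test sequence over a set of region-level (cluster-averaged)
#' RDMs:
#'
#' 1. *Within-stimulus gate* — fit of the Shared Phonemes model to the
#'    combined within-type distances, tested in every cluster (Bonferroni
#'    over the number of clusters).
#' 2. *Across-stimulus Shared Phonemes* — only in clusters passing step 1
#'    (Bonferroni over the number of clusters tested at this step).
#' 3. *Sublexical and Lexical, across-stimulus* — only in clusters passing
#'    step 2 (Bonferroni per model over the number of clusters tested).
#' 4. *Per-type follow-up* — for clusters with a significant across-type
#'    Sublexical fit, the Sublexical model is additionally tested in each
#'    stimulus type's within-type distances separately.
#'
#' Every fit is Kendall tau-a per subject, Fisher-z transformed, and tested
#' against zero with a one-tailed one-sample t-test; the Bonferroni family at
#' each step is the number of clusters in which that model is tested.
#'
#' @param cluster_rdms Named list of subjects x pairs matrices, as returned
#'   by [cluster_average_rdms()].
#' @param conditions Condition tibble.
#' @param alpha Significance level after Bonferroni correction.
#' @return A `two_step_fit` object; `tidy()` returns the per-test table.
#' @export
run_two_step <- function(cluster_rdms, conditions, alpha = 0.05) {
  types <- unique(conditions$stimulus_type)
  models <- list(
    shared_phonemes = shared_phonemes_model(conditions),
    sublexical = sublexical_model(conditions),
    lexical = lexical_model(conditions)
  )
  masks <- list(
    within = partition_mask(conditions, "within_type_any"),
    across = partition_mask(conditions, "across_type")
  )
  for (tt in types) {
    masks[[paste0("within_", tt)]] <-
      partition_mask(conditions, "within_type", type = tt)
  }
  clusters <- names(cluster_rdms)
  rows <- list()
  fit_in <- function(cluster, model_name, mask_name, step, n_family) {
    rdms <- cluster_rdms[[cluster]]
    z <- apply(rdms, 1L, function(dd) {
      rdm_model_fit(dd, models[[model_name]], masks[[mask_name]])$z
    })
    res <- group_model_test(z)
    tibble::tibble(cluster = cluster, step = step, model = model_name,
                   partition = mask_name, n = res$n, mean_z = mean(z),
                   t = res$t, df = res$df, p = res$p, d_z = res$d_z,
                   n_family = n_family,
                   p_bonf = min(1, res$p * n_family),
                   significant = res$p * n_family < alpha)
  }

  step1 <- dplyr::bind_rows(lapply(clusters, fit_in,
                                   model_name = "shared_phonemes",
                                   mask_name = "within", step = 1L,
                                   n_family = length(clusters)))
  pass1 <- step1$cluster[step1$significant]
  rows$step1 <- step1

  if (length(pass1)) {
    step2 <- dplyr::bind_rows(lapply(pass1, fit_in,
                                     model_name = "shared_phonemes",
                                     mask_name = "across", step = 2L,
                                     n_family = length(pass1)))
    rows$step2 <- step2
    pass2 <- step2$cluster[step2$significant]
    if (length(pass2)) {
      step3 <- dplyr::bind_rows(lapply(c("sublexical", "lexical"), function(mm) {
        dplyr::bind_rows(lapply(pass2, fit_in, model_name = mm,
                                mask_name = "across", step = 3L,
                                n_family = length(pass2)))
      }))
      rows$step3 <- step3
      pass3 <- step3$cluster[step3$model == "sublexical" & step3$significant]
      if (length(pass3)) {
        rows$followup <- dplyr::bind_rows(lapply(types, function(tt) {
          dplyr::bind_rows(lapply(pass3, fit_in, model_name = "sublexical",
                                  mask_name = paste0("within_", tt),
                                  step = 4L, n_family = length(pass3)))
        }))
      }
    }
  }
  structure(list(table = dplyr::bind_rows(rows), alpha = alpha,
                 conditions = conditions),
            class = "two_step_fit")
}

#' @export
print.two_step_fit <- function(x, ...) {
  cat("<two_step_fit>", nrow(x$table), "tests over",
      dplyr::n_distinct(x$table$cluster), "cluster(s)\n")
  print(x$table)
  invisible(x)
}

#' Contrast of encoding strength across phoneme positions
#'
#' One-way repeated-measures ANOVA of per-subject model fits over the three
#' segment positions (initial consonant, vowel, final consonant), asking
#' whether any position is encoded more strongly than the others. With n
#' subjects the F statistic has (2, 2(n - 1)) degrees of freedom.
#'
#' @param fits Subjects x 3 matrix (columns initial/vowel/final) or a long
#'   tibble with columns `subject`, `position`, `z`.
#' @return One-row tibble: `F`, `df1`, `df2`, `p`.
#' @export
segment_position_contrast <- function(fits) {
  if (is.matrix(fits) || is.data.frame(fits) && !"position" %in% names(fits)) {
    fits <- as.matrix(fits)
    long <- tibble::tibble(
      subject = factor(rep(seq_len(nrow(fits)), ncol(fits))),
      position = factor(rep(colnames(fits) %||%
                              paste0("pos", seq_len(ncol(fits))),
                            each = nrow(fits))),
      z = as.numeric(fits)
    )
  } else {
    long <- dplyr::mutate(fits, subject = factor(.data$subject),
                          position = factor(.data$position))
  }
  if (nlevels(long$subject) < 2L) abort("need at least 2 subjects")
  # identical fits across positions: no within-subject variation at all,
  # so the contrast is exactly null
  subj_mean <- stats::ave(long$z, long$subject)
  if (all(abs(long$z - subj_mean) < 1e-12)) {
    n <- nlevels(long$subject)
    k <- nlevels(long$position)
    return(tibble::tibble(F = 0, df1 = k - 1L, df2 = (k - 1L) * (n - 1L),
                          p = 1))
  }
  fit <- aov(z ~ position + Error(subject), data = long)
  s <- summary(fit)[["Error: Within"]][[1L]]
  tibble::tibble(F = s["position", "F value"],
                 df1 = s["position", "Df"],
                 df2 = s["Residuals", "Df"],
                 p = s["position", "Pr(>F)"])
}

#' Brain-behaviour correlation
#'
#' Pearson correlation between per-subject across-stimulus model fits and
#' reading scores, with a one-tailed (positive) p-value from
#' `t = r sqrt(n - 2) / sqrt(1 - r^2)`.
#'
#' @param fits Per-subject model-fit values (Fisher z).
#' @param scores Per-subject reading scores.
#' @return A `behavior_correlation` tibble: `r`, `n`, `df`, `t`, `p`.
#' @export
brain_behavior_corr <- function(fits, scores) {
  n <- length(fits)
  if (n < 4L) abort("need at least 4 subjects for the correlation")
  if (length(scores) != n) abort("fits and scores must have equal length")
  if (sd(fits) == 0 || sd(scores) == 0) {
    abort("zero variance in fits or scores")
  }
  ht <- suppressWarnings(cor.test(fits, scores, alternative = "greater"))
  out <- tibble::tibble(r = unname(ht$estimate), n = n, df = n - 2L,
                        t = unname(ht$statistic), p = ht$p.value)
  structure(out, class = c("behavior_correlation", class(out)))
}

#' Classical multidimensional scaling of an RDM
#'
#' Torgerson double-centring (via [stats::cmdscale()]): embeds the conditions
#' in a low-dimensional space whose inter-point distances approximate the
#' representational distances. Negative estimated distances (legitimate for
#' the unbiased crossnobis estimator) are clamped to zero with a warning;
#' dimensions beyond the number of positive eigenvalues are dropped with a
#' warning.
#'
#' @param rdm An `rdm_data`, a square symmetric matrix, or a `dist`.
#' @param dims Number of embedding dimensions (default 2).
#' @return An `mds_coords` tibble: `condition`, `dim1`, `dim2`, ...
#'   (attribute `eig`: the eigenvalues).
#' @export
classical_mds <- function(rdm, dims = 2L) {
  m <- if (inherits(rdm, c("rdm_data", "model_rdm"))) rdm_matrix(rdm)
       else as.matrix(rdm)
  if (any(is.na(m[upper.tri(m)]))) abort("MDS needs a complete distance matrix")
  diag(m) <- 0
  if (any(m < 0)) {
    warn("negative distances clamped to 0 for MDS")
    m[m < 0] <- 0
  }
  if (nrow(m) == 1L) {
    out <- tibble::tibble(condition = rownames(m) %||% "1", dim1 = 0)
    if (dims >= 2L) out$dim2 <- 0
    return(structure(out, class = c("mds_coords", class(out)), eig = 0))
  }
  fit <- cmdscale(stats::as.dist(m), k = min(dims, nrow(m) - 1L), eig = TRUE)
  pts <- as.matrix(fit$points)
  pos <- sum(fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig)))
  if (ncol(pts) < dims || pos < dims) {
    warn(paste("only", ncol(pts), "positive-eigenvalue dimensions available"))
  }
  out <- tibble::as_tibble(pts, .name_repair = ~ paste0("dim", seq_along(.x)))
  out <- dplyr::mutate(out, condition = rownames(m) %||%
                         as.character(seq_len(nrow(m))), .before = 1L)
  structure(out, class = c("mds_coords", class(out)), eig = fit$eig)
}
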