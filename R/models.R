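#' Unordered condition pairs in canonical order
#'
#' Enumerates all C(n, 2) unordered condition pairs of a condition table, in
#' row-major order of the canonical condition ordering (`i < j`). Every RDM in
#' the package — theoretical or empirical — is stored over this pair list, so
#' pair indices are directly comparable across objects.
#'
#' @param conditions Condition tibble from [enumerate_conditions()].
#' @return A tibble with one row per pair: indices `i`, `j`, condition labels
#'   and the word/stimulus-type/form fields of both members.
#' @export
condition_pairs <- function(conditions) {
  n <- nrow(conditions)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  # order pairs i-major
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  i <- unname(idx[, "row"]); j <- unname(idx[, "col"])
  tibble::tibble(
    pair = seq_along(i),
    i = i, j = j,
    cond_i = conditions$condition[i], cond_j = conditions$condition[j],
    word_i = conditions$word[i], word_j = conditions$word[j],
    type_i = conditions$stimulus_type[i], type_j = conditions$stimulus_type[j],
    form_i = conditions$form[i], form_j = conditions$form[j]
  )
}

#' Pair-subset masks over the condition pairs
#'
#' Builds the logical selector over [condition_pairs()] used to restrict an
#' analysis to a subset of distances:
#'
#' * `within_type` — both conditions of the pair share the given
#'   `stimulus_type` (120 pairs per type for the 32-condition design);
#' * `within_type_any` — both members share a type, either type (240 pairs);
#' * `across_type` — the two members differ in stimulus type (256 pairs);
#' * `across_form_within_type` — same type, different form;
#' * `same_form_within_type` — same type, same form.
#'
#' @param conditions Condition tibble.
#' @param relation One of the relations above.
#' @param type Stimulus type, required for `relation = "within_type"`.
#' @return A logical vector over the pair list (attribute `relation`).
#' @export
partition_mask <- function(conditions,
                           relation = c("within_type", "within_type_any",
                                        "across_type",
                                        "across_form_within_type",
                                        "same_form_within_type"),
                           type = NULL) {
  relation <- match.arg(relation)
  p <- condition_pairs(conditions)
  same_type <- p$type_i == p$type_j
  mask <- switch(relation,
    within_type = {
      if (is.null(type)) abort("relation 'within_type' needs a `type`")
      same_type & p$type_i == type
    },
    within_type_any = same_type,
    across_type = !same_type,
    across_form_within_type = same_type & p$form_i != p$form_j,
    same_form_within_type = same_type & p$form_i == p$form_j
  )
  structure(mask, relation = relation, type = type)
}

new_model_rdm <- function(pairs, value, included, conditions, name) {
  out <- dplyr::mutate(pairs, value = value, included = included)
  structure(out,
            class = c("model_rdm", class(pairs)),
            conditions = conditions, model = name)
}

#' Theoretical dissimilarity models
#'
#' The three word-level models, defined over all condition pairs:
#'
#' * `shared_phonemes_model()` — dissimilarity between two conditions is the
#'   number of phoneme positions at which their words differ,
#'   `3 - shared_phoneme_count()`; same-word pairs (any form or stimulus
#'   type) get 0. All pairs are evaluated. This model mixes lexical and
#'   sublexical similarity.
#' * `sublexical_model()` — identical predictions, but every pair whose two
#'   conditions carry the same lexical word is excluded from evaluation, so
#'   that any fit is carried by partial phoneme overlap between *different*
#'   words only (phonology conditional on lexical identity).
#' * `lexical_model()` — 0 for same-word pairs and 1 for all different-word
#'   pairs: each word is most similar to itself and equally dissimilar to
#'   every other word.
#' * `position_model()` — 0 if the two words share the phoneme at one
#'   position (`initial`, `vowel` or `final`), else 1; same-word pairs are
#'   excluded so position effects cannot be driven by word identity.
#'
#' Model values are kept on an integer scale; model-data comparison uses
#' Kendall tau-a, which only sees ranks, so any affine rescaling of the
#' predictions is equivalent.
#'
#' @param conditions Condition tibble from [enumerate_conditions()].
#' @return A `model_rdm`: the pair tibble with `value` (predicted
#'   dissimilarity) and `included` (evaluation mask) columns.
#' @export
shared_phonemes_model <- function(conditions) {
  p <- condition_pairs(conditions)
  value <- 3L - shared_phoneme_count(p$word_i, p$word_j)
  new_model_rdm(p, value, rep(TRUE, nrow(p)), conditions, "shared_phonemes")
}

#' @rdname shared_phonemes_model
#' @export
sublexical_model <- function(conditions) {
  m <- shared_phonemes_model(conditions)
  m$included <- m$word_i != m$word_j
  attr(m, "model") <- "sublexical"
  m
}

#' @rdname shared_phonemes_model
#' @export
lexical_model <- function(conditions) {
  p <- condition_pairs(conditions)
  value <- as.integer(p$word_i != p$word_j)
  new_model_rdm(p, value, rep(TRUE, nrow(p)), conditions, "lexical")
}

#' @rdname shared_phonemes_model
#' @param position Phoneme position: `"initial"`, `"vowel"` or `"final"`.
#' @export
position_model <- function(conditions, position = c("initial", "vowel", "final")) {
  position <- match.arg(position)
  p <- condition_pairs(conditions)
  words <- word_set()
  ph <- words[[position]]
  value <- as.integer(ph[match(p$word_i, words$word)] !=
                        ph[match(p$word_j, words$word)])
  new_model_rdm(p, value, p$word_i != p$word_j, conditions,
                paste0("position_", position))
}

#' Square-matrix view of an RDM
#'
#' Expands a pair-table RDM (theoretical `model_rdm` or empirical `rdm_data`)
#' into a symmetric condition x condition matrix. Cells outside the
#' evaluation mask are `NA`; the diagonal is `NA` (self-pairs are never
#' estimated).
#'
#' @param x A `model_rdm` or `rdm_data` object.
#' @return A numeric matrix with condition labels as dimnames.
#' @export
rdm_matrix <- function(x) {
  conditions <- attr(x, "conditions")
  n <- nrow(conditions)
  v <- if ("value" %in% names(x)) x$value else x$distance
  if ("included" %in% names(x)) v[!x$included] <- NA_real_
  m <- matrix(NA_real_, n, n,
              dimnames = list(conditions$condition, conditions$condition))
  m[cbind(x$i, x$j)] <- v
  m[cbind(x$j, x$i)] <- v
  m
}

#' Export an RDM and its condition manifest as tab-separated text
#'
#' Writes the square-matrix view (masked cells as `NA`) plus a companion
#' `<path>_conditions.tsv` manifest with the canonical condition ordering.
#'
#' @param x A `model_rdm` or `rdm_data`.
#' @param path Output file for the matrix.
#' @export
write_rdm <- function(x, path) {
  m <- rdm_matrix(x)
  df <- tibble::as_tibble(m, .name_repair = "minimal")
  df <- dplyr::mutate(df, condition = rownames(m), .before = 1L)
  readr::write_tsv(df, path)
  manifest <- attr(x, "conditions")
  readr::write_tsv(manifest, sub("(\\.[a-zA-Z]+)?$", "_conditions.tsv", path))
  invisible(path)
}
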