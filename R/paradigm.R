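#' Paradigm specification
#'
#' Describes the sparse-sampling fMRI paradigm for one participant group:
#' the stimulus types shown to that group, the per-run trial composition, and
#' the spacing constraints used when pseudorandomly distributing null and
#' target/decision trials through a run.
#'
#' Each run holds 170 trials of 3.95 s (one brain volume per trial): 128
#' stimulus trials, 10 null (rest) trials, 16 target trials and 16 decision
#' trials, each decision immediately following its target. Spacing constraints
#' are expressed as a discretised truncated-normal distribution over gaps in
#' trial indices; the defaults emulate the observed summaries of the original
#' design (null gaps: min 8, max 26, mean 17, sd 3; target-pair gaps: min 7,
#' max 14, mean 11, sd 2).
#'
#' @param group `"hearing"` (visual speech + auditory speech) or `"deaf"`
#'   (visual speech + dynamic text).
#' @param n_runs Number of runs per session.
#' @param trial_duration Trial (= volume repetition) duration in seconds.
#' @param n_stimulus,n_null,n_target,n_decision Per-run trial composition.
#' @param null_gap,target_gap Lists with elements `min`, `max`, `mean`, `sd`
#'   giving the gap distribution (in trial indices) for successive null trials
#'   and successive target-decision pairs.
#' @param stimulus_delay Seconds from trial (volume) onset to stimulus onset;
#'   stimuli play in the silent gap after the 2.45 s acquisition window.
#' @param acquisition_time Volume acquisition duration (s); sampling times for
#'   the GLM are taken at acquisition midpoints.
#' @param max_attempts Bound on rejection-sampling attempts before the
#'   generator fails with the violated constraint.
#' @return A `paradigm_spec` object (a list).
#' @export
paradigm_spec <- function(group = c("hearing", "deaf"),
                          n_runs = 4L,
                          trial_duration = 3.95,
                          n_stimulus = 128L,
                          n_null = 10L,
                          n_target = 16L,
                          n_decision = 16L,
                          null_gap = list(min = 8, max = 26, mean = 17, sd = 3),
                          target_gap = list(min = 7, max = 14, mean = 11, sd = 2),
                          stimulus_delay = 2.5,
                          acquisition_time = 2.45,
                          max_attempts = 1000L) {
  group <- match.arg(group)
  n_total <- n_stimulus + n_null + n_target + n_decision
  if (n_decision != n_target) {
    abort("each decision trial follows a target trial: counts must match")
  }
  spec <- list(
    group = group,
    stimulus_types = switch(group,
      hearing = c("visual_speech", "auditory_speech"),
      deaf    = c("visual_speech", "dynamic_text")
    ),
    n_runs = as.integer(n_runs),
    trial_duration = trial_duration,
    n_stimulus = as.integer(n_stimulus),
    n_null = as.integer(n_null),
    n_target = as.integer(n_target),
    n_decision = as.integer(n_decision),
    n_total = as.integer(n_total),
    null_gap = null_gap,
    target_gap = target_gap,
    stimulus_delay = stimulus_delay,
    acquisition_time = acquisition_time,
    max_attempts = as.integer(max_attempts)
  )
  structure(spec, class = "paradigm_spec")
}

#' @export
print.paradigm_spec <- function(x, ...) {
  cat("<paradigm_spec> group:", x$group,
      "| types:", paste(x$stimulus_types, collapse = " / "), "\n")
  cat("  runs:", x$n_runs, "x", x$n_total, "trials",
      sprintf("(%d stimulus, %d null, %d target, %d decision) @ %.2f s",
              x$n_stimulus, x$n_null, x$n_target, x$n_decision,
              x$trial_duration), "\n")
  invisible(x)
}

#' Enumerate the 32 conditions of a group's design
#'
#' Builds the word x stimulus-type x form condition grid in the canonical
#' order used everywhere in the package: word-major (in [word_set()] order),
#' then stimulus type (visual speech first), then form (`A`, `B`). RDM rows,
#' columns and pair indices all follow this ordering, so it is stable across
#' calls and documented here once.
#'
#' @param spec A [paradigm_spec()].
#' @return A tibble with 32 rows and columns `condition`, `word`,
#'   `stimulus_type`, `form`.
#' @export
enumerate_conditions <- function(spec = paradigm_spec()) {
  words <- word_set()$word
  grid <- tidyr::expand_grid(
    word = words,
    stimulus_type = spec$stimulus_types,
    form = c("A", "B")
  )
  dplyr::mutate(grid,
    condition = paste(.data$word, .data$stimulus_type, .data$form, sep = "."),
    .before = 1L
  )
}

#' Enumerate the 64 unique stimuli
#'
#' Each condition was recorded/rendered in two exemplars, giving 64 unique
#' stimuli per group (8 words x 2 stimulus types x 2 forms x 2 exemplars).
#'
#' @inheritParams enumerate_conditions
#' @return A tibble with 64 rows; `stimulus` is the unique label.
#' @export
enumerate_stimuli <- function(spec = paradigm_spec()) {
  conds <- enumerate_conditions(spec)
  grid <- tidyr::expand_grid(condition = conds$condition, exemplar = c(1L, 2L))
  grid <- dplyr::left_join(grid, conds, by = "condition")
  dplyr::mutate(grid,
    stimulus = paste(.data$condition, .data$exemplar, sep = "."),
    .before = 1L
  )[, c("stimulus", "condition", "word", "stimulus_type", "form", "exemplar")]
}

#' Per-stimulus presentation durations
#'
#' Draws a fixed duration for each unique stimulus (uniform within the
#' recorded range of its stimulus type), held constant across that stimulus'
#' repetitions. Ranges follow the recorded materials: auditory words
#' 0.558-0.972 s, visual speech 1.04-1.36 s, dynamic text 1.00-1.32 s.
#'
#' @inheritParams enumerate_conditions
#' @param seed Integer seed for the draw.
#' @return The [enumerate_stimuli()] tibble with a `duration` column (s).
#' @export
stimulus_durations <- function(spec = paradigm_spec(), seed = 1L) {
  stim <- enumerate_stimuli(spec)
  range_for <- function(type) {
    switch(type,
      auditory_speech = c(0.558, 0.972),
      visual_speech   = c(1.040, 1.360),
      dynamic_text    = c(1.000, 1.320)
    )
  }
  with_seed(seed, {
    stim$duration <- vapply(stim$stimulus_type, function(tt) {
      r <- range_for(tt)
      round(runif(1L, r[1L], r[2L]), 3L)
    }, numeric(1))
  })
  stim
}
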