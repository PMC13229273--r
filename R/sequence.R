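#' Generate one constrained run sequence
#'
#' Builds the ordered trial sequence of a single run: 128 stimulus trials in
#' two blocks of 64 (each block a permutation of all 64 unique stimuli), 10
#' null trials, and 16 target-decision pairs, 170 trials in total. Placement
#' is pseudorandom under the paradigm's constraints:
#'
#' * the first null trial opens the run (the run-start rest trial); gaps
#'   between successive nulls follow the spec's `null_gap` distribution;
#' * every decision trial immediately follows its target trial; gaps between
#'   successive target-pair onsets follow `target_gap` as a soft constraint
#'   (collisions with already-placed trials shift a pair forward);
#' * no two consecutive trials present the same lexical word, regardless of
#'   stimulus type (target trials present stimuli too and are included).
#'
#' Generation rejection-samples until all hard constraints hold, failing with
#' the violated constraint after `spec$max_attempts` attempts.
#'
#' @param spec A [paradigm_spec()].
#' @param run_index Run number (1-based).
#' @param seed Integer seed; the same seed reproduces the run exactly.
#' @param targets Optional tibble of 16 target stimuli for this run (columns
#'   as [enumerate_stimuli()]); when `NULL` a balanced per-run set is drawn
#'   (all 8 words in each stimulus type, forms and exemplars balanced).
#' @param durations Optional [stimulus_durations()] table; drawn from `seed`
#'   when missing.
#' @return A `run_sequence` tibble with one row per trial: `index` (0-based),
#'   `onset` (s, `index * trial_duration`), `kind`, `stimulus`, `condition`,
#'   `word`, `stimulus_type`, `form`, `exemplar`, `duration`.
#' @export
#' @examples
#' run <- generate_run_sequence(paradigm_spec(), run_index = 1, seed = 7)
#' dplyr::count(run, kind)
generate_run_sequence <- function(spec = paradigm_spec(), run_index = 1L,
                                  seed = 1L, targets = NULL,
                                  durations = NULL) {
  if (is.null(durations)) durations <- stimulus_durations(spec, seed = seed)
  run_seed <- (seed + 104729 * (run_index - 1)) %% 2147483647
  with_seed(run_seed, {
    if (is.null(targets)) targets <- draw_run_targets(spec)
    build_run(spec, run_index, targets, durations, seed)
  })
}

# -- internals ---------------------------------------------------------------

build_run <- function(spec, run_index, targets, durations, seed) {
  n <- spec$n_total
  for (attempt in seq_len(spec$max_attempts)) {
    null_pos <- place_nulls(spec)
    if (is.null(null_pos)) next
    starts <- place_target_pairs(spec, null_pos)
    if (is.null(starts)) next
    occupied <- c(null_pos, starts, starts + 1L)
    stim_slots <- setdiff(0:(n - 1L), occupied)
    stopifnot(length(stim_slots) == spec$n_stimulus)
    stream <- draw_stimulus_stream(spec)
    if (is.null(stream)) next
    run <- assemble_run(spec, run_index, null_pos, starts, stim_slots,
                        stream, targets, durations, seed)
    if (!is.null(run)) return(run)
  }
  abort(paste0("could not satisfy run constraints after ", spec$max_attempts,
               " attempts (null/target spacing or word-adjacency infeasible)"))
}

place_nulls <- function(spec) {
  g <- spec$null_gap
  for (i in 1:50) {
    gaps <- sample_gaps(spec$n_null - 1L, g$mean, g$sd, g$min, g$max)
    pos <- c(0L, cumsum(gaps))
    if (max(pos) <= spec$n_total - 1L) return(pos)
  }
  NULL
}

place_target_pairs <- function(spec, null_pos) {
  g <- spec$target_gap
  n <- spec$n_total
  occupied <- null_pos
  starts <- integer(spec$n_target)
  cand <- sample(2:6, 1L)
  for (k in seq_len(spec$n_target)) {
    if (k > 1L) cand <- starts[k - 1L] + sample_gaps(1L, g$mean, g$sd, g$min, g$max)
    while (cand %in% occupied || (cand + 1L) %in% occupied) cand <- cand + 1L
    if (cand + 1L > n - 1L) return(NULL)
    starts[k] <- cand
    occupied <- c(occupied, cand, cand + 1L)
  }
  starts
}

# Two blocks of 64, each containing every unique stimulus exactly once, with
# no lexical word repeated on consecutive stream positions (a conservative
# version of the final-sequence adjacency constraint).
draw_stimulus_stream <- function(spec) {
  stim <- enumerate_stimuli(spec)
  b1 <- permute_block(stim$word, prev_word = NA_character_)
  if (is.null(b1)) return(NULL)
  b2 <- permute_block(stim$word, prev_word = stim$word[b1[64L]])
  if (is.null(b2)) return(NULL)
  stim[c(b1, b2), ]
}

permute_block <- function(words, prev_word, restarts = 200L) {
  n <- length(words)
  for (r in seq_len(restarts)) {
    remaining <- rep(TRUE, n)
    out <- integer(n)
    prev <- prev_word
    ok <- TRUE
    for (pos in seq_len(n)) {
      allowed <- which(remaining & (is.na(prev) | words != prev))
      if (length(allowed) == 0L) { ok <- FALSE; break }
      pick <- allowed[sample.int(length(allowed), 1L)]
      out[pos] <- pick
      remaining[pick] <- FALSE
      prev <- words[pick]
    }
    if (ok) return(out)
  }
  NULL
}

# Balanced targets for a single run: in each stimulus type all 8 words, with
# the four form x exemplar combinations each used twice.
draw_run_targets <- function(spec) {
  stim <- enumerate_stimuli(spec)
  out <- lapply(spec$stimulus_types, function(tt) {
    combos <- sample(rep(1:4, 2L))
    words <- sample(word_set()$word)
    form <- c("A", "A", "B", "B")[combos]
    exemplar <- c(1L, 2L, 1L, 2L)[combos]
    key <- paste(words, tt, form, exemplar, sep = ".")
    stim[match(key, stim$stimulus), ]
  })
  dplyr::bind_rows(out)
}

assemble_run <- function(spec, run_index, null_pos, starts, stim_slots,
                         stream, targets, durations, seed) {
  n <- spec$n_total
  kind <- rep("stimulus", n)
  kind[null_pos + 1L] <- "null"
  kind[starts + 1L] <- "target"
  kind[starts + 2L] <- "decision"

  word <- rep(NA_character_, n)
  stimulus <- rep(NA_character_, n)
  word[stim_slots + 1L] <- stream$word
  stimulus[stim_slots + 1L] <- stream$stimulus

  # assign target stimuli to target slots; reshuffle if a lexical word ends
  # up adjacent to the same word on a neighbouring stimulus trial
  for (try in 1:50) {
    ord <- sample.int(nrow(targets))
    w <- word
    w[starts + 1L] <- targets$word[ord]
    adjacent_same <- !is.na(w[-n]) & !is.na(w[-1L]) & w[-n] == w[-1L]
    if (!any(adjacent_same)) {
      word <- w
      stimulus[starts + 1L] <- targets$stimulus[ord]
      tbl <- tibble::tibble(
        index = 0:(n - 1L),
        onset = (0:(n - 1L)) * spec$trial_duration,
        kind = kind,
        stimulus = stimulus
      )
      tbl <- dplyr::left_join(
        tbl,
        durations[, c("stimulus", "condition", "word", "stimulus_type",
                      "form", "exemplar", "duration")],
        by = "stimulus"
      )
      tbl$duration[tbl$kind == "decision"] <- 1.5
      attr(tbl, "spec") <- spec
      attr(tbl, "run_index") <- as.integer(run_index)
      attr(tbl, "seed") <- as.integer(seed)
      class(tbl) <- c("run_sequence", class(tbl))
      return(tbl)
    }
  }
  NULL
}

# -- session -----------------------------------------------------------------

#' Generate a full four-run session
#'
#' Generates the runs of one session under a session-wide target allocation:
#' across the four runs, the 64 unique stimuli each serve as a target exactly
#' once, and every run's 16 targets cover all 8 words in each stimulus type
#' with forms and exemplars balanced. The allocation uses random 4 x 4 Latin
#' squares (words x runs, entries = form x exemplar combination).
#'
#' @inheritParams generate_run_sequence
#' @return A list of `run_sequence` tibbles (class `session`).
#' @export
generate_session <- function(spec = paradigm_spec(), seed = 1L,
                             durations = NULL) {
  seeds <- derive_seeds(seed, spec$n_runs + 2L)
  if (is.null(durations)) durations <- stimulus_durations(spec, seed = seeds[1L])
  alloc <- with_seed(seeds[2L], session_target_allocation(spec))
  runs <- lapply(seq_len(spec$n_runs), function(r) {
    generate_run_sequence(spec, run_index = r, seed = seeds[2L + r],
                          targets = alloc[[r]], durations = durations)
  })
  structure(runs, class = "session", spec = spec, seed = as.integer(seed))
}

random_latin_square_4 <- function() {
  base <- (outer(0:3, 0:3, `+`) %% 4L) + 1L
  base <- base[sample.int(4L), sample.int(4L)]
  matrix(sample.int(4L)[base], 4L, 4L)
}

session_target_allocation <- function(spec) {
  stim <- enumerate_stimuli(spec)
  combo_form <- c("A", "A", "B", "B")
  combo_exemplar <- c(1L, 2L, 1L, 2L)
  per_run <- vector("list", spec$n_runs)
  for (tt in spec$stimulus_types) {
    words <- sample(word_set()$word)
    groups <- list(words[1:4], words[5:8])
    for (g in groups) {
      sq <- random_latin_square_4()
      for (r in seq_len(spec$n_runs)) {
        combos <- sq[, r]
        key <- paste(g, tt, combo_form[combos], combo_exemplar[combos], sep = ".")
        per_run[[r]] <- dplyr::bind_rows(per_run[[r]],
                                         stim[match(key, stim$stimulus), ])
      }
    }
  }
  per_run
}

# -- validation --------------------------------------------------------------

#' Re-check all run/session invariants independently of the generator
#'
#' `check_run_sequence()` returns a character vector of violated invariants
#' (empty when the run is valid); `validate_run_sequence()` and
#' `validate_session()` abort on the first problem. The checks are written
#' against the trial table alone and share no code with the generator.
#'
#' @param run A `run_sequence` tibble.
#' @param spec The paradigm the run claims to instantiate.
#' @return `check_run_sequence()`: character vector of issues;
#'   the validators return the input invisibly.
#' @export
check_run_sequence <- function(run, spec = attr(run, "spec")) {
  issues <- character()
  note <- function(msg) issues <<- c(issues, msg)

  counts <- table(factor(run$kind,
                         levels = c("stimulus", "null", "target", "decision")))
  want <- c(spec$n_stimulus, spec$n_null, spec$n_target, spec$n_decision)
  if (!all(counts == want)) note("trial-kind composition mismatch")
  if (nrow(run) != spec$n_total) note("total trial count mismatch")
  if (!isTRUE(all.equal(run$onset, run$index * spec$trial_duration))) {
    note("onsets are not index * trial_duration")
  }
  prev <- which(run$kind == "decision") - 1L
  if (any(prev < 1L) || !all(run$kind[prev] == "target")) {
    note("a decision trial does not immediately follow a target trial")
  }
  has_stim <- !is.na(run$stimulus)
  if (!identical(has_stim, run$kind %in% c("stimulus", "target"))) {
    note("stimulus present iff kind is stimulus/target violated")
  }
  w <- run$word
  same <- !is.na(w[-length(w)]) & !is.na(w[-1L]) & w[-length(w)] == w[-1L]
  if (any(same)) note("same lexical word on consecutive trials")
  stim_rows <- run[run$kind == "stimulus", ]
  if (nrow(stim_rows) == 2L * 64L) {
    b1 <- stim_rows$stimulus[1:64]
    b2 <- stim_rows$stimulus[65:128]
    if (dplyr::n_distinct(b1) != 64L || dplyr::n_distinct(b2) != 64L) {
      note("a 64-trial block does not contain each unique stimulus once")
    }
  }
  issues
}

#' @rdname check_run_sequence
#' @export
validate_run_sequence <- function(run, spec = attr(run, "spec")) {
  issues <- check_run_sequence(run, spec)
  if (length(issues)) abort(paste("invalid run sequence:", issues[1L]))
  invisible(run)
}

#' @rdname check_run_sequence
#' @param session A list of runs from [generate_session()].
#' @export
validate_session <- function(session, spec = attr(session, "spec")) {
  lapply(session, validate_run_sequence, spec = spec)
  tgt <- dplyr::bind_rows(lapply(session, function(r) r[r$kind == "target", ]))
  if (dplyr::n_distinct(tgt$stimulus) != 2L * spec$n_target * 2L) {
    abort("session targets do not cover all 64 unique stimuli exactly once")
  }
  for (r in session) {
    t_r <- r[r$kind == "target", ]
    per_type <- table(t_r$stimulus_type)
    if (!all(per_type == spec$n_target / 2L)) {
      abort("a run's targets are not balanced over stimulus types")
    }
    for (tt in spec$stimulus_types) {
      sub <- t_r[t_r$stimulus_type == tt, ]
      if (dplyr::n_distinct(sub$word) != 8L ||
          !all(table(sub$form) == 4L) || !all(table(sub$exemplar) == 4L)) {
        abort("a run's targets are not balanced over words/forms/exemplars")
      }
    }
  }
  invisible(session)
}

# -- summaries and export ----------------------------------------------------

#' Summarise a run's composition and spacing
#'
#' Computes per-kind trial counts and the spacing statistics (in trial
#' indices) between successive null trials and between successive
#' target-decision pairs.
#'
#' @param run A `run_sequence` tibble.
#' @return A one-row tibble of counts, the decision/stimulus ratio, and gap
#'   summaries (`null_gap_*`, `target_gap_*`).
#' @export
design_summary <- function(run) {
  ng <- gap_stats(run$index[run$kind == "null"])
  tg <- gap_stats(run$index[run$kind == "target"])
  kc <- function(k) sum(run$kind == k)
  tibble::tibble(
    n_total = nrow(run),
    n_stimulus = kc("stimulus"), n_null = kc("null"),
    n_target = kc("target"), n_decision = kc("decision"),
    decision_stimulus_ratio = kc("decision") / kc("stimulus"),
    null_gap_min = ng$min, null_gap_max = ng$max,
    null_gap_mean = ng$mean, null_gap_sd = ng$sd,
    target_gap_min = tg$min, target_gap_max = tg$max,
    target_gap_mean = tg$mean, target_gap_sd = tg$sd
  )
}

#' Event table for a run (BIDS-events dialect)
#'
#' Converts a run sequence to an event table with stimulus-locked onsets:
#' `onset = trial onset + stimulus_delay`, i.e. the moment the stimulus plays
#' inside the silent gap. `trial_type` is the condition label for stimulus and
#' target trials, and the kind otherwise.
#'
#' @param run A `run_sequence` tibble.
#' @param spec The paradigm spec (defaults to the run's own).
#' @return A tibble with columns `onset`, `duration`, `trial_type`, `word`,
#'   `stimulus_type`, `form`, `exemplar`, `kind`.
#' @export
events_table <- function(run, spec = attr(run, "spec")) {
  tibble::tibble(
    onset = run$onset + spec$stimulus_delay,
    duration = ifelse(is.na(run$duration), 0, run$duration),
    trial_type = ifelse(is.na(run$condition), run$kind, run$condition),
    word = run$word,
    stimulus_type = run$stimulus_type,
    form = run$form,
    exemplar = run$exemplar,
    kind = run$kind
  )
}

#' @rdname events_table
#' @param path File to write (tab-separated text).
#' @export
write_events <- function(run, path, spec = attr(run, "spec")) {
  readr::write_tsv(events_table(run, spec), path)
  invisible(path)
}
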