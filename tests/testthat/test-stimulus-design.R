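test_that("the word set is the factorial CVC grid", {
  ws <- word_set()
  expect_equal(ws$word,
               c("beam", "beat", "boom", "boot", "real", "reef", "rule", "roof"))
  expect_false(anyDuplicated(ws$word) > 0)
  # every word has exactly the three positional slots
  expect_true(all(nchar(ws$initial) > 0 & nchar(ws$vowel) > 0 &
                    nchar(ws$final) > 0))
  # initial x vowel fully crossed, final nested within initial
  expect_equal(sort(ws$word[ws$initial == "b"]),
               c("beam", "beat", "boom", "boot"))
  expect_setequal(ws$final[ws$initial == "b"], c("m", "t"))
  expect_setequal(ws$final[ws$initial == "r"], c("l", "f"))
})

test_that("shared_phoneme_count matches the positional oracle and its laws", {
  ws <- word_set()$word
  expect_equal(shared_phoneme_count("beam", "beam"), 3L)
  expect_equal(shared_phoneme_count("beam", "beat"), 2L)
  expect_equal(shared_phoneme_count("beam", "rule"), 0L)
  for (a in ws) {
    for (b in ws) {
      expect_equal(shared_phoneme_count(a, b), oracle_shared_count(a, b))
      expect_equal(shared_phoneme_count(a, b), shared_phoneme_count(b, a))
    }
  }
  # b-initial vs r-initial words share at most the vowel
  cross <- expand.grid(a = ws[1:4], b = ws[5:8], stringsAsFactors = FALSE)
  expect_true(all(shared_phoneme_count(cross$a, cross$b) <= 1L))
  expect_error(shared_phoneme_count("beam", "dog"), "unknown word")
})

test_that("condition enumeration has the documented size and order", {
  hearing <- enumerate_conditions(paradigm_spec("hearing"))
  expect_equal(nrow(hearing), 32L)
  expect_equal(sum(hearing$stimulus_type == "visual_speech"), 16L)
  expect_equal(sum(hearing$stimulus_type == "auditory_speech"), 16L)
  # word-major canonical order, stable across calls
  expect_equal(hearing$word[1:4], rep("beam", 4L))
  expect_identical(hearing, enumerate_conditions(paradigm_spec("hearing")))
  deaf <- enumerate_conditions(paradigm_spec("deaf"))
  expect_setequal(unique(deaf$stimulus_type),
                  c("visual_speech", "dynamic_text"))
  expect_equal(nrow(enumerate_stimuli(paradigm_spec())), 64L)
})

test_that("generated runs satisfy every composition and ordering invariant", {
  spec <- paradigm_spec()
  for (seed in c(7L, 101L, 5005L)) {
    run <- generate_run_sequence(spec, run_index = 1L, seed = seed)
    expect_length(check_run_sequence(run, spec), 0L)
    cnt <- table(run$kind)
    expect_equal(unname(cnt[c("stimulus", "null", "target", "decision")]),
                 c(128L, 10L, 16L, 16L), ignore_attr = TRUE)
  }
})

test_that("run generation is deterministic in the seed", {
  spec <- paradigm_spec()
  a <- generate_run_sequence(spec, 1L, seed = 11L)
  b <- generate_run_sequence(spec, 1L, seed = 11L)
  c <- generate_run_sequence(spec, 1L, seed = 12L)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("sessions cover all 64 stimuli as targets with balanced runs", {
  for (grp in c("hearing", "deaf")) {
    spec <- paradigm_spec(grp)
    sess <- generate_session(spec, seed = if (grp == "hearing") 1L else 2L)
    expect_silent(validate_session(sess, spec))
    tgt <- do.call(rbind, lapply(sess, function(r) r[r$kind == "target", ]))
    expect_equal(dplyr::n_distinct(tgt$stimulus), 64L)
    for (r in sess) {
      per_type <- table(r$stimulus_type[r$kind == "target"])
      expect_equal(unname(per_type), c(8L, 8L), ignore_attr = TRUE)
    }
  }
})

test_that("design_summary reports counts, ratio and spacing", {
  run <- generate_run_sequence(paradigm_spec(), 1L, seed = 33L)
  ds <- design_summary(run)
  expect_equal(ds$n_total, 170L)
  expect_equal(ds$decision_stimulus_ratio, 0.125)
  expect_gte(ds$null_gap_min, 8)
  expect_lte(ds$null_gap_max, 26)
  expect_gte(ds$target_gap_min, 7)
})

test_that("event tables export in the tab-separated events dialect", {
  spec <- paradigm_spec()
  run <- generate_run_sequence(spec, 1L, seed = 3L)
  ev <- events_table(run, spec)
  expect_named(ev, c("onset", "duration", "trial_type", "word",
                     "stimulus_type", "form", "exemplar", "kind"))
  expect_equal(ev$onset, run$onset + spec$stimulus_delay)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events(run, path, spec)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 170L)
  expect_equal(back$trial_type[run$kind == "null"],
               rep("null", 10L))
})

test_that("stimulus durations are fixed per stimulus and within range", {
  spec <- paradigm_spec()
  dur <- stimulus_durations(spec, seed = 4L)
  expect_equal(nrow(dur), 64L)
  aud <- dur$duration[dur$stimulus_type == "auditory_speech"]
  expect_true(all(aud >= 0.558 & aud <= 0.972))
  run <- generate_run_sequence(spec, 1L, seed = 4L, durations = dur)
  # the same stimulus keeps one duration across its repetitions
  reps <- run[run$kind == "stimulus", c("stimulus", "duration")]
  expect_true(all(tapply(reps$duration, reps$stimulus,
                         function(x) length(unique(x))) == 1L))
})
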