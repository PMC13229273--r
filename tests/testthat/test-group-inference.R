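test_that("kendall tau-a matches its definition and the brute-force oracle", {
  expect_equal(kendall_tau_a(1:4, 1:4), 1)
  expect_equal(kendall_tau_a(1:4, 4:1), -1)
  expect_equal(kendall_tau_a(c(1, 1, 2), c(1, 2, 3)), 2 / 3)
  expect_error(kendall_tau_a(1:3, 1:4), "equal length")
  withr::with_seed(1L, {
    for (k in 1:300) {
      n <- sample(4:9, 1L)
      x <- sample(1:4, n, replace = TRUE)   # heavy ties
      y <- sample(1:4, n, replace = TRUE)
      expect_identical(kendall_tau_a(x, y), oracle_tau_a(x, y))
    }
  })
})

test_that("fisher z is atanh with clamping at the boundary", {
  expect_equal(fisher_z(0), 0)
  expect_equal(round(fisher_z(0.5), 4L), 0.5493)
  expect_equal(fisher_z(0.5), 0.5 * log(3))
  expect_equal(fisher_z(-0.3), -fisher_z(0.3))
  expect_warning(z1 <- fisher_z(1), "clamped")
  expect_true(is.finite(z1))
})

test_that("one-sample t reports d_z = t / sqrt(n) and handles edge cases", {
  x <- withr::with_seed(2L, rnorm(25L, 0.3))
  res <- one_sample_t(x)
  expect_equal(res$d_z, res$t / sqrt(25L))
  expect_equal(res$df, 24L)
  ref <- t.test(x, alternative = "greater")
  expect_equal(res$p, ref$p.value)
  expect_error(one_sample_t(rep(2, 10L)), "zero variance")
  sym <- c(-2, -1, 1, 2)
  res0 <- one_sample_t(sym, tail = "one")
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 0.5)
})

test_that("paired t is antisymmetric and null-calibrated", {
  a <- withr::with_seed(3L, rnorm(12L))
  b <- withr::with_seed(4L, rnorm(12L))
  r1 <- paired_t(a, b)
  r2 <- paired_t(b, a)
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$p, r2$p)
  same <- paired_t(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  rej <- withr::with_seed(5L, {
    mean(replicate(4000L, paired_t(rnorm(10L), rnorm(10L))$p < 0.05))
  })
  expect_lt(abs(rej - 0.05), 0.01)
})

test_that("the two-step procedure gates and corrects as specified", {
  conds <- enumerate_conditions(paradigm_spec())
  sp <- shared_phonemes_model(conds)
  lex <- lexical_model(conds)
  n_sub <- 10L
  mk_cluster <- function(signal, noise_sd, seed) {
    withr::with_seed(seed, {
      t(replicate(n_sub, signal + rnorm(length(signal), 0, noise_sd)))
    })
  }
  cluster_rdms <- list(
    phon   = mk_cluster(sp$value, 0.8, 6L),     # full phonological structure
    silent = mk_cluster(rep(0, nrow(sp)), 1, 7L),  # no structure: gate fails
    lexical = mk_cluster(lex$value, 0.3, 8L)    # identity-only structure
  )
  fit <- run_two_step(cluster_rdms, conds)
  tbl <- tidy(fit)
  s1 <- tbl[tbl$step == 1L, ]
  expect_setequal(s1$cluster, names(cluster_rdms))
  expect_true(all(s1$n_family == 3L))
  expect_true(s1$significant[s1$cluster == "phon"])
  expect_false(s1$significant[s1$cluster == "silent"])
  # the silent cluster is never tested downstream
  expect_false("silent" %in% tbl$cluster[tbl$step > 1L])
  # phonological cluster: sublexical and lexical both significant across
  s3p <- tbl[tbl$step == 3L & tbl$cluster == "phon", ]
  expect_true(all(s3p$significant))
  # lexical-only cluster: lexical fits, sublexical does not
  s3l <- tbl[tbl$step == 3L & tbl$cluster == "lexical", ]
  if (nrow(s3l)) {
    expect_true(s3l$significant[s3l$model == "lexical"])
    expect_false(s3l$significant[s3l$model == "sublexical"])
  }
  # per-type follow-ups exist only for sublexical-significant clusters
  s4 <- tbl[tbl$step == 4L, ]
  expect_true(all(s4$cluster == "phon"))
  expect_equal(glance(fit)$n_clusters, 3L)
})

test_that("segment-position contrast is a repeated-measures ANOVA", {
  flat <- matrix(rep(c(1, 2, 1.5), each = 25L), 25L, 3L,
                 dimnames = list(NULL, c("initial", "vowel", "final")))
  flat_same <- matrix(rep(rnorm(25L), 3L), 25L, 3L,
                      dimnames = dimnames(flat))
  res0 <- segment_position_contrast(flat_same)
  expect_equal(res0$F, 0, tolerance = 1e-10)
  res <- segment_position_contrast(flat + withr::with_seed(9L,
                                                           matrix(rnorm(75L), 25L)))
  expect_equal(c(res$df1, res$df2), c(2L, 48L))
  # null calibration against the F(2, 2(n-1)) reference distribution
  fs <- withr::with_seed(10L, {
    replicate(800L, segment_position_contrast(
      matrix(rnorm(8L * 3L), 8L, 3L,
             dimnames = list(NULL, c("initial", "vowel", "final"))))$F)
  })
  ks <- suppressWarnings(stats::ks.test(fs, function(q) stats::pf(q, 2, 14)))
  expect_gt(ks$p.value, 0.01)
})

test_that("brain-behaviour correlation uses the one-tailed t transform", {
  fits <- withr::with_seed(11L, rnorm(25L))
  scores <- 3 + 2 * fits + withr::with_seed(12L, rnorm(25L, 0, 2))
  res <- brain_behavior_corr(fits, scores)
  expect_equal(res$df, 23L)
  tt <- res$r * sqrt(23L) / sqrt(1 - res$r^2)
  expect_equal(res$t, tt)
  expect_equal(res$p, stats::pt(tt, 23L, lower.tail = FALSE))
  perfect <- brain_behavior_corr(fits, 2 * fits + 1)
  expect_equal(perfect$r, 1)
  expect_lt(perfect$p, 1e-10)
  expect_error(brain_behavior_corr(fits, rep(1, 25L)), "zero variance")
  # permutation null: one-tailed p is uniform
  ps <- withr::with_seed(13L, {
    replicate(600L, brain_behavior_corr(rnorm(15L), rnorm(15L))$p)
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("classical MDS recovers planar configurations", {
  pts <- withr::with_seed(14L, matrix(rnorm(12L), 6L, 2L))
  D <- as.matrix(dist(pts))
  rownames(D) <- colnames(D) <- paste0("c", 1:6)
  emb <- classical_mds(D, dims = 2L)
  D2 <- as.matrix(dist(as.matrix(emb[, c("dim1", "dim2")])))
  expect_equal(unname(D2), unname(D), tolerance = 1e-8)
  # all-equal distances: equilateral triangle
  tri <- matrix(1, 3L, 3L); diag(tri) <- 0
  emb3 <- classical_mds(tri)
  d3 <- dist(as.matrix(emb3[, -1L]))
  expect_equal(as.numeric(d3), rep(1, 3L), tolerance = 1e-8)
  # single item sits at the origin
  one <- classical_mds(matrix(0, 1L, 1L))
  expect_equal(one$dim1, 0)
  # negative crossnobis estimates are clamped with a warning
  neg <- tri; neg[1L, 2L] <- neg[2L, 1L] <- -0.05
  expect_warning(classical_mds(neg), "clamped")
})
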