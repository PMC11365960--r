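test_that("similarity is 100 on identical tracks and bounded in [0, 100]", {
  fx <- fx_rendition_tracks()
  for (lab in c("A", "B", "X")) {
    x <- fx$tracks[[lab]][[1]]
    expect_equal(syllable_similarity(x, x, fx$scaling)$value, 100)
  }
  all_tracks <- unlist(fx$tracks, recursive = FALSE)
  with_seed(10L, {
    for (k in 1:25) {
      ij <- sample(length(all_tracks), 2)
      s <- syllable_similarity(all_tracks[[ij[1]]], all_tracks[[ij[2]]], fx$scaling)
      expect_gte(s$value, 0); expect_lte(s$value, 100)
    }
  })
})

test_that("similarity is exactly symmetric in its arguments", {
  fx <- fx_rendition_tracks()
  all_tracks <- unlist(fx$tracks, recursive = FALSE)
  with_seed(11L, {
    for (k in 1:50) {
      ij <- sample(length(all_tracks), 2)
      ab <- syllable_similarity(all_tracks[[ij[1]]], all_tracks[[ij[2]]], fx$scaling)$value
      ba <- syllable_similarity(all_tracks[[ij[2]]], all_tracks[[ij[1]]], fx$scaling)$value
      expect_identical(ab, ba)
    }
  })
})

test_that("tracks shorter than two frames are rejected", {
  fx <- fx_rendition_tracks()
  x <- fx$tracks$A[[1]]
  stub <- x
  stub$frames <- stub$frames[1, , drop = FALSE]
  stub$times <- stub$times[1]
  expect_error(syllable_similarity(stub, x, fx$scaling), ">= 2 frames")
})

test_that("zero-jitter renditions give self-similarity mean 100, std 0, 45 pairs", {
  tracks <- fx_zero_jitter_tracks(10L)
  fx <- fx_rendition_tracks()
  ss <- self_similarity(tracks, fx$scaling, label = "Z")
  expect_equal(ss$mean, 100)
  expect_equal(ss$std, 0)
  expect_identical(ss$n_pairs, 45L)
  expect_error(self_similarity(tracks[1], fx$scaling), ">= 2")
})

test_that("self-similarity decreases with rendition jitter", {
  a <- syllable_archetype("J", "harmonic_stack", 650, 650, n_harmonics = 5,
                          duration_ms = 90)
  fx <- fx_rendition_tracks()
  mk <- function(jit, seed0) {
    lapply(1:8, function(i) {
      extract_features(synth_syllable(a, jit, seed = seed0 + i), id = "J")
    })
  }
  lo <- self_similarity(mk(rendition_jitter(0.01, 0.02, 0.05), 100L), fx$scaling)
  hi <- self_similarity(mk(rendition_jitter(0.08, 0.20, 0.30), 200L), fx$scaling)
  expect_gt(lo$mean, hi$mean)
})

test_that("disjoint archetypes score far below within-type similarity", {
  fx <- fx_rendition_tracks()
  self_A <- self_similarity(fx$tracks$A, fx$scaling, label = "A")
  cross <- cross_similarity(fx$tracks["A"], fx$tracks["X"], fx$scaling)
  expect_lt(max(cross$score), stats::quantile(self_A$scores, 0.05))
})

test_that("cross-similarity of a type with itself reproduces the self pair set", {
  fx <- fx_rendition_tracks()
  self_B <- self_similarity(fx$tracks$B, fx$scaling, label = "B")
  cross <- cross_similarity(fx$tracks["B"], fx$tracks["B"], fx$scaling)
  off_diag <- cross$score[cross$rendition_a != cross$rendition_b]
  expect_equal(sort(unique(round(off_diag, 9))),
               sort(unique(round(self_B$scores, 9))))
  expect_true(all(cross$score[cross$rendition_a == cross$rendition_b] == 100))
})

test_that("relabelling identical renditions leaves the score distribution unchanged", {
  fx <- fx_rendition_tracks()
  # same archetype synthesised under two labels; distributions should agree
  a <- syllable_archetype("P", "chirp", 2500, 3500, duration_ms = 70)
  setup <- finch_study_setup()
  g1 <- lapply(1:8, function(i) extract_features(
    synth_syllable(a, setup$jitter, seed = 300L + i), id = "P"))
  g2 <- lapply(1:8, function(i) extract_features(
    synth_syllable(a, setup$jitter, seed = 400L + i), id = "Q"))
  self_p <- self_similarity(g1, fx$scaling)$scores
  cross_pq <- cross_similarity(list(P = g1), list(Q = g2), fx$scaling)$score
  ks <- suppressWarnings(stats::ks.test(self_p, cross_pq))
  expect_gt(ks$p.value, 0.01)
})

test_that("ECD curves are monotone with bands bracketing the point curve", {
  scores <- rep(80, 5)
  e <- ecd_with_ci(scores, n_bootstrap = 200, seed = 1L)
  expect_true(all(e$score == 80))
  expect_true(all(e$ci_lo == e$ecdf & e$ci_hi == e$ecdf))  # zero-width bands

  x <- with_seed(3L, stats::runif(200, 0, 100))
  e2 <- ecd_with_ci(x, n_bootstrap = 300, seed = 2L)
  expect_true(all(diff(e2$ecdf) >= 0))
  expect_true(all(e2$ci_lo <= e2$ecdf & e2$ecdf <= e2$ci_hi))
  expect_error(ecd_with_ci(c(1, 2, 3)), ">= 5")
})

test_that("the empirical CDF of uniform scores tracks the true CDF", {
  x <- with_seed(5L, stats::runif(1000, 0, 100))
  e <- ecd_with_ci(x, n_bootstrap = 100, seed = 5L)
  expect_lt(max(abs(e$ecdf - e$score / 100)), 0.05)
})

test_that("bootstrap bands are deterministic given the seed", {
  x <- with_seed(6L, stats::runif(100, 0, 100))
  e1 <- ecd_with_ci(x, n_bootstrap = 200, seed = 9L)
  e2 <- ecd_with_ci(x, n_bootstrap = 200, seed = 9L)
  expect_identical(e1, e2)
  e3 <- ecd_with_ci(x, n_bootstrap = 200, seed = 10L)
  expect_false(identical(e1$ci_lo, e3$ci_lo))
})
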