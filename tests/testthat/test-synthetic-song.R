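test_that("zero-jitter harmonic stack has exact duration and harmonic peaks", {
  a <- syllable_archetype("h", "harmonic_stack", 600, 600, n_harmonics = 3,
                          duration_ms = 120)
  w <- synth_syllable(a, rendition_jitter(0, 0, 0), seed = 1L)
  expect_equal(wave_duration(w), 0.120, tolerance = 1e-6)
  # spectrum peaks at 600/1200/1800 Hz
  n <- length(w$samples)
  pw <- (Mod(stats::fft(w$samples))^2)[seq_len(n %/% 2)]
  freqs <- (seq_len(n %/% 2) - 1) / n * w$sr
  # collapse adjacent-bin leakage: keep only local maxima
  lmax <- c(FALSE, pw[2:(length(pw) - 1)] > pw[1:(length(pw) - 2)] &
              pw[2:(length(pw) - 1)] >= pw[3:length(pw)], FALSE)
  pw[!lmax] <- 0
  top3 <- sort(freqs[order(pw, decreasing = TRUE)[1:3]])
  expect_equal(top3, c(600, 1200, 1800), tolerance = 0.02)
})

test_that("syllable synthesis is bit-identical under the same seed", {
  a <- syllable_archetype("n", "noise_burst", noise_band = c(1000, 3000),
                          duration_ms = 80)
  j <- rendition_jitter(0.05, 0.1, 0.1)
  w1 <- synth_syllable(a, j, noise_floor_db = -40, seed = 1L)
  w2 <- synth_syllable(a, j, noise_floor_db = -40, seed = 1L)
  expect_identical(w1$samples, w2$samples)
})

test_that("duration jitter reproduces the nominal coefficient of variation", {
  a <- syllable_archetype("c", "chirp", 2000, 4000, duration_ms = 100)
  durs <- vapply(1:200, function(s) {
    wave_duration(synth_syllable(a, rendition_jitter(0, 0.1, 0), seed = s))
  }, numeric(1))
  cv <- stats::sd(durs) / mean(durs)
  expect_gt(cv, 0.07)
  expect_lt(cv, 0.13)
})

test_that("fundamental above Nyquist is rejected", {
  a <- syllable_archetype("bad", "chirp", 3000, 25000, duration_ms = 50)
  expect_error(synth_syllable(a, sr = 40000), "Nyquist")
})

test_that("zero-branching corpus follows the grammar exactly", {
  setup <- finch_study_setup(n_novel = 0)
  g <- song_grammar(core_motif = c("A", "B", "C", "D"),
                    branch_prob = 0, motifs_per_bout_range = c(1L, 3L))
  arche <- setup$archetypes[c("i", "A", "B", "C", "D")]
  co <- synth_corpus(arche, g, rendition_jitter(0, 0, 0), novelty = NULL,
                     n_bouts = 10, noise_floor_db = -Inf, seed = 3L)
  for (b in 1:10) {
    labs <- co$truth$label[co$truth$bout == b]
    labs <- labs[labs != "i"]
    expect_identical(labs, rep(c("A", "B", "C", "D"),
                               times = length(labs) / 4))
  }
})

test_that("zero-jitter renditions of a label are bit-identical within a corpus", {
  setup <- finch_study_setup(n_novel = 0)
  co <- synth_corpus(setup$archetypes, setup$grammar, rendition_jitter(0, 0, 0),
                     novelty = NULL, n_bouts = 3, noise_floor_db = -Inf,
                     seed = 5L)
  tr <- co$truth[co$truth$bout == 1L, ]
  a_rows <- tr[tr$label == "A", ]
  w <- co$waves[[1]]$samples
  cuts <- lapply(seq_len(nrow(a_rows)), function(i) {
    i0 <- round(a_rows$onset_s[i] * co$sr)
    w[(i0 + 1):(i0 + round(0.110 * co$sr))]
  })
  for (i in seq_along(cuts)[-1]) expect_identical(cuts[[i]], cuts[[1]])
})

test_that("ground-truth segments are ordered, disjoint, gap-separated", {
  setup <- finch_study_setup()
  co <- synth_corpus(setup$archetypes, setup$grammar, setup$jitter,
                     novelty = setup$novelty, n_bouts = 5, seed = 11L)
  for (b in 1:5) {
    tr <- co$truth[co$truth$bout == b, ]
    expect_true(all(diff(tr$onset_s) > 0))
    expect_true(all(tr$offset_s > tr$onset_s))
    gaps <- tr$onset_s[-1] - tr$offset_s[-nrow(tr)]
    expect_equal(gaps, rep(0.050, length(gaps)), tolerance = 1e-3)
  }
})

test_that("corpus regeneration with the same seed is bit-identical", {
  setup <- finch_study_setup()
  co1 <- synth_corpus(setup$archetypes, setup$grammar, setup$jitter,
                      novelty = setup$novelty, n_bouts = 3, seed = 17L)
  co2 <- synth_corpus(setup$archetypes, setup$grammar, setup$jitter,
                      novelty = setup$novelty, n_bouts = 3, seed = 17L)
  expect_identical(lapply(co1$waves, `[[`, "samples"),
                   lapply(co2$waves, `[[`, "samples"))
  expect_identical(co1$truth, co2$truth)
})

test_that("novelty occurrence follows its probability and position policy", {
  setup <- finch_study_setup()
  nov1 <- novelty_spec(setup$novelty$novel_archetypes, occurrence_prob = 1)
  bouts <- simulate_bout_labels(setup$grammar, nov1, n_bouts = 20, seed = 2L)
  novel_flags <- attr(bouts, "novel")
  for (k in seq_along(bouts)) {
    b <- bouts[[k]]
    is_nov <- novel_flags[[k]]
    # one novel occurrence per motif rendition, each directly after the
    # motif-final label E
    ends <- which(b == "E")
    n_motifs <- length(ends[c(diff(ends) != 1, TRUE)])   # stutters collapse
    expect_identical(sum(is_nov), n_motifs)
    expect_true(all(b[which(is_nov) - 1L] == "E"))
  }
  # occurrence_prob 0.3 over many motifs: observed fraction within 0.05
  nov03 <- novelty_spec(setup$novelty$novel_archetypes, occurrence_prob = 0.3)
  bouts <- simulate_bout_labels(setup$grammar, nov03, n_bouts = 200, seed = 4L)
  n_motifs <- sum(vapply(bouts, function(b) {
    ends <- which(b == "E"); length(ends[c(diff(ends) != 1, TRUE)])
  }, integer(1)))
  n_novel <- sum(unlist(attr(bouts, "novel")))
  expect_gt(n_motifs, 400)
  expect_lt(abs(n_novel / n_motifs - 0.3), 0.05)
})

test_that("novel labels overlapping the grammar are rejected", {
  setup <- finch_study_setup()
  bad <- novelty_spec(list(syllable_archetype("A", "noise_burst",
                                              noise_band = c(1000, 2000),
                                              duration_ms = 50)))
  expect_error(
    synth_corpus(setup$archetypes, setup$grammar, setup$jitter,
                 novelty = bad, n_bouts = 1, seed = 1L),
    "overlap")
})

test_that("WAV round-trip preserves samples at both bit depths", {
  w <- synth_syllable(syllable_archetype("h", "harmonic_stack", 500, 500,
                                         n_harmonics = 4, duration_ms = 50),
                      seed = 8L)
  p16 <- tempfile(fileext = ".wav"); p32 <- tempfile(fileext = ".wav")
  wav_write(w, p16, "pcm16")
  wav_write(w, p32, "float32")
  r16 <- wav_read(p16); r32 <- wav_read(p32)
  expect_equal(r16$sr, w$sr)
  expect_equal(r16$samples, w$samples, tolerance = 1e-4)   # 16-bit quantisation
  expect_equal(r32$samples, w$samples, tolerance = 1e-7)   # float32 rounding
  unlink(c(p16, p32))
})
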