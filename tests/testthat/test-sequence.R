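test_that("transition matrix counts ordered pairs within bouts", {
  tm <- transition_matrix(list(strsplit("ABCDABCD", "")[[1]]))
  expect_identical(unname(tm$counts["A", "B"]), 2L)
  expect_identical(unname(tm$counts["D", "A"]), 1L)
  expect_equal(unname(tm$proportions["A", "B"]), 1)

  tm2 <- transition_matrix(list(c("A", "A", "A", "A")))
  expect_equal(unname(tm2$proportions["A", "A"]), 1)

  # no transitions across bout boundaries
  tm3 <- transition_matrix(list(c("A", "B"), c("C", "D")))
  expect_identical(unname(tm3$counts["B", "C"]), 0L)
})

test_that("every nonzero row of transition proportions sums to one", {
  with_seed(61L, {
    for (k in 1:20) {
      tm <- transition_matrix(random_bouts(5))
      rs <- rowSums(tm$proportions)
      expect_true(all(abs(rs[rs > 0] - 1) < 1e-12))
    }
  })
})

test_that("linearity is 1 for a perfectly linear song and matches hand counts", {
  bouts <- replicate(10, strsplit("ABCDABCD", "")[[1]], simplify = FALSE)
  expect_equal(sequence_linearity(bouts), 1)

  # {ABCD, ABED, ACD}: 5 notes; transition types A->B, B->C, C->D, B->E,
  # E->D, A->C -> 5/6
  b2 <- list(c("A", "B", "C", "D"), c("A", "B", "E", "D"), c("A", "C", "D"))
  expect_equal(sequence_linearity(b2), 5 / 6)

  # a new transition type without a new note strictly lowers linearity
  b3 <- c(b2, list(c("D", "C")))
  expect_lt(sequence_linearity(b3), sequence_linearity(b2))

  expect_error(sequence_linearity(list(c("A"), c("B"))), "undefined")
})

test_that("consistency is 1 for a perfectly consistent song and matches hand counts", {
  bouts <- replicate(10, strsplit("ABCDABCD", "")[[1]], simplify = FALSE)
  expect_equal(sequence_consistency(bouts), 1)

  # A->B 9x, A->C 1x, plus 90 deterministic D->E transitions: 99/100
  b2 <- c(replicate(9, c("A", "B"), simplify = FALSE),
          list(c("A", "C")),
          replicate(90, c("D", "E"), simplify = FALSE))
  expect_equal(sequence_consistency(b2), 0.99)

  expect_error(sequence_consistency(list("A")), "undefined|consistency")
})

test_that("linearity and consistency match the brute-force oracle", {
  with_seed(71L, {
    for (k in 1:200) {
      bouts <- random_bouts(sample(1:6, 1),
                            alphabet_size = sample(2:8, 1),
                            max_len = 60L)
      expect_equal(sequence_linearity(bouts, include_intro = TRUE),
                   oracle_linearity(bouts))
      expect_equal(sequence_consistency(bouts, include_intro = TRUE),
                   oracle_consistency(bouts))
    }
  })
})

test_that("both statistics are invariant to relabelling of the alphabet", {
  with_seed(72L, {
    for (k in 1:20) {
      bouts <- random_bouts(4, alphabet_size = 6)
      perm <- sample(LETTERS[1:6])
      relab <- lapply(bouts, function(b) perm[match(b, LETTERS[1:6])])
      expect_equal(sequence_linearity(relab), sequence_linearity(bouts))
      expect_equal(sequence_consistency(relab), sequence_consistency(bouts))
    }
  })
})

test_that("transition proportions converge to a first-order Markov generator", {
  P <- matrix(c(0.7, 0.2, 0.1,
                0.1, 0.6, 0.3,
                0.3, 0.3, 0.4), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  labs <- c("A", "B", "C")
  chain <- with_seed(81L, {
    x <- character(10001)
    x[1] <- "A"
    for (i in 2:10001) x[i] <- sample(labs, 1, prob = P[x[i - 1], ])
    x
  })
  tm <- transition_matrix(list(chain))
  expect_lt(max(abs(tm$proportions - P)), 0.05)
})

test_that("consistency decreases with the grammar's branching probability", {
  setup <- finch_study_setup(n_novel = 0)
  mean_cons <- vapply(c(0, 0.2, 0.4), function(bp) {
    g <- song_grammar(core_motif = setup$grammar$core_motif, branch_prob = bp)
    mean(vapply(1:20, function(s) {
      sequence_consistency(simulate_bout_labels(g, n_bouts = 10, seed = 1000L + s))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_cons) < 0))
})

test_that("introductory notes are excluded by default and kept on request", {
  bouts <- list(c("i", "i", "A", "B", "A", "B"))
  expect_equal(sequence_linearity(bouts), 1)      # {A,B} / {A->B, B->A}
  lin_with_i <- sequence_linearity(bouts, include_intro = TRUE)
  expect_equal(lin_with_i, 3 / 4)                 # + i, i->i, i->A
})

test_that("position histogram puts end-appended novel syllables in bin 0", {
  bouts <- list(c("i", "A", "B", "C", "X", "A", "B", "C"),
                c("A", "B", "C", "A", "B", "C", "Y"))
  h <- novel_position_histogram(bouts, c("X", "Y"), c("A", "B", "C"))
  expect_identical(h$bins, 0L)
  expect_equal(h$prob, 1)
  expect_identical(h$n_occurrences, 2L)
  expect_equal(sum(h$prob), 1)
})

test_that("positions inside and after motifs bin correctly, repeats collapse", {
  # novel inserted between B and C of the second motif: position -1
  bouts <- list(c("A", "B", "C", "A", "B", "X", "C"))
  h <- novel_position_histogram(bouts, "X", c("A", "B", "C"))
  expect_identical(h$bins, -1L)
  # stuttered rendition still counts as a completed motif
  b2 <- list(c("A", "A", "B", "C", "X"))
  h2 <- novel_position_histogram(b2, "X", c("A", "B", "C"))
  expect_identical(h2$bins, 0L)
  # a bout with novel labels but no completed motif is skipped with a warning
  expect_warning(
    h3 <- novel_position_histogram(list(c("A", "B", "X")), "X", c("A", "B", "C")),
    "skipped")
  expect_identical(h3$n_skipped, 1L)
  expect_error(novel_position_histogram(list("A"), "A", c("A", "B")), "disjoint")
})

test_that("simulated motif-end novelty concentrates at bin 0", {
  setup <- finch_study_setup()
  bouts <- simulate_bout_labels(setup$grammar, setup$novelty, n_bouts = 50,
                                seed = 91L)
  h <- novel_position_histogram(bouts, c("X", "Y"), setup$grammar$core_motif)
  expect_gte(h$prob[h$bins == 0], 0.9)
  expect_equal(sum(h$prob), 1)
})

test_that("bout splitting follows annotation gaps", {
  ann <- data.frame(onset_s = c(0.1, 0.3, 5.0, 5.2), offset_s = c(0.2, 0.4, 5.1, 5.3),
                    label = c("A", "B", "A", "B"))
  bouts <- bouts_from_annotations(ann, bout_gap_s = 2)
  expect_identical(length(bouts), 2L)
  expect_identical(bouts[[1]], c("A", "B"))
})
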