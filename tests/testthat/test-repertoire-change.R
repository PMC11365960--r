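fake_self <- function(label, mean, std, n = 10L) {
  scores <- with_seed(utf8ToInt(label), stats::rnorm(n, mean, std))
  structure(list(label = label, mean = mean, std = std,
                 n_pairs = n, scores = scores),
            class = "self_similarity")
}

test_that("the 1.96-sigma rule evaluates hand-computed margins", {
  self_stats <- list(A = fake_self("A", 90, 4), B = fake_self("B", 92, 3))
  # thresholds: 90 - 1.96*4 = 82.16 and 92 - 1.96*3 = 86.12
  v <- classify_novel("cand", self_stats, c(A = 60, B = 70))
  expect_true(v$is_novel)
  expect_equal(unname(v$margins), c(60 - 82.16, 70 - 86.12))

  # one cross mean above its threshold defeats novelty (all-types quantifier)
  v2 <- classify_novel("cand", self_stats, c(A = 60, B = 88))
  expect_false(v2$is_novel)
})

test_that("a copy of a pre-existing type is not classified as novel", {
  self_stats <- list(A = fake_self("A", 94, 3), B = fake_self("B", 90, 5))
  v <- classify_novel("A2", self_stats, c(A = 93.5, B = 55))
  expect_false(v$is_novel)
})

test_that("incomplete cross-similarity evidence is rejected", {
  self_stats <- list(A = fake_self("A", 94, 3), B = fake_self("B", 90, 5))
  expect_error(classify_novel("cand", self_stats, c(A = 60)), "missing")
})

test_that("novelty verdicts are monotone in z: larger z is stricter", {
  with_seed(21L, {
    for (rep in 1:40) {
      n_pre <- sample(2:5, 1)
      self_stats <- lapply(seq_len(n_pre), function(i) {
        fake_self(LETTERS[i], stats::runif(1, 80, 98), stats::runif(1, 1, 12))
      })
      names(self_stats) <- LETTERS[seq_len(n_pre)]
      cm <- stats::setNames(stats::runif(n_pre, 30, 98), LETTERS[seq_len(n_pre)])
      zs <- sort(stats::runif(3, 0.5, 4))
      verdicts <- vapply(zs, function(z) {
        classify_novel("c", self_stats, cm, novelty_criterion(z))$is_novel
      }, logical(1))
      # the threshold mean - z*std falls as z grows, so a larger z can only
      # turn novel verdicts into not-novel, never the reverse
      expect_true(all(diff(as.integer(verdicts)) <= 0))
    }
  })
})

test_that("novel verdicts are counted per subject", {
  self_stats <- list(A = fake_self("A", 90, 4))
  v_yes <- classify_novel("n1", self_stats, c(A = 50))
  v_no <- classify_novel("n2", self_stats, c(A = 89))
  expect_identical(count_new_syllables(list(v_no, v_no)), 0L)
  expect_identical(count_new_syllables(list(v_yes, v_no, v_yes)), 2L)
})

make_blobs <- function(centres, n_each, epoch, sd = 0.4, seed = 1L) {
  with_seed(seed, {
    V <- do.call(rbind, lapply(seq_len(nrow(centres)), function(i) {
      matrix(stats::rnorm(n_each * ncol(centres), mean = rep(centres[i, ], each = n_each),
                          sd = sd), nrow = n_each)
    }))
  })
  list(vectors = V, epochs = rep(epoch, each = n_each))
}

test_that("clustering finds no new clusters in baseline-only data", {
  centres <- matrix(c(0, 0, 8, 0, 0, 8, 8, 8), ncol = 2, byrow = TRUE)
  b <- make_blobs(centres, 60, rep("baseline", 4), seed = 31L)
  cc <- embed_and_cluster(b$vectors, b$epochs, min_cluster_size = 25,
                          refine_iter = 0, seed = 1L)
  expect_identical(cc$n_new_clusters, 0L)
  expect_gte(cc$n_clusters, 4L)
})

test_that("three injected final-epoch blobs yield three new clusters", {
  centres_old <- matrix(c(0, 0, 10, 0, 0, 10), ncol = 2, byrow = TRUE)
  centres_new <- matrix(c(10, 10, -10, 5, 5, -10), ncol = 2, byrow = TRUE)
  old_b <- make_blobs(centres_old, 40, rep("baseline", 3), seed = 32L)
  old_f <- make_blobs(centres_old, 40, rep("final", 3), seed = 33L)
  new_f <- make_blobs(centres_new, 40, rep("final", 3), sd = 1.2, seed = 34L)
  V <- rbind(old_b$vectors, old_f$vectors, new_f$vectors)
  ep <- c(old_b$epochs, old_f$epochs, new_f$epochs)
  cc <- embed_and_cluster(V, ep, min_cluster_size = 25, refine_iter = 5, seed = 2L)
  expect_identical(cc$n_new_clusters, 3L)
  expect_identical(cc$n_clusters, 6L)
})

test_that("clustering is deterministic given the seed and rejects bad input", {
  centres <- matrix(c(0, 0, 9, 9), ncol = 2, byrow = TRUE)
  b <- make_blobs(centres, 40, c("baseline", "final"), seed = 35L)
  c1 <- embed_and_cluster(b$vectors, b$epochs, refine_iter = 0, seed = 7L)
  c2 <- embed_and_cluster(b$vectors, b$epochs, refine_iter = 0, seed = 7L)
  expect_identical(c1$cluster, c2$cluster)
  expect_identical(c1$n_new_clusters, c2$n_new_clusters)

  expect_error(embed_and_cluster(matrix(1, 60, 3), rep("baseline", 60)),
               "degenerate")
  expect_error(embed_and_cluster(matrix(stats::rnorm(30), 10, 3),
                                 rep("baseline", 10)), ">= 50")
})

test_that("false-novel rate on novelty-free jittered corpora stays low", {
  # the specificity property behind control-condition counts: over 20 seeded
  # rendition sets with realistic jitter and no injected types, at most 5%
  # of pre-existing types may be misclassified as novel
  setup <- finch_study_setup(n_novel = 0)
  arche <- setup$archetypes
  n_false <- 0L; n_total <- 0L
  for (run in 1:20) {
    tracks <- lapply(arche, function(a) {
      lapply(1:6, function(i) {
        extract_features(synth_syllable(a, setup$jitter, noise_floor_db = -40,
                                        seed = run * 1000L + utf8ToInt(a$label) * 7L + i),
                         id = a$label)
      })
    })
    scaling <- estimate_scaling(unlist(tracks, recursive = FALSE),
                                n_background = 2000, seed = run)
    # "baseline": first 3 renditions; "final" candidates: last 3
    base <- lapply(tracks, function(t) t[1:3])
    final <- lapply(tracks, function(t) t[4:6])
    self_stats <- lapply(names(base), function(lab) {
      self_similarity(base[[lab]], scaling, label = lab)
    })
    names(self_stats) <- names(base)
    cm <- cross_similarity_means(cross_similarity(final, base, scaling))
    for (cand in names(final)) {
      row <- cm[cm$type_a == cand, ]
      v <- classify_novel(cand, self_stats, stats::setNames(row$mean, row$type_b))
      n_total <- n_total + 1L
      n_false <- n_false + as.integer(v$is_novel)
    }
  }
  expect_lte(n_false / n_total, 0.05)
})

test_that("nonparametric group comparisons match the established implementations", {
  g_same <- list(a = c(1, 2, 3, 4, 5, 6), b = c(1, 2, 3, 4, 5, 6))
  res <- compare_score_groups(g_same, "wilcoxon_rank_sum")
  expect_gt(res$p_value, 0.9)

  with_seed(51L, {
    g2 <- list(a = stats::rnorm(100), b = stats::rnorm(100, 3))
  })
  expect_lt(compare_score_groups(g2, "wilcoxon_rank_sum")$p_value, 0.001)
  expect_lt(compare_score_groups(g2, "kruskal_wallis")$p_value, 0.001)

  # Kruskal-Wallis on {1,2,3},{4,5,6},{7,8,9}: rank sums 6, 15, 24 give
  # H = 12/(9*10) * (36/3 + 225/3 + 576/3) - 3*10 = 7.2 (no ties)
  kw <- compare_score_groups(list(a = 1:3, b = 4:6, c = 7:9), "kruskal_wallis")
  expect_equal(kw$statistic, 7.2)

  expect_error(compare_score_groups(list(a = 1:3, b = 1:4), "wilcoxon_signed_rank"),
               "equal")
  expect_error(compare_score_groups(list(a = 1:3, b = 1:4), "friedman"), "equal")
})
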