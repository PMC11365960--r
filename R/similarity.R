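#' Percent similarity between two syllable renditions
#'
#' The comparison is conducted symmetrically across the time course of the
#' pair: both feature tracks are linearly time-rescaled to a common length
#' `K` (the rounded mean of the two frame counts), each aligned frame pair
#' is compared by Euclidean distance of the MAD-scaled feature vectors, and
#' a frame pair counts as similar when its distance falls below the
#' `q`-quantile of the background distance distribution of random frame
#' pairs from the scaling corpus. The score is 100 times the similar-frame
#' fraction; linear rescaling makes it symmetric in its arguments by
#' construction, and identical tracks score exactly 100.
#'
#' @param a,b `feature_track`s with >= 2 frames each.
#' @param scaling a [estimate_scaling()] result shared by both tracks.
#' @param q background-distance quantile defining "similar" (default 0.5).
#' @return list of class `similarity_score`: `value` (percent in `[0, 100]`),
#'   `pair` (the two track ids), `k_frames`.
#' @export
syllable_similarity <- function(a, b, scaling, q = 0.5) {
  ma <- feature_matrix(a); mb <- feature_matrix(b)
  if (nrow(ma) < 2L || nrow(mb) < 2L) {
    stop("tracks must have >= 2 frames", call. = FALSE)
  }
  thr <- similarity_threshold(scaling, q)
  value <- score_scaled_pair(scale_frames(ma, scaling), scale_frames(mb, scaling), thr)
  structure(list(value = value, pair = c(a$id, b$id),
                 k_frames = max(2L, round((nrow(ma) + nrow(mb)) / 2))),
            class = "similarity_score")
}

similarity_threshold <- function(scaling, q) {
  max(stats::quantile(scaling$bg_distances, q, names = FALSE), 1e-9)
}

# Percent score between two MAD-scaled frame matrices.
score_scaled_pair <- function(sa, sb, thr) {
  k <- max(2L, round((nrow(sa) + nrow(sb)) / 2))
  a <- rescale_track(sa, k)
  b <- rescale_track(sb, k)
  d2 <- rowSums((a - b)^2)
  100 * mean(d2 < thr * thr)
}

# Linear time-rescaling of a frame matrix to k rows.
rescale_track <- function(mat, k) {
  n <- nrow(mat)
  if (n == k) return(mat)
  xout <- seq(1, n, length.out = k)
  lo <- pmax(floor(xout), 1L)
  hi <- pmin(lo + 1L, n)
  fr <- xout - lo
  mat[lo, , drop = FALSE] * (1 - fr) + mat[hi, , drop = FALSE] * fr
}

#' Self-similarity of one syllable type across renditions
#'
#' All pairwise percent-similarity scores among up to `n_max` renditions
#' (the first `n_max` in temporal order; the study used ten), summarised as
#' mean +/- std. These per-type statistics feed the 1.96-sigma novelty
#' criterion.
#'
#' @param renditions list of `feature_track`s of one type (>= 2).
#' @param scaling shared [estimate_scaling()] result.
#' @param n_max maximum number of renditions used (default 10).
#' @param label type label recorded in the result.
#' @param q passed to [syllable_similarity()].
#' @return list of class `self_similarity`: `label`, `mean`, `std`,
#'   `n_pairs`, `scores`.
#' @export
self_similarity <- function(renditions, scaling, n_max = 10L,
                            label = NA_character_, q = 0.5) {
  if (length(renditions) < 2L) stop("need >= 2 renditions", call. = FALSE)
  use <- renditions[seq_len(min(length(renditions), n_max))]
  n <- length(use)
  thr <- similarity_threshold(scaling, q)
  scaled <- lapply(use, function(t) scale_frames(feature_matrix(t), scaling))
  scores <- numeric(n * (n - 1L) / 2L)
  p <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      p <- p + 1L
      scores[p] <- score_scaled_pair(scaled[[i]], scaled[[j]], thr)
    }
  }
  structure(list(label = label, mean = mean(scores),
                 std = if (length(scores) > 1L) stats::sd(scores) else 0,
                 n_pairs = length(scores), scores = scores),
            class = "self_similarity")
}

#' @export
print.self_similarity <- function(x, ...) {
  cat(sprintf("<self_similarity '%s': %.2f +/- %.2f %% over %d pairs>\n",
              x$label, x$mean, x$std, x$n_pairs))
  invisible(x)
}

#' Cross-similarity score distributions between groups of syllable types
#'
#' For every pair of a type in `group_a` and a type in `group_b`, computes
#' the full set of pairwise rendition scores (up to `n_max` renditions per
#' type), not just means, so ECD curves can be built from them. Empty types
#' are skipped with a warning.
#'
#' @param group_a,group_b named lists: type label -> list of `feature_track`s.
#' @param scaling shared [estimate_scaling()] result.
#' @param n_max renditions used per type (default 10).
#' @param q passed to [syllable_similarity()].
#' @return data.frame with columns `type_a`, `type_b`, `rendition_a`,
#'   `rendition_b`, `score`.
#' @export
cross_similarity <- function(group_a, group_b, scaling, n_max = 10L, q = 0.5) {
  thr <- similarity_threshold(scaling, q)
  take <- function(g) lapply(g, function(r) {
    lapply(r[seq_len(min(length(r), n_max))],
           function(t) scale_frames(feature_matrix(t), scaling))
  })
  sa <- take(group_a); sb <- take(group_b)
  ta <- tb <- character(0); ia <- ib <- integer(0); sc <- numeric(0)
  for (la in names(sa)) {
    if (length(sa[[la]]) == 0L) { warning("empty type '", la, "' skipped"); next }
    for (lb in names(sb)) {
      if (length(sb[[lb]]) == 0L) { warning("empty type '", lb, "' skipped"); next }
      na <- length(sa[[la]]); nb <- length(sb[[lb]])
      s <- numeric(na * nb)
      p <- 0L
      for (i in seq_len(na)) {
        for (j in seq_len(nb)) {
          p <- p + 1L
          s[p] <- score_scaled_pair(sa[[la]][[i]], sb[[lb]][[j]], thr)
        }
      }
      ta <- c(ta, rep(la, p)); tb <- c(tb, rep(lb, p))
      ia <- c(ia, rep(seq_len(na), each = nb)); ib <- c(ib, rep(seq_len(nb), na))
      sc <- c(sc, s)
    }
  }
  data.frame(type_a = ta, type_b = tb, rendition_a = ia, rendition_b = ib,
             score = sc, stringsAsFactors = FALSE)
}

#' Mean cross-similarity per type pair
#' @param cross data.frame from [cross_similarity()].
#' @return data.frame `type_a`, `type_b`, `mean`, `n`.
#' @export
cross_similarity_means <- function(cross) {
  agg <- stats::aggregate(score ~ type_a + type_b, data = cross, FUN = mean)
  names(agg)[3] <- "mean"
  agg$n <- stats::aggregate(score ~ type_a + type_b, data = cross, FUN = length)$score
  agg
}

#' Empirical cumulative density curve with bootstrap confidence bands
#'
#' Point ECD of the scores plus pointwise 95% bands: the 2.5th/97.5th
#' percentiles of ECD values over `n_bootstrap` resamples with replacement
#' (same n), evaluated at the sorted sample values. Bands are widened where
#' needed to bracket the point curve. Deterministic given `seed`.
#'
#' @param scores numeric vector of >= 5 percent scores.
#' @param n_bootstrap number of bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return data.frame of class `ecd_curve`: `score`, `ecdf`, `ci_lo`,
#'   `ci_hi`, with attribute `n_bootstrap`.
#' @export
ecd_with_ci <- function(scores, n_bootstrap = 1000L, seed = 1L) {
  if (length(scores) < 5L) stop("need >= 5 scores for an ECD curve", call. = FALSE)
  x <- sort(scores)
  n <- length(x)
  point <- stats::ecdf(x)(x)
  boot <- with_seed(seed, {
    vapply(seq_len(n_bootstrap), function(b) {
      stats::ecdf(sample(x, n, replace = TRUE))(x)
    }, numeric(n))
  })
  lo <- apply(boot, 1, stats::quantile, probs = 0.025, names = FALSE)
  hi <- apply(boot, 1, stats::quantile, probs = 0.975, names = FALSE)
  out <- data.frame(score = x, ecdf = point,
                    ci_lo = pmin(lo, point), ci_hi = pmax(hi, point))
  attr(out, "n_bootstrap") <- n_bootstrap
  class(out) <- c("ecd_curve", "data.frame")
  out
}
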