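#' Novelty criterion for syllable types
#'
#' A candidate syllable type is considered novel when its similarity to
#' every pre-existing type diverges by more than `z` standard deviations
#' below that type's self-similarity (default `z = 1.96`). Divergence is
#' taken one-sided below, since novelty means lower similarity. In `"each"`
#' mode (default) the candidate must clear the threshold of every
#' pre-existing type using that type's own self-similarity std; `"pooled"`
#' mode compares the candidate's pooled cross-similarity mean against the
#' mean - z * std of all pre-existing self-similarity scores pooled.
#'
#' @param z positive std multiplier (default 1.96).
#' @param mode `"each"` or `"pooled"`.
#' @param min_std dispersion floor in percent (default 1, the score's
#'   frame-quantisation scale). Highly stereotyped types can have a
#'   self-similarity std of exactly 0, which would turn the threshold
#'   `mean - z * std` into a degenerate test that any infinitesimal score
#'   difference "diverges" from; the floor keeps the criterion meaningful.
#' @return an object of class `novelty_criterion`.
#' @export
novelty_criterion <- function(z = 1.96, mode = c("each", "pooled"),
                              min_std = 1) {
  stopifnot_scalar(z, "z", lo = 1e-12)
  stopifnot_scalar(min_std, "min_std", lo = 0)
  structure(list(z = z, mode = match.arg(mode), min_std = min_std),
            class = "novelty_criterion")
}

#' Classify one candidate syllable type as novel or pre-existing
#'
#' @param candidate candidate type label.
#' @param self_stats named list of [self_similarity()] results, one per
#'   pre-existing type.
#' @param cross_means named numeric vector: mean cross-similarity of the
#'   candidate to each pre-existing type. Every pre-existing type must have
#'   an entry (incomplete evidence is rejected).
#' @param criterion a [novelty_criterion()].
#' @return list of class `novelty_verdict`: `candidate`, `margins` (named:
#'   cross mean minus the type's novelty threshold `self mean - z * self
#'   std`; novel iff every margin < 0), `is_novel`.
#' @export
classify_novel <- function(candidate, self_stats, cross_means,
                           criterion = novelty_criterion()) {
  if (length(self_stats) < 1L) stop("need >= 1 pre-existing type", call. = FALSE)
  pre <- names(self_stats)
  missing <- setdiff(pre, names(cross_means))
  if (length(missing)) {
    stop("missing cross-similarity for pre-existing type(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (criterion$mode == "each") {
    thr <- vapply(self_stats, function(s) {
      s$mean - criterion$z * max(s$std, criterion$min_std)
    }, numeric(1))
    margins <- as.numeric(cross_means[pre]) - thr
    names(margins) <- pre
    is_novel <- all(margins < 0)
  } else {
    pooled <- unlist(lapply(self_stats, function(s) s$scores))
    thr <- mean(pooled) - criterion$z * max(stats::sd(pooled), criterion$min_std)
    margins <- stats::setNames(mean(as.numeric(cross_means[pre])) - thr, "pooled")
    is_novel <- margins < 0
  }
  structure(list(candidate = candidate, margins = margins,
                 is_novel = unname(is_novel)),
            class = "novelty_verdict")
}

#' @export
print.novelty_verdict <- function(x, ...) {
  cat(sprintf("<novelty_verdict '%s': %s (min margin %.2f)>\n", x$candidate,
              if (x$is_novel) "NOVEL" else "pre-existing", min(x$margins)))
  invisible(x)
}

#' Count novel syllable types from a set of verdicts
#'
#' @param verdicts list of [classify_novel()] results from one subject and
#'   one epoch comparison.
#' @return integer count of novel types.
#' @export
count_new_syllables <- function(verdicts) {
  sum(vapply(verdicts, function(v) isTRUE(v$is_novel), logical(1)))
}

#' Fixed-length summary vector of one syllable rendition
#'
#' Mean and standard deviation of each of the six spectral features plus the
#' syllable duration: 13 values, the clustering representation that avoids
#' per-frame resampling choices.
#'
#' @param track a `feature_track`.
#' @return named numeric vector of length 13.
#' @export
syllable_summary_vector <- function(track) {
  m <- feature_matrix(track)
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  sdv[is.na(sdv)] <- 0
  dur <- max(track$times) - min(track$times)
  stats::setNames(c(mu, sdv, dur),
                  c(paste0(FEATURE_NAMES, "_mean"), paste0(FEATURE_NAMES, "_sd"),
                    "duration_s"))
}

# Hierarchical density-based clustering (HDBSCAN, excess-of-mass cluster
# selection) on a precomputed distance matrix. Steps: (1) mutual
# reachability distances max(core_i, core_j, d_ij) with core_i the
# min_pts-nearest-neighbour distance; (2) single-linkage hierarchy;
# (3) condensed tree: a dendrogram split is a true split only when both
# sides have >= min_cluster_size points, otherwise the small side falls out
# of the running cluster; (4) flat clusters = the locally most stable
# (excess of mass) clusters, everything else noise (0). Handles clusters of
# very different density -- a fixed-radius density rule cannot separate
# tight pre-existing syllable types while keeping sparse, variable novel
# types intact.
hdbscan_labels <- function(dmat, min_pts, min_cluster_size) {
  n <- nrow(dmat)
  core <- apply(dmat, 1, function(r) sort(r)[min_pts + 1L])
  mreach <- pmax(dmat, outer(core, core, pmax))
  hc <- stats::hclust(stats::as.dist(mreach), method = "single")
  merge <- hc$merge
  heights <- pmax(hc$height, 1e-12)
  # subtree sizes per internal node
  sizes <- integer(n - 1L)
  for (i in seq_len(n - 1L)) {
    sizes[i] <- sum(ifelse(merge[i, ] < 0, 1L, sizes[pmax(merge[i, ], 1L)]))
  }
  leaves_of <- function(node) {         # iterative subtree leaf collection
    out <- integer(0); stack <- node
    while (length(stack)) {
      nd <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (nd < 0) out <- c(out, -nd) else stack <- c(stack, merge[nd, ])
    }
    out
  }
  # condensed tree accumulators
  max_cl <- 2L * n
  stab <- numeric(max_cl); birth <- numeric(max_cl)
  parent_cl <- integer(max_cl); children <- vector("list", max_cl)
  pt_cluster <- integer(n)              # condensed-tree parent of each point
  n_cl <- 1L; birth[1L] <- 0; parent_cl[1L] <- 0L
  node_size <- function(ch) if (ch < 0) 1L else sizes[ch]
  # top-down walk: (tree node, running cluster id)
  stack <- list(c(n - 1L, 1L))
  while (length(stack)) {
    fr <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    node <- fr[1]; cl <- fr[2]
    lam <- 1 / heights[node]
    ch <- merge[node, ]
    s <- c(node_size(ch[1]), node_size(ch[2]))
    if (all(s >= min_cluster_size)) {
      stab[cl] <- stab[cl] + sum(s) * (lam - birth[cl])   # cluster dies here
      for (k in 1:2) {
        n_cl <- n_cl + 1L
        birth[n_cl] <- lam; parent_cl[n_cl] <- cl
        children[[cl]] <- c(children[[cl]], n_cl)
        stack[[length(stack) + 1L]] <- c(ch[k], n_cl)
      }
    } else {
      for (k in 1:2) {
        if (s[k] >= min_cluster_size) {           # cluster continues
          stack[[length(stack) + 1L]] <- c(ch[k], cl)
        } else {                                  # points fall out at lam
          pts <- if (ch[k] < 0) -ch[k] else leaves_of(ch[k])
          stab[cl] <- stab[cl] + length(pts) * (lam - birth[cl])
          pt_cluster[pts] <- cl
        }
      }
    }
  }
  # excess-of-mass selection, root (cluster 1) never selectable
  selected <- logical(n_cl)
  s_hat <- numeric(n_cl)
  for (cl in n_cl:1L) {
    kids <- children[[cl]]
    kid_sum <- if (length(kids)) sum(s_hat[kids]) else 0
    if (cl == 1L) { s_hat[cl] <- kid_sum; next }
    if (length(kids) && kid_sum > stab[cl]) {
      s_hat[cl] <- kid_sum
    } else {
      s_hat[cl] <- stab[cl]
      selected[cl] <- TRUE
      # deselect all descendants
      dstack <- kids
      while (length(dstack)) {
        d <- dstack[[length(dstack)]]; dstack <- dstack[-length(dstack)]
        selected[d] <- FALSE
        dstack <- c(dstack, children[[d]])
      }
    }
  }
  # flat labels: nearest selected ancestor of each point's parent cluster
  labels <- integer(n)
  sel_ids <- which(selected)
  if (length(sel_ids)) {
    map <- integer(n_cl)
    map[sel_ids] <- seq_along(sel_ids)
    for (p in seq_len(n)) {
      cl <- pt_cluster[p]
      while (cl > 0L && !selected[cl]) cl <- parent_cl[cl]
      labels[p] <- if (cl > 0L) map[cl] else 0L
    }
  }
  # enforce the minimum size on final memberships, renumber consecutively
  if (any(labels > 0L)) {
    tab <- tabulate(labels, nbins = max(labels))
    labels[labels %in% which(tab < min_cluster_size)] <- 0L
    keep <- sort(unique(labels[labels > 0L]))
    labels <- match(labels, keep, nomatch = 0L)
  }
  labels
}

#' Embed syllables in 2-D and count epoch-specific clusters
#'
#' The cluster-based cross-check of the feature-route novelty count: each
#' syllable rendition is summarised as a fixed-length vector
#' ([syllable_summary_vector()]), z-scored, clustered with hierarchical
#' density-based clustering (HDBSCAN with a minimum cluster size; smaller
#' clusters and unassigned points count as noise), and embedded in two
#' dimensions for visualisation (classical MDS, optionally refined by
#' nonmetric MDS). Clustering runs in the full summary space, not the 2-D
#' projection, so cluster counts do not depend on projection quality. A
#' cluster is "new" when at least `new_fraction` of its members carry the
#' final epoch tag. Deterministic given `seed`.
#'
#' @param vectors numeric matrix, one row per syllable (finite values; all
#'   rows identical is rejected).
#' @param epochs character vector per row, `"baseline"` or `"final"`.
#' @param min_cluster_size clusters smaller than this become noise
#'   (default 25).
#' @param min_pts neighbourhood size for the density (core distance) estimate
#'   (default 5).
#' @param new_fraction final-epoch membership fraction defining a new
#'   cluster (default 0.95).
#' @param refine_iter nonmetric-MDS refinement iterations for the 2-D
#'   embedding (0 = classical MDS only; refinement does not affect cluster
#'   counts).
#' @param seed integer seed (used for the degeneracy-breaking jitter).
#' @return list of class `cluster_comparison`: `embedding` (n x 2),
#'   `cluster` (integer, 0 = noise), `epoch`, `n_new_clusters`,
#'   `n_clusters`.
#' @export
embed_and_cluster <- function(vectors, epochs, min_cluster_size = 25L,
                              min_pts = 5L, new_fraction = 0.95,
                              refine_iter = 10L, seed = 1L) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < 50L) stop("need >= 50 syllables to cluster", call. = FALSE)
  if (!all(is.finite(vectors))) stop("summary vectors must be finite", call. = FALSE)
  sds <- apply(vectors, 2, stats::sd)
  if (all(sds < 1e-12)) stop("degenerate input: all summary vectors identical", call. = FALSE)
  z <- sweep(sweep(vectors, 2, colMeans(vectors)), 2, pmax(sds, 1e-9), "/")
  # tiny seeded jitter breaks exact duplicates (zero distances stall
  # nonmetric MDS) without moving points at any meaningful scale
  z <- z + with_seed(seed, matrix(stats::rnorm(length(z), 0, 1e-7), nrow(z)))
  dmat <- as.matrix(stats::dist(z))
  labels <- hdbscan_labels(dmat, min_pts, min_cluster_size)
  # classical MDS of Euclidean distances == PCA scores, computed the cheap way
  init <- stats::prcomp(z, rank. = 2)$x[, 1:2, drop = FALSE]
  emb <- init
  if (refine_iter > 0L) {
    emb <- tryCatch(
      MASS::isoMDS(stats::as.dist(dmat), y = init, k = 2,
                   maxit = refine_iter, trace = FALSE)$points,
      error = function(e) init)
  }
  ncl <- max(labels)
  n_new <- 0L
  if (ncl > 0L) {
    for (k in seq_len(ncl)) {
      memb <- epochs[labels == k]
      if (mean(memb == "final") >= new_fraction) n_new <- n_new + 1L
    }
  }
  structure(list(embedding = emb, cluster = labels, epoch = epochs,
                 n_new_clusters = n_new, n_clusters = ncl),
            class = "cluster_comparison")
}

#' @export
print.cluster_comparison <- function(x, ...) {
  cat(sprintf("<cluster_comparison: %d clusters (%d new), %d noise points>\n",
              x$n_clusters, x$n_new_clusters, sum(x$cluster == 0L)))
  invisible(x)
}

#' Write a cluster table as CSV
#' @param cc a `cluster_comparison`.
#' @param path CSV path (`syllable_id, epoch, x, y, cluster`).
#' @export
cluster_table_write <- function(cc, path) {
  utils::write.csv(data.frame(syllable_id = seq_along(cc$cluster),
                              epoch = cc$epoch,
                              x = cc$embedding[, 1], y = cc$embedding[, 2],
                              cluster = cc$cluster),
                   path, row.names = FALSE)
  invisible(path)
}

#' Nonparametric comparison of score groups
#'
#' Thin dispatch to the established implementations in \pkg{stats}:
#' Kruskal-Wallis, Wilcoxon rank-sum, Wilcoxon signed-rank (paired, requires
#' equal lengths), and Friedman (groups as matrix columns, equal lengths).
#'
#' @param groups named list of numeric score vectors.
#' @param test one of `"kruskal_wallis"`, `"wilcoxon_rank_sum"`,
#'   `"wilcoxon_signed_rank"`, `"friedman"`.
#' @return list with `statistic`, `p_value`, `method`.
#' @export
compare_score_groups <- function(groups,
                                 test = c("kruskal_wallis", "wilcoxon_rank_sum",
                                          "wilcoxon_signed_rank", "friedman")) {
  test <- match.arg(test)
  res <- switch(test,
    kruskal_wallis = stats::kruskal.test(groups),
    wilcoxon_rank_sum = {
      if (length(groups) != 2L) stop("rank-sum test needs exactly 2 groups", call. = FALSE)
      stats::wilcox.test(groups[[1]], groups[[2]], exact = FALSE)
    },
    wilcoxon_signed_rank = {
      if (length(groups) != 2L) stop("signed-rank test needs exactly 2 groups", call. = FALSE)
      if (length(groups[[1]]) != length(groups[[2]])) {
        stop("paired test needs equal group lengths", call. = FALSE)
      }
      stats::wilcox.test(groups[[1]], groups[[2]], paired = TRUE, exact = FALSE)
    },
    friedman = {
      lens <- lengths(groups)
      if (length(unique(lens)) != 1L) {
        stop("Friedman test needs equal group lengths", call. = FALSE)
      }
      stats::friedman.test(do.call(cbind, groups))
    })
  list(statistic = unname(res$statistic), p_value = res$p.value,
       method = res$method)
}
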