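#' @name sequence_analysis
#' @title Syllable-sequence statistics
#'
#' @description
#' Bout-level sequence statistics used to characterise song stereotypy and
#' where novel syllables enter the song: transition matrices (ordered
#' adjacent label pairs within bouts, never across bout boundaries),
#' sequence linearity (number of distinct notes divided by number of
#' distinct transition types; 1 for a perfectly linear song), sequence
#' consistency (fraction of transitions that follow their source's typical,
#' i.e. modal, successor; 1 for a perfectly consistent song), and the
#' relative-position histogram of novel syllables with respect to core
#' motif ends. Introductory notes are excluded by default, as they are
#' annotated separately from song syllables.
NULL

# Normalise input to a list of character label vectors, optionally dropping
# introductory notes; empty bouts are removed.
prep_bouts <- function(bouts, include_intro = FALSE, intro_label = "i") {
  if (is.character(bouts)) bouts <- list(bouts)
  bouts <- lapply(bouts, as.character)
  if (!include_intro) bouts <- lapply(bouts, function(b) b[b != intro_label])
  bouts[lengths(bouts) > 0L]
}

# Pooled within-bout transitions, in observation order.
bout_transitions <- function(bouts) {
  pairs <- lapply(bouts, function(b) {
    n <- length(b)
    if (n < 2L) return(NULL)
    data.frame(from = b[-n], to = b[-1], stringsAsFactors = FALSE)
  })
  do.call(rbind, pairs)
}

#' Syllable transition matrix
#'
#' Counts of ordered adjacent label pairs within each bout (no transitions
#' across bout boundaries) and the row-normalised transition proportions
#' (rows with no outgoing transitions stay all-zero).
#'
#' @param bouts list of character label vectors (one per bout).
#' @param include_intro keep introductory notes (default `FALSE`).
#' @param intro_label introductory-note label (default `"i"`).
#' @param alphabet optional fixed label alphabet; defaults to the sorted
#'   labels observed.
#' @return list of class `transition_matrix`: `alphabet`, `counts`,
#'   `proportions`.
#' @export
transition_matrix <- function(bouts, include_intro = FALSE, intro_label = "i",
                              alphabet = NULL) {
  bouts <- prep_bouts(bouts, include_intro, intro_label)
  if (!length(bouts)) stop("no labelled syllables in bouts", call. = FALSE)
  alphabet <- alphabet %||% sort(unique(unlist(bouts)))
  if (!length(alphabet)) stop("empty alphabet", call. = FALSE)
  counts <- matrix(0L, length(alphabet), length(alphabet),
                   dimnames = list(from = alphabet, to = alphabet))
  tr <- bout_transitions(bouts)
  if (!is.null(tr)) {
    tab <- table(factor(tr$from, alphabet), factor(tr$to, alphabet))
    counts <- counts + unclass(tab)
  }
  rs <- rowSums(counts)
  props <- counts / ifelse(rs > 0, rs, 1)
  structure(list(alphabet = alphabet, counts = counts, proportions = props),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix over {%s}: %d transitions>\n",
              paste(x$alphabet, collapse = ","), sum(x$counts)))
  print(round(x$proportions, 3))
  invisible(x)
}

#' Write a transition matrix as CSV
#' @param tm a [transition_matrix()].
#' @param path CSV path; rows = source labels, columns = target labels.
#' @param what `"proportions"` or `"counts"`.
#' @export
transition_matrix_write <- function(tm, path, what = c("proportions", "counts")) {
  what <- match.arg(what)
  utils::write.csv(as.data.frame(tm[[what]]), path, row.names = TRUE)
  invisible(path)
}

#' Sequence linearity
#'
#' Number of distinct notes divided by number of distinct transition types,
#' pooled over the analysed bout set (one value per bird and condition);
#' 1 for a perfectly linear song. With `per_bout = TRUE`, returns one value
#' per bout instead.
#'
#' @inheritParams transition_matrix
#' @param per_bout compute per bout rather than pooled.
#' @return linearity ratio in `(0, 1]`, or a vector with `per_bout = TRUE`.
#' @export
sequence_linearity <- function(bouts, include_intro = FALSE, intro_label = "i",
                               per_bout = FALSE) {
  bouts <- prep_bouts(bouts, include_intro, intro_label)
  one <- function(bs) {
    tr <- bout_transitions(bs)
    if (is.null(tr) || nrow(tr) == 0L) {
      stop("no transitions observed; linearity undefined", call. = FALSE)
    }
    n_notes <- length(unique(unlist(bs)))
    n_types <- nrow(unique(tr))
    n_notes / n_types
  }
  if (per_bout) vapply(bouts, function(b) one(list(b)), numeric(1)) else one(bouts)
}

#' Sequence consistency
#'
#' Fraction of observed transitions that are typical, where the typical
#' transition of each source label is its modal successor (ties broken to
#' the earliest-observed successor); 1 for a perfectly consistent song.
#' Pooled over the analysed bout set by default.
#'
#' @inheritParams sequence_linearity
#' @return consistency ratio in `(0, 1]`, or a vector with `per_bout = TRUE`.
#' @export
sequence_consistency <- function(bouts, include_intro = FALSE, intro_label = "i",
                                 per_bout = FALSE) {
  bouts <- prep_bouts(bouts, include_intro, intro_label)
  one <- function(bs) {
    tr <- bout_transitions(bs)
    if (is.null(tr) || nrow(tr) == 0L) {
      stop("no transitions observed; consistency undefined", call. = FALSE)
    }
    typical <- 0L
    for (src in unique(tr$from)) {
      succ <- tr$to[tr$from == src]
      counts <- table(factor(succ, levels = unique(succ)))  # earliest-first levels
      typical <- typical + max(counts)
    }
    typical / nrow(tr)
  }
  if (per_bout) vapply(bouts, function(b) one(list(b)), numeric(1)) else one(bouts)
}

# Greedy left-to-right non-overlapping occurrences of motif in labels;
# returns the end indices of completed motifs.
find_motif_ends <- function(labels, motif) {
  L <- length(motif)
  ends <- integer(0)
  i <- 1L
  while (i + L - 1L <= length(labels)) {
    if (all(labels[i:(i + L - 1L)] == motif)) {
      ends <- c(ends, i + L - 1L)
      i <- i + L
    } else {
      i <- i + 1L
    }
  }
  ends
}

#' Relative-position histogram of novel syllables
#'
#' For each novel-syllable occurrence, its sequence position relative to the
#' end of the nearest completed core-motif rendition: bin 0 means
#' immediately after the motif's last syllable, negative bins fall inside
#' the motif, positive bins trail further after it. Motifs are located in
#' the bout's non-novel label sequence; consecutive repeats of a label are
#' collapsed first (so stuttered renditions still count as completed
#' motifs). Occurrences in bouts without any detectable completed motif are
#' skipped with a warning and reported in `n_skipped`.
#'
#' @param bouts list of character label vectors.
#' @param novel_labels labels of novel syllable types (disjoint from
#'   `core_motif`).
#' @param core_motif ordered core-motif labels.
#' @param intro_label introductory-note label, excluded before analysis.
#' @param collapse_repeats collapse consecutive duplicate labels before
#'   motif matching (default `TRUE`).
#' @return list of class `position_histogram`: `bins` (integer positions),
#'   `prob` (sums to 1 over counted occurrences), `n_occurrences`,
#'   `n_skipped`.
#' @export
novel_position_histogram <- function(bouts, novel_labels, core_motif,
                                     intro_label = "i",
                                     collapse_repeats = TRUE) {
  if (length(intersect(novel_labels, core_motif))) {
    stop("novel labels must be disjoint from the core motif", call. = FALSE)
  }
  bouts <- prep_bouts(bouts, include_intro = FALSE, intro_label = intro_label)
  positions <- integer(0)
  n_skipped <- 0L
  for (b in bouts) {
    is_nov <- b %in% novel_labels
    if (!any(is_nov)) next
    base <- b[!is_nov]
    # number of non-novel tokens preceding each novel occurrence
    k_orig <- (cumsum(!is_nov))[is_nov]
    if (collapse_repeats && length(base)) {
      r <- rle(base)
      run_of_token <- rep(seq_along(r$lengths), r$lengths)
      k <- ifelse(k_orig == 0L, 0L, run_of_token[pmax(k_orig, 1L)])
      base <- r$values
    } else {
      k <- k_orig
    }
    ends <- find_motif_ends(base, core_motif)
    if (!length(ends)) {
      n_skipped <- n_skipped + sum(is_nov)
      warning("bout with novel syllables but no completed core motif; ",
              sum(is_nov), " occurrence(s) skipped", call. = FALSE)
      next
    }
    for (kk in k) {
      rel <- kk - ends
      best <- which.min(abs(rel) - 0.25 * (rel >= 0))  # ties prefer preceding end
      positions <- c(positions, rel[best])
    }
  }
  if (!length(positions)) {
    return(structure(list(bins = integer(0), prob = numeric(0),
                          n_occurrences = 0L, n_skipped = n_skipped),
                     class = "position_histogram"))
  }
  tab <- table(positions)
  structure(list(bins = as.integer(names(tab)),
                 prob = as.numeric(tab) / length(positions),
                 n_occurrences = length(positions), n_skipped = n_skipped),
            class = "position_histogram")
}

#' @export
print.position_histogram <- function(x, ...) {
  cat(sprintf("<position_histogram: %d occurrences (%d skipped)>\n",
              x$n_occurrences, x$n_skipped))
  if (length(x$bins)) print(stats::setNames(round(x$prob, 3), x$bins))
  invisible(x)
}

#' Split an annotation table into bouts
#'
#' Bout boundaries are inferred from silent gaps longer than `bout_gap_s`
#' between consecutive annotations (recording sessions are continuous).
#'
#' @param ann data.frame with `onset_s`, `offset_s`, `label`, sorted or not.
#' @param bout_gap_s gap threshold in seconds (default 2).
#' @return list of character label vectors, one per bout, with the
#'   annotation row indices attached as attribute `"rows"`.
#' @export
bouts_from_annotations <- function(ann, bout_gap_s = 2) {
  if (nrow(ann) == 0L) return(list())
  ann <- ann[order(ann$onset_s), , drop = FALSE]
  gap <- c(0, ann$onset_s[-1] - ann$offset_s[-nrow(ann)])
  bout_id <- cumsum(gap > bout_gap_s) + 1L
  out <- split(ann$label, bout_id)
  attr(out, "rows") <- split(seq_len(nrow(ann)), bout_id)
  unname_keep_attr(out)
}

unname_keep_attr <- function(x) {
  rows <- attr(x, "rows")
  x <- unname(x)
  attr(x, "rows") <- if (!is.null(rows)) unname(rows) else NULL
  x
}
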