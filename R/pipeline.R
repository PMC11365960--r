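#' Build a validated end-to-end run configuration
#'
#' Collects every stage's parameters in one structure: synthesis (or WAV
#' input), segmentation, feature extraction, similarity scoring, novelty
#' detection, clustering, and sequence statistics. Parameters are validated
#' here so an invalid run is rejected before any output is written.
#'
#' @param mode `"synthetic"` (generate the corpus) or `"wav"` (read WAV
#'   files plus annotations).
#' @param seed global integer seed; every stochastic stage derives its seed
#'   from it.
#' @param out_dir output directory for intermediates and the report, or
#'   `NULL` to keep results in memory only.
#' @param synth list: `n_novel` (0-2), `n_bouts` per epoch, `sr`,
#'   `noise_floor_db`, and optionally `setup` (a [finch_study_setup()]-like
#'   list overriding archetypes/grammar/jitter/novelty).
#' @param segmentation a [segmentation_params()].
#' @param features list: `frame_ms`, `hop_ms`, `band`.
#' @param similarity list: `q`, `n_max`, `n_bootstrap`.
#' @param novelty list: `z`, `mode`, `min_cluster_size`, `min_pts`,
#'   `new_fraction`, `refine_iter`.
#' @param sequence list: `include_intro`, `intro_label`, `bout_gap_s`.
#' @param wav list (wav mode): per epoch (`baseline`, `final`) a list with
#'   `wav` (vector of bout WAV paths) and `annotations` (CSV path).
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "wav"), seed = 1L, out_dir = NULL,
                       synth = list(), segmentation = segmentation_params(),
                       features = list(), similarity = list(),
                       novelty = list(), sequence = list(), wav = list()) {
  mode <- match.arg(mode)
  stopifnot_scalar(seed, "seed", lo = 0, hi = 2^31 - 1)
  synth <- utils::modifyList(list(n_novel = 2L, n_bouts = 50L, sr = 40000,
                                  noise_floor_db = -40, setup = NULL), synth)
  stopifnot_scalar(synth$n_bouts, "synth$n_bouts", lo = 1)
  if (!synth$n_novel %in% 0:2) stop("synth$n_novel must be 0, 1 or 2", call. = FALSE)
  features <- utils::modifyList(list(frame_ms = 9.27, hop_ms = 1,
                                     band = c(300, 8000)), features)
  similarity <- utils::modifyList(list(q = 0.5, n_max = 10L, n_bootstrap = 1000L),
                                  similarity)
  stopifnot_scalar(similarity$q, "similarity$q", lo = 0, hi = 1)
  novelty <- utils::modifyList(list(z = 1.96, mode = "each", min_std = 1,
                                    min_cluster_size = 25L, min_pts = 5L,
                                    new_fraction = 0.95, refine_iter = 0L),
                               novelty)
  stopifnot_scalar(novelty$z, "novelty$z", lo = 1e-12)
  sequence <- utils::modifyList(list(include_intro = FALSE, intro_label = "i",
                                     bout_gap_s = 2), sequence)
  if (!inherits(segmentation, "segmentation_params")) {
    stop("`segmentation` must be a segmentation_params() object", call. = FALSE)
  }
  if (mode == "wav") {
    for (ep in c("baseline", "final")) {
      blk <- wav[[ep]]
      if (is.null(blk$wav) || !length(blk$wav)) {
        stop("wav mode: missing WAV paths for epoch '", ep, "'", call. = FALSE)
      }
      if (is.null(blk$annotations)) {
        stop("wav mode: missing annotations for epoch '", ep,
             "' (labelling requires an annotation CSV)", call. = FALSE)
      }
    }
  }
  cfg <- structure(list(mode = mode, seed = as.integer(seed), out_dir = out_dir,
                        synth = synth, segmentation = segmentation,
                        features = features, similarity = similarity,
                        novelty = novelty, sequence = sequence, wav = wav),
                   class = "run_config")
  cfg
}

#' Hash of a run configuration
#'
#' MD5 of the deparsed configuration; recorded in every report so any result
#' is traceable to the exact parameter set that produced it.
#' @param config a [run_config()].
#' @return character MD5 hash.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  writeLines(deparse(unclass(config)), tf)
  unname(tools::md5sum(tf))
}

#' Serialise a run configuration to YAML, and back
#'
#' Only plain parameters are serialised (custom `synth$setup` archetype
#' lists are not); a configuration built from defaults and scalar overrides
#' round-trips unchanged.
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `path` (write); a [run_config()] (read).
#' @export
run_config_write <- function(config, path) {
  plain <- unclass(config)
  plain$segmentation <- unclass(plain$segmentation)
  plain$synth$setup <- NULL
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname run_config_write
#' @export
run_config_read <- function(path) {
  plain <- yaml::read_yaml(path)
  seg <- do.call(segmentation_params, plain$segmentation)
  run_config(mode = plain$mode, seed = plain$seed, out_dir = plain$out_dir,
             synth = plain$synth, segmentation = seg,
             features = plain$features, similarity = plain$similarity,
             novelty = plain$novelty, sequence = plain$sequence,
             wav = plain$wav %||% list())
}

#' Read syllable annotations from CSV
#'
#' Expects header `onset_s,offset_s,label`; extra columns are kept. Rows are
#' validated (numeric onset/offset, offset > onset); a malformed row is
#' rejected with its line number. Bout membership is inferred from silent
#' gaps longer than `bout_gap_s`.
#'
#' @param path CSV path.
#' @param bout_gap_s gap threshold separating bouts (default 2 s).
#' @return data.frame with the input columns plus `bout`.
#' @export
read_annotations <- function(path, bout_gap_s = 2) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("onset_s", "offset_s", "label")
  if (!all(need %in% names(ann))) {
    stop("annotation file ", path, " must have columns ",
         paste(need, collapse = ","), call. = FALSE)
  }
  if (nrow(ann)) {
    bad <- which(!is.finite(ann$onset_s) | !is.finite(ann$offset_s) |
                   ann$offset_s <= ann$onset_s)
    if (length(bad)) {
      stop("malformed annotation at line ", bad[1] + 1L, " of ", path,
           " (offset must exceed onset)", call. = FALSE)
    }
  }
  ann <- ann[order(ann$onset_s), , drop = FALSE]
  if (nrow(ann)) {
    gap <- c(0, ann$onset_s[-1] - ann$offset_s[-nrow(ann)])
    ann$bout <- cumsum(gap > bout_gap_s) + 1L
  } else {
    ann$bout <- integer(0)
  }
  rownames(ann) <- NULL
  ann
}

# Segment, label and featurise one epoch. Returns list(segments, tracks,
# bouts) where tracks is label -> list of feature_tracks and bouts is a list
# of label vectors.
process_epoch <- function(waves, truth, config, epoch) {
  seg_all <- list()
  tracks <- list()
  bouts <- list()
  ft <- config$features
  for (b in seq_along(waves)) {
    segs <- segment_syllables(waves[[b]], config$segmentation)
    tb <- truth[truth$bout == b, , drop = FALSE]
    segs <- label_segments(segs, tb)
    segs$bout <- if (nrow(segs)) b else integer(0)
    keep_lab <- !is.na(segs$label)
    bouts[[b]] <- segs$label[keep_lab]
    for (i in which(keep_lab)) {
      if ((segs$offset_s[i] - segs$onset_s[i]) * 1000 < ft$frame_ms + 2 * ft$hop_ms) next
      tr <- extract_features(waves[[b]], segs[i, ], frame_ms = ft$frame_ms,
                             hop_ms = ft$hop_ms, band = ft$band,
                             id = sprintf("%s_b%03d_%s_%d", epoch, b, segs$label[i], i))
      if (nrow(tr$frames) < 2L) next
      lab <- segs$label[i]
      tracks[[lab]] <- c(tracks[[lab]], list(tr))
    }
    seg_all[[b]] <- segs
  }
  list(segments = do.call(rbind, seg_all), tracks = tracks, bouts = bouts)
}

#' Run the full analysis pipeline
#'
#' Executes synthesis (or WAV input), segmentation, labelling, feature
#' extraction, similarity scoring, 1.96-sigma novelty classification, the
#' embedding/clustering cross-check, and sequence statistics, for a
#' baseline and a final epoch. Deterministic given the config seed in
#' synthetic mode. If `config$out_dir` is set, intermediates and the report
#' are written there via [write_report()].
#'
#' @param config a [run_config()].
#' @return a list of class `run_report`; key fields: `new_syllable_count`
#'   (feature route), `n_new_clusters` (cluster route), `verdicts`,
#'   `self_stats`, `cross_means`, `sequence` (per-epoch linearity,
#'   consistency), `position_histogram`, `transition` (per-epoch matrices),
#'   `ecd` (self/cross score ECDs), `config_hash`, `version`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  if (config$mode == "synthetic") {
    setup <- config$synth$setup %||% finch_study_setup(n_novel = config$synth$n_novel)
    corpora <- list(
      baseline = synth_corpus(setup$archetypes, setup$grammar, setup$jitter,
                              novelty = NULL, n_bouts = config$synth$n_bouts,
                              sr = config$synth$sr,
                              noise_floor_db = config$synth$noise_floor_db,
                              epoch = "baseline",
                              seed = derive_seed(config$seed, 1L)),
      final = synth_corpus(setup$archetypes, setup$grammar, setup$jitter,
                           novelty = setup$novelty,
                           n_bouts = config$synth$n_bouts,
                           sr = config$synth$sr,
                           noise_floor_db = config$synth$noise_floor_db,
                           epoch = "final",
                           seed = derive_seed(config$seed, 2L)))
    core_motif <- setup$grammar$core_motif
    intro_label <- setup$grammar$intro_label
  } else {
    corpora <- lapply(c(baseline = "baseline", final = "final"), function(ep) {
      blk <- config$wav[[ep]]
      ann <- read_annotations(blk$annotations, config$sequence$bout_gap_s)
      waves <- lapply(blk$wav, wav_read)
      if (!"bout" %in% names(ann) || max(ann$bout) > length(waves)) {
        ann$bout <- pmin(ann$bout, length(waves))
      }
      list(waves = waves, truth = cbind(ann, epoch = ep))
    })
    core_motif <- config$wav$core_motif %||%
      stop("wav mode requires wav$core_motif for sequence analysis", call. = FALSE)
    intro_label <- config$sequence$intro_label
  }

  eps <- lapply(c(baseline = "baseline", final = "final"), function(ep) {
    process_epoch(corpora[[ep]]$waves, corpora[[ep]]$truth, config, ep)
  })

  # --- similarity scoring ----------------------------------------------
  base_tracks <- eps$baseline$tracks
  final_tracks <- eps$final$tracks
  scaling <- estimate_scaling(unlist(base_tracks, recursive = FALSE),
                              seed = derive_seed(config$seed, 3L))
  nmax <- config$similarity$n_max
  q <- config$similarity$q
  usable <- names(base_tracks)[vapply(base_tracks, length, integer(1)) >= 2L]
  self_stats <- lapply(stats::setNames(usable, usable), function(lab) {
    self_similarity(base_tracks[[lab]], scaling, n_max = nmax, label = lab, q = q)
  })

  cross <- cross_similarity(final_tracks, base_tracks[usable], scaling,
                            n_max = nmax, q = q)
  cmeans <- cross_similarity_means(cross)

  crit <- novelty_criterion(z = config$novelty$z, mode = config$novelty$mode,
                            min_std = config$novelty$min_std)
  verdicts <- lapply(names(final_tracks), function(cand) {
    cm <- cmeans[cmeans$type_a == cand, ]
    classify_novel(cand, self_stats,
                   stats::setNames(cm$mean, cm$type_b), crit)
  })
  names(verdicts) <- names(final_tracks)
  novel_labels <- names(verdicts)[vapply(verdicts, `[[`, logical(1), "is_novel")]

  # --- clustering cross-check ------------------------------------------
  all_tracks <- c(unlist(base_tracks, recursive = FALSE),
                  unlist(final_tracks, recursive = FALSE))
  epochs_vec <- c(rep("baseline", length(unlist(base_tracks, recursive = FALSE))),
                  rep("final", length(unlist(final_tracks, recursive = FALSE))))
  vecs <- t(vapply(all_tracks, syllable_summary_vector, numeric(13)))
  clusters <- embed_and_cluster(vecs, epochs_vec,
                                min_cluster_size = config$novelty$min_cluster_size,
                                min_pts = config$novelty$min_pts,
                                new_fraction = config$novelty$new_fraction,
                                refine_iter = config$novelty$refine_iter,
                                seed = derive_seed(config$seed, 4L))

  # --- sequence statistics ---------------------------------------------
  seq_stats <- lapply(eps, function(e) {
    list(linearity = sequence_linearity(e$bouts,
                                        include_intro = config$sequence$include_intro,
                                        intro_label = intro_label),
         consistency = sequence_consistency(e$bouts,
                                            include_intro = config$sequence$include_intro,
                                            intro_label = intro_label),
         n_bouts = length(e$bouts))
  })
  transition <- lapply(eps, function(e) {
    transition_matrix(e$bouts, include_intro = config$sequence$include_intro,
                      intro_label = intro_label)
  })
  hist_labels <- setdiff(novel_labels, core_motif)
  if (length(hist_labels) < length(novel_labels)) {
    warning("novel verdict on a core-motif label; excluded from the position histogram",
            call. = FALSE)
  }
  pos_hist <- if (length(hist_labels)) {
    novel_position_histogram(eps$final$bouts, hist_labels, core_motif,
                             intro_label = intro_label)
  } else NULL

  # --- ECD curves -------------------------------------------------------
  self_scores <- unlist(lapply(self_stats, `[[`, "scores"))
  novel_cross <- cross$score[cross$type_a %in% novel_labels]
  ecd <- list(
    self = if (length(self_scores) >= 5)
      ecd_with_ci(self_scores, config$similarity$n_bootstrap,
                  seed = derive_seed(config$seed, 5L)) else NULL,
    novel_cross = if (length(novel_cross) >= 5)
      ecd_with_ci(novel_cross, config$similarity$n_bootstrap,
                  seed = derive_seed(config$seed, 6L)) else NULL)

  report <- structure(list(
    new_syllable_count = length(novel_labels),
    novel_labels = novel_labels,
    n_new_clusters = clusters$n_new_clusters,
    verdicts = verdicts,
    self_stats = self_stats,
    cross_means = cmeans,
    cross_scores = cross,
    clusters = clusters,
    sequence = seq_stats,
    transition = transition,
    position_histogram = pos_hist,
    ecd = ecd,
    segments = lapply(eps, function(e) e$segments),
    bouts = lapply(eps, function(e) e$bouts),
    n_segments = vapply(eps, function(e) nrow(e$segments), integer(1)),
    config_hash = config_hash(config),
    version = as.character(utils::packageVersion("finchsong"))),
    class = "run_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  segments: baseline %d, final %d\n",
              x$n_segments[["baseline"]], x$n_segments[["final"]]))
  cat(sprintf("  new syllables (feature route): %d [%s]\n",
              x$new_syllable_count, paste(x$novel_labels, collapse = ",")))
  cat(sprintf("  new clusters  (cluster route): %d\n", x$n_new_clusters))
  for (ep in names(x$sequence)) {
    cat(sprintf("  %s: linearity %.3f, consistency %.3f (%d bouts)\n", ep,
                x$sequence[[ep]]$linearity, x$sequence[[ep]]$consistency,
                x$sequence[[ep]]$n_bouts))
  }
  invisible(x)
}

#' Write a run report and its intermediates to disk
#'
#' Writes `report.json` (counts, verdict margins, sequence statistics,
#' position histogram, config hash) plus CSV intermediates: per-epoch
#' segments, the cross-similarity score table, the cluster table, per-epoch
#' transition matrices, and ECD curves, so every number in the JSON is
#' traceable to an artifact on disk.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ep in names(report$segments)) {
    segments_write(report$segments[[ep]],
                   file.path(dir, paste0("segments_", ep, ".csv")))
    transition_matrix_write(report$transition[[ep]],
                            file.path(dir, paste0("transitions_", ep, ".csv")))
  }
  utils::write.csv(report$cross_scores, file.path(dir, "cross_scores.csv"),
                   row.names = FALSE)
  cluster_table_write(report$clusters, file.path(dir, "clusters.csv"))
  for (nm in names(report$ecd)) {
    if (!is.null(report$ecd[[nm]])) {
      utils::write.csv(report$ecd[[nm]], file.path(dir, paste0("ecd_", nm, ".csv")),
                       row.names = FALSE)
    }
  }
  js <- list(
    new_syllable_count = report$new_syllable_count,
    novel_labels = report$novel_labels,
    n_new_clusters = report$n_new_clusters,
    verdicts = lapply(report$verdicts, function(v) {
      list(candidate = v$candidate, is_novel = v$is_novel,
           margins = as.list(v$margins))
    }),
    self_stats = lapply(report$self_stats, function(s) {
      list(label = s$label, mean = s$mean, std = s$std, n_pairs = s$n_pairs)
    }),
    sequence = report$sequence,
    position_histogram = if (!is.null(report$position_histogram)) {
      list(bins = report$position_histogram$bins,
           prob = report$position_histogram$prob,
           n_occurrences = report$position_histogram$n_occurrences,
           n_skipped = report$position_histogram$n_skipped)
    },
    n_segments = as.list(report$n_segments),
    config_hash = report$config_hash,
    version = report$version)
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
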