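#' Segmentation parameters
#'
#' Controls amplitude-threshold syllable detection. The default automated
#' threshold tracks the noise floor: the envelope's 20th percentile plus
#' 10 dB. A fixed absolute threshold (dBFS) is available for reproducibility.
#' Runs shorter than `min_syllable_ms` (default 5 ms, the minimum syllable
#' length used for segmentation in the study) are discarded; silent gaps
#' shorter than `min_gap_ms` are merged so within-syllable amplitude dips do
#' not split syllables (zebra finch inter-syllable gaps are ~50 ms).
#'
#' @param frame_ms,hop_ms RMS analysis frame and hop in ms (`frame >= hop > 0`).
#' @param threshold_mode `"percentile"` or `"fixed_db"`.
#' @param threshold_value percentile in (0, 100) for `"percentile"` mode, or
#'   an absolute dBFS threshold for `"fixed_db"` mode.
#' @param offset_db dB added above the percentile (percentile mode only).
#' @param min_syllable_ms minimum syllable duration in ms.
#' @param min_gap_ms gaps shorter than this are merged, in ms.
#' @param refine logical; refine boundaries with 1 ms fine frames so the
#'   duration filter operates on near-true event durations.
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(frame_ms = 5, hop_ms = 1,
                                threshold_mode = c("percentile", "fixed_db"),
                                threshold_value = 20, offset_db = 10,
                                min_syllable_ms = 5, min_gap_ms = 5,
                                refine = TRUE) {
  threshold_mode <- match.arg(threshold_mode)
  stopifnot_scalar(frame_ms, "frame_ms", lo = 1e-3)
  stopifnot_scalar(hop_ms, "hop_ms", lo = 1e-3, hi = frame_ms)
  stopifnot_scalar(min_syllable_ms, "min_syllable_ms", lo = 0)
  stopifnot_scalar(min_gap_ms, "min_gap_ms", lo = 0)
  if (threshold_mode == "percentile") {
    stopifnot_scalar(threshold_value, "threshold_value", lo = 0, hi = 100)
  }
  structure(list(frame_ms = frame_ms, hop_ms = hop_ms,
                 threshold_mode = threshold_mode,
                 threshold_value = threshold_value, offset_db = offset_db,
                 min_syllable_ms = min_syllable_ms, min_gap_ms = min_gap_ms,
                 refine = isTRUE(refine)),
            class = "segmentation_params")
}

#' Compute an RMS amplitude envelope in dB full scale
#'
#' One value per hop; frame `k` covers samples
#' `[(k-1)*hop + 1, (k-1)*hop + frame]` and is stamped with its centre time.
#' Values are clamped at -120 dB.
#'
#' @param w a [waveform()] longer than one frame.
#' @param frame_ms,hop_ms frame and hop in ms.
#' @return a data.frame with columns `time_s` (frame centres) and `db`, with
#'   attributes `hop_s` and `frame_s`.
#' @export
compute_envelope <- function(w, frame_ms = 5, hop_ms = 1) {
  fr <- max(1L, round(frame_ms / 1000 * w$sr))
  hp <- max(1L, round(hop_ms / 1000 * w$sr))
  n <- length(w$samples)
  if (n < fr) stop("waveform shorter than one frame", call. = FALSE)
  n_frames <- (n - fr) %/% hp + 1L
  csum <- c(0, cumsum(w$samples^2))
  starts <- (seq_len(n_frames) - 1L) * hp
  rms <- sqrt((csum[starts + fr + 1L] - csum[starts + 1L]) / fr)
  db <- pmax(20 * log10(pmax(rms, 1e-12)), -120)
  out <- data.frame(time_s = (starts + (fr - 1) / 2) / w$sr, db = db)
  attr(out, "hop_s") <- hp / w$sr
  attr(out, "frame_s") <- fr / w$sr
  out
}

segment_threshold <- function(env_db, params) {
  if (params$threshold_mode == "percentile") {
    stats::quantile(env_db, params$threshold_value / 100, names = FALSE) +
      params$offset_db
  } else {
    params$threshold_value
  }
}

# Runs of TRUE in a logical vector -> matrix of (start, end) indices.
logical_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Detect syllable segments by amplitude threshold
#'
#' Finds maximal runs of the supra-threshold RMS envelope, merges silent gaps
#' shorter than `min_gap_ms`, refines onset/offset against a 1 ms fine
#' envelope (so boundary smearing by the analysis frame does not inflate
#' durations), and discards runs shorter than `min_syllable_ms`. Returns
#' sorted, non-overlapping segments with half-open `[onset, offset)` times in
#' seconds from waveform start. All-silent input yields zero rows.
#'
#' @param w a [waveform()].
#' @param params a [segmentation_params()].
#' @return data.frame with columns `onset_s`, `offset_s`, `label` (`NA` until
#'   labelled).
#' @export
segment_syllables <- function(w, params = segmentation_params()) {
  env <- compute_envelope(w, params$frame_ms, params$hop_ms)
  hop_s <- attr(env, "hop_s")
  frame_s <- attr(env, "frame_s")
  thr <- segment_threshold(env$db, params)
  supra <- env$db > thr
  empty <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      label = character(0), stringsAsFactors = FALSE)
  if (!any(supra)) return(empty)
  runs <- logical_runs(supra)
  # merge gaps shorter than min_gap_ms
  if (nrow(runs) > 1L) {
    keep <- list(runs[1L, ])
    for (i in 2L:nrow(runs)) {
      prev <- keep[[length(keep)]]
      gap_s <- (runs[i, "start"] - prev["end"] - 1L) * hop_s
      if (gap_s < params$min_gap_ms / 1000) {
        prev["end"] <- runs[i, "end"]
        keep[[length(keep)]] <- prev
      } else {
        keep[[length(keep) + 1L]] <- runs[i, ]
      }
    }
    runs <- do.call(rbind, keep)
  }
  onsets <- env$time_s[runs[, "start"]] - frame_s / 2
  offsets <- env$time_s[runs[, "end"]] + frame_s / 2
  if (params$refine && frame_s > 0.0015) {
    fine <- compute_envelope(w, frame_ms = 1, hop_ms = 0.25)
    fhop <- attr(fine, "hop_s")
    fsupra <- fine$db > thr
    for (i in seq_along(onsets)) {
      lo <- max(1L, floor(onsets[i] / fhop)); hi <- min(nrow(fine), ceiling(offsets[i] / fhop))
      idx <- lo:hi
      hit <- idx[fsupra[idx]]
      if (length(hit)) {
        onsets[i] <- fine$time_s[hit[1L]] - attr(fine, "frame_s") / 2
        offsets[i] <- fine$time_s[hit[length(hit)]] + attr(fine, "frame_s") / 2
      }
    }
  }
  onsets <- pmax(onsets, 0)
  offsets <- pmin(offsets, wave_duration(w))
  keep <- (offsets - onsets) >= params$min_syllable_ms / 1000
  out <- data.frame(onset_s = onsets[keep], offset_s = offsets[keep],
                    label = rep(NA_character_, sum(keep)),
                    stringsAsFactors = FALSE)
  out[order(out$onset_s), , drop = FALSE]
}

#' Label detected segments from ground-truth annotations
#'
#' Assigns to each detected segment the ground-truth label with maximal
#' temporal overlap; segments overlapping no annotation keep `NA`. This is
#' the synthetic-corpus stand-in for the study's manual/DAS labelling.
#'
#' @param segments data.frame from [segment_syllables()].
#' @param truth data.frame with `onset_s`, `offset_s`, `label` for the same
#'   bout.
#' @param min_overlap minimum overlap (fraction of segment duration) to
#'   accept a label.
#' @return `segments` with `label` filled in.
#' @export
label_segments <- function(segments, truth, min_overlap = 0.3) {
  if (nrow(segments) == 0L) return(segments)
  for (i in seq_len(nrow(segments))) {
    ov <- pmin(segments$offset_s[i], truth$offset_s) -
      pmax(segments$onset_s[i], truth$onset_s)
    j <- which.max(ov)
    if (length(j) && ov[j] > min_overlap * (segments$offset_s[i] - segments$onset_s[i])) {
      segments$label[i] <- truth$label[j]
    }
  }
  segments
}

#' Write segments as CSV or Audacity label track
#'
#' CSV columns `onset_s,offset_s,label`; the Audacity format is
#' tab-separated `onset<TAB>offset<TAB>label` for manual inspection.
#'
#' @param segments segment data.frame.
#' @param path output path.
#' @param format `"csv"` or `"audacity"`.
#' @return `path`, invisibly.
#' @export
segments_write <- function(segments, path, format = c("csv", "audacity")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(segments[, c("onset_s", "offset_s", "label")], path,
                     row.names = FALSE)
  } else {
    utils::write.table(segments[, c("onset_s", "offset_s", "label")], path,
                       sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}
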