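#' Define a syllable archetype
#'
#' An archetype is the idealised acoustic template of one syllable type.
#' Renditions are produced by [synth_syllable()] with per-rendition jitter.
#' Four kinds cover the element classes visible in zebra finch spectrograms:
#' harmonic stacks, frequency-modulated chirps, broadband noise bursts, and
#' short soft introductory notes (up-chirps).
#'
#' @param label short type label (e.g. `"A"`; `"i"` for introductory notes).
#' @param kind one of `"harmonic_stack"`, `"chirp"`, `"noise_burst"`,
#'   `"intro_note"`.
#' @param f0_start,f0_end fundamental frequency in Hz at syllable start/end
#'   (linearly interpolated). Ignored for `noise_burst`.
#' @param n_harmonics number of harmonics for harmonic kinds (>= 1).
#' @param noise_band `c(low, high)` Hz pass band for `noise_burst`, else `NULL`.
#' @param duration_ms nominal duration in ms (>= 5, the minimum syllable
#'   length used in segmentation).
#' @param amplitude linear peak gain in (0, 1].
#' @return an object of class `syllable_archetype`.
#' @export
syllable_archetype <- function(label, kind, f0_start = 1000, f0_end = f0_start,
                               n_harmonics = 1L, noise_band = NULL,
                               duration_ms = 100, amplitude = 0.8) {
  kind <- match.arg(kind, c("harmonic_stack", "chirp", "noise_burst", "intro_note"))
  stopifnot_scalar(duration_ms, "duration_ms", lo = 5)
  stopifnot_scalar(amplitude, "amplitude", lo = 1e-6, hi = 1)
  if (kind != "noise_burst") {
    stopifnot_scalar(f0_start, "f0_start", lo = 1)
    stopifnot_scalar(f0_end, "f0_end", lo = 1)
  }
  if (kind == "harmonic_stack" && n_harmonics < 1L) {
    stop("harmonic kinds need n_harmonics >= 1", call. = FALSE)
  }
  if (kind == "noise_burst") {
    if (is.null(noise_band) || length(noise_band) != 2L || noise_band[1] >= noise_band[2]) {
      stop("noise_burst needs noise_band = c(low, high) with low < high", call. = FALSE)
    }
  }
  structure(list(label = as.character(label), kind = kind,
                 f0_start = f0_start, f0_end = f0_end,
                 n_harmonics = as.integer(n_harmonics),
                 noise_band = noise_band,
                 duration_ms = duration_ms, amplitude = amplitude),
            class = "syllable_archetype")
}

#' Define rendition-to-rendition jitter
#'
#' Fractional coefficients of variation applied multiplicatively (Gaussian,
#' mean 1) to fundamental frequency, duration, and amplitude of each rendition.
#'
#' @param f0_cv,dur_cv,amp_cv coefficients of variation in `[0, 0.5]`.
#' @return an object of class `rendition_jitter`.
#' @export
rendition_jitter <- function(f0_cv = 0, dur_cv = 0, amp_cv = 0) {
  for (nm in c("f0_cv", "dur_cv", "amp_cv")) {
    stopifnot_scalar(get(nm), nm, lo = 0, hi = 0.5)
  }
  structure(list(f0_cv = f0_cv, dur_cv = dur_cv, amp_cv = amp_cv),
            class = "rendition_jitter")
}

add_jitter <- function(a, b) {
  rendition_jitter(min(0.5, a$f0_cv + b$f0_cv),
                   min(0.5, a$dur_cv + b$dur_cv),
                   min(0.5, a$amp_cv + b$amp_cv))
}

#' Define a song grammar
#'
#' The grammar encodes the stereotyped structure of an adult zebra finch bout:
#' a few soft introductory notes, then 1+ renditions of a fixed core motif
#' (4-7 syllables in the study population), syllables separated by short
#' silent gaps (~50 ms). `branch_prob` is the per-position probability of
#' deviating from the core sequence; the deviation implemented is an
#' immediate repetition of the current syllable (stuttering), a naturally
#' occurring zebra finch song variation.
#'
#' @param core_motif character vector of core syllable labels (non-empty).
#' @param intro_label label of the introductory note type.
#' @param intro_count_range integer `c(min, max)` introductory notes per bout.
#' @param motifs_per_bout_range integer `c(min, max)` motif renditions per bout.
#' @param gap_ms silent gap between syllables in ms (> 0; ~50 in zebra finch).
#' @param branch_prob probability in `[0, 1]` of deviating (repeating) at each
#'   core-motif position.
#' @return an object of class `song_grammar`.
#' @export
song_grammar <- function(core_motif, intro_label = "i",
                         intro_count_range = c(1L, 4L),
                         motifs_per_bout_range = c(2L, 4L),
                         gap_ms = 50, branch_prob = 0.1) {
  if (length(core_motif) < 1L) stop("core_motif must be non-empty", call. = FALSE)
  stopifnot_scalar(gap_ms, "gap_ms", lo = 1e-9)
  stopifnot_scalar(branch_prob, "branch_prob", lo = 0, hi = 1)
  stopifnot(length(intro_count_range) == 2L, intro_count_range[1] <= intro_count_range[2],
            length(motifs_per_bout_range) == 2L,
            motifs_per_bout_range[1] >= 1L,
            motifs_per_bout_range[1] <= motifs_per_bout_range[2])
  if (intro_label %in% core_motif) stop("intro_label must not be a core label", call. = FALSE)
  structure(list(core_motif = as.character(core_motif),
                 intro_label = as.character(intro_label),
                 intro_count_range = as.integer(intro_count_range),
                 motifs_per_bout_range = as.integer(motifs_per_bout_range),
                 gap_ms = gap_ms, branch_prob = branch_prob),
            class = "song_grammar")
}

#' Define a repertoire-expansion condition
#'
#' Describes the novel syllable types injected into the final-epoch song and
#' how they occur: after each completed motif rendition with probability
#' `occurrence_prob` (policy `"motif_end"`, the pattern reported for
#' manipulated birds) or at uniformly random sequence positions
#' (`"uniform"`). Novel renditions receive `extra_jitter` on top of the
#' corpus jitter, making them less similar across repetitions than
#' pre-existing syllables.
#'
#' @param novel_archetypes list of [syllable_archetype()]s with labels
#'   disjoint from the grammar's.
#' @param occurrence_prob probability in `[0, 1]` that a motif rendition is
#'   followed by one novel syllable.
#' @param position_policy `"motif_end"` or `"uniform"`.
#' @param extra_jitter [rendition_jitter()] added to the corpus jitter for
#'   novel renditions.
#' @return an object of class `novelty_spec`.
#' @export
novelty_spec <- function(novel_archetypes, occurrence_prob = 0.6,
                         position_policy = c("motif_end", "uniform"),
                         extra_jitter = rendition_jitter(0.02, 0.05, 0.10)) {
  position_policy <- match.arg(position_policy)
  stopifnot_scalar(occurrence_prob, "occurrence_prob", lo = 0, hi = 1)
  if (length(novel_archetypes) < 1L) stop("need >= 1 novel archetype", call. = FALSE)
  labs <- vapply(novel_archetypes, function(a) a$label, character(1))
  if (anyDuplicated(labs)) stop("novel labels must be unique", call. = FALSE)
  names(novel_archetypes) <- labs
  structure(list(novel_archetypes = novel_archetypes,
                 occurrence_prob = occurrence_prob,
                 position_policy = position_policy,
                 extra_jitter = extra_jitter),
            class = "novelty_spec")
}

raised_cosine_ramps <- function(n, sr, ramp_ms = 5) {
  ramp <- min(round(ramp_ms / 1000 * sr), floor(n / 5))
  env <- rep(1, n)
  if (ramp > 0) {
    up <- 0.5 * (1 - cos(pi * seq_len(ramp) / ramp))
    env[seq_len(ramp)] <- up
    env[n - ramp + seq_len(ramp)] <- rev(up)
  }
  env
}

# Deterministic synthesis core: no RNG except for noise_burst sample draws,
# which the caller must seed.
synth_core <- function(arche, sr, dur_factor = 1, f0_factor = 1, amp_factor = 1) {
  dur_s <- arche$duration_ms / 1000 * dur_factor
  n <- max(round(dur_s * sr), 8L)
  nyq <- sr / 2
  if (arche$kind == "noise_burst") {
    x <- stats::rnorm(n)
    nb <- pmin(arche$noise_band, nyq * 0.999)
    X <- stats::fft(x)
    freqs <- (seq_len(n) - 1) / n * sr
    freqs <- pmin(freqs, sr - freqs)           # two-sided spectrum
    X[freqs < nb[1] | freqs > nb[2]] <- 0
    x <- Re(stats::fft(X, inverse = TRUE)) / n
  } else {
    f0 <- seq(arche$f0_start, arche$f0_end, length.out = n) * f0_factor
    if (max(f0) >= nyq) {
      stop(sprintf("archetype '%s': f0 reaches %.0f Hz, at or above Nyquist (%.0f Hz)",
                   arche$label, max(f0), nyq), call. = FALSE)
    }
    phase <- 2 * pi * cumsum(f0) / sr
    if (arche$kind == "harmonic_stack") {
      x <- numeric(n)
      for (h in seq_len(arche$n_harmonics)) {
        if (h * max(f0) >= nyq) break         # harmonics above Nyquist omitted
        x <- x + sin(h * phase) / h
      }
    } else {                                  # chirp / intro_note
      x <- sin(phase)
    }
  }
  x <- x * raised_cosine_ramps(n, sr)
  peak <- max(abs(x))
  if (peak > 0) x <- x / peak
  x * min(1, arche$amplitude * amp_factor)
}

# Truncated multiplicative jitter factor: Gaussian around 1, floored so
# durations/amplitudes stay positive.
jitter_factor <- function(cv) {
  if (cv <= 0) return(1)
  max(0.2, stats::rnorm(1, 1, cv))
}

#' Synthesise one syllable rendition
#'
#' Applies multiplicative Gaussian jitter to duration, fundamental frequency
#' and amplitude, synthesises the archetype, and optionally adds white
#' Gaussian background noise at a fixed level below the syllable peak.
#' Deterministic given `seed`.
#'
#' @param archetype a [syllable_archetype()].
#' @param jitter a [rendition_jitter()]; all-zero for identical renditions.
#' @param noise_floor_db background noise level in dB relative to the syllable
#'   peak (negative; `-Inf` disables noise).
#' @param sr sampling rate in Hz.
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @return a [waveform()].
#' @export
synth_syllable <- function(archetype, jitter = rendition_jitter(),
                           noise_floor_db = -Inf, sr = 40000, seed = NULL) {
  run <- function() {
    x <- synth_core(archetype, sr,
                    dur_factor = jitter_factor(jitter$dur_cv),
                    f0_factor = jitter_factor(jitter$f0_cv),
                    amp_factor = jitter_factor(jitter$amp_cv))
    if (is.finite(noise_floor_db)) {
      x <- x + stats::rnorm(length(x), 0, max(abs(x)) * 10^(noise_floor_db / 20))
    }
    waveform(x, sr)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# One bout's label sequence. Returns a data.frame with columns
# label, is_novel, motif_end (flag: position is the last syllable of a
# completed core-motif rendition).
bout_label_sequence <- function(grammar, novelty = NULL) {
  n_intro <- sample(grammar$intro_count_range[1]:grammar$intro_count_range[2], 1L)
  n_motifs <- sample(grammar$motifs_per_bout_range[1]:grammar$motifs_per_bout_range[2], 1L)
  labels <- rep(grammar$intro_label, n_intro)
  is_novel <- rep(FALSE, n_intro)
  motif_end <- rep(FALSE, n_intro)
  novel_labels <- if (is.null(novelty)) character(0) else names(novelty$novel_archetypes)
  pending_uniform <- 0L
  for (m in seq_len(n_motifs)) {
    L <- length(grammar$core_motif)
    for (k in seq_along(grammar$core_motif)) {
      lab <- grammar$core_motif[k]
      reps <- 1L + (grammar$branch_prob > 0 && stats::runif(1) < grammar$branch_prob)
      labels <- c(labels, rep(lab, reps))
      is_novel <- c(is_novel, rep(FALSE, reps))
      me <- rep(FALSE, reps); me[reps] <- (k == L)
      motif_end <- c(motif_end, me)
    }
    if (!is.null(novelty) && stats::runif(1) < novelty$occurrence_prob) {
      nov <- sample(novel_labels, 1L)
      if (novelty$position_policy == "motif_end") {
        labels <- c(labels, nov)
        is_novel <- c(is_novel, TRUE)
        motif_end <- c(motif_end, FALSE)
      } else {
        pending_uniform <- pending_uniform + 1L
      }
    }
  }
  if (pending_uniform > 0L) {
    for (j in seq_len(pending_uniform)) {
      nov <- sample(novel_labels, 1L)
      pos <- sample(length(labels) + 1L, 1L)
      labels <- append(labels, nov, after = pos - 1L)
      is_novel <- append(is_novel, TRUE, after = pos - 1L)
      motif_end <- append(motif_end, FALSE, after = pos - 1L)
    }
  }
  data.frame(label = labels, is_novel = is_novel, motif_end = motif_end,
             stringsAsFactors = FALSE)
}

#' Simulate bout label sequences without audio
#'
#' Runs the grammar (and optional novelty condition) at the symbolic level
#' only, for sequence-statistics studies where synthesising and re-segmenting
#' audio adds nothing. Deterministic given `seed`.
#'
#' @inheritParams synth_corpus
#' @return a list of character vectors, one per bout, with attribute
#'   `"novel"` marking novel positions (list of logical vectors).
#' @export
simulate_bout_labels <- function(grammar, novelty = NULL, n_bouts, seed = 1L) {
  stopifnot_scalar(n_bouts, "n_bouts", lo = 1)
  with_seed(seed, {
    seqs <- lapply(seq_len(n_bouts), function(b) bout_label_sequence(grammar, novelty))
  })
  out <- lapply(seqs, function(d) d$label)
  attr(out, "novel") <- lapply(seqs, function(d) d$is_novel)
  out
}

#' Synthesise a multi-bout song corpus with ground-truth annotations
#'
#' Generates one waveform per bout following the grammar, with per-rendition
#' jitter, optional injected novel syllables, syllables separated by the
#' grammar gap, 100 ms of lead-in/out, bout peak normalised to 0.9 full
#' scale, and white Gaussian background noise at `noise_floor_db` below the
#' bout peak. Deterministic given `seed`.
#'
#' @param archetypes list of [syllable_archetype()]s covering every grammar
#'   label (named by label or labelled internally).
#' @param grammar a [song_grammar()].
#' @param jitter a [rendition_jitter()] applied to every rendition.
#' @param novelty a [novelty_spec()] or `NULL` for a baseline epoch.
#' @param n_bouts number of bouts (>= 1; the study analysed the first 50
#'   bouts of each recording epoch).
#' @param sr sampling rate in Hz (40 kHz in the study).
#' @param noise_floor_db background noise in dB below bout peak (`-Inf` for
#'   noise-free synthesis).
#' @param epoch epoch tag stored in the ground truth; defaults to
#'   `"baseline"` without novelty and `"final"` with it.
#' @param seed integer seed.
#' @return a list with `waves` (list of [waveform()]s), `truth` (data.frame:
#'   `bout, onset_s, offset_s, label, archetype, epoch`; times are within-bout
#'   seconds), and `sr`.
#' @export
synth_corpus <- function(archetypes, grammar, jitter = rendition_jitter(),
                         novelty = NULL, n_bouts = 50L, sr = 40000,
                         noise_floor_db = -40,
                         epoch = if (is.null(novelty)) "baseline" else "final",
                         seed = 1L) {
  stopifnot_scalar(n_bouts, "n_bouts", lo = 1)
  names(archetypes) <- vapply(archetypes, function(a) a$label, character(1))
  all_arche <- archetypes
  if (!is.null(novelty)) {
    overlap <- intersect(names(novelty$novel_archetypes),
                         c(grammar$core_motif, grammar$intro_label))
    if (length(overlap)) {
      stop("novel labels overlap grammar labels: ", paste(overlap, collapse = ", "),
           call. = FALSE)
    }
    all_arche <- c(all_arche, novelty$novel_archetypes)
  }
  missing <- setdiff(c(grammar$core_motif, grammar$intro_label), names(archetypes))
  if (length(missing)) {
    stop("no archetype for grammar label(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  gap_n <- round(grammar$gap_ms / 1000 * sr)
  pad_n <- round(0.1 * sr)
  with_seed(seed, {
    waves <- vector("list", n_bouts)
    truth <- vector("list", n_bouts)
    for (b in seq_len(n_bouts)) {
      seq_df <- bout_label_sequence(grammar, novelty)
      pieces <- vector("list", nrow(seq_df))
      onsets <- offsets <- numeric(nrow(seq_df))
      pos <- pad_n
      for (k in seq_len(nrow(seq_df))) {
        jit <- jitter
        if (seq_df$is_novel[k]) jit <- add_jitter(jitter, novelty$extra_jitter)
        x <- synth_core(all_arche[[seq_df$label[k]]], sr,
                        dur_factor = jitter_factor(jit$dur_cv),
                        f0_factor = jitter_factor(jit$f0_cv),
                        amp_factor = jitter_factor(jit$amp_cv))
        pieces[[k]] <- x
        onsets[k] <- pos / sr
        offsets[k] <- (pos + length(x)) / sr
        pos <- pos + length(x) + gap_n
      }
      total_n <- pos - gap_n + pad_n
      bout <- numeric(total_n)
      for (k in seq_len(nrow(seq_df))) {
        i0 <- round(onsets[k] * sr)
        bout[i0 + seq_along(pieces[[k]])] <- pieces[[k]]
      }
      peak <- max(abs(bout))
      if (peak > 0) bout <- bout * (0.9 / peak)
      if (is.finite(noise_floor_db)) {
        bout <- bout + stats::rnorm(total_n, 0, 0.9 * 10^(noise_floor_db / 20))
      }
      waves[[b]] <- waveform(bout, sr)
      truth[[b]] <- data.frame(bout = b, onset_s = onsets, offset_s = offsets,
                               label = seq_df$label,
                               archetype = seq_df$label, epoch = epoch,
                               stringsAsFactors = FALSE)
    }
    list(waves = waves, truth = do.call(rbind, truth), sr = sr)
  })
}

#' Write / read ground-truth annotations as CSV
#'
#' Plain CSV with header `bout,onset_s,offset_s,label,archetype,epoch`.
#'
#' @param truth ground-truth data.frame from [synth_corpus()].
#' @param path CSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
ground_truth_write <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname ground_truth_write
#' @export
ground_truth_read <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Default study conditions: archetypes, grammar, jitter, novelty
#'
#' One place that fixes the synthetic study conditions used throughout the
#' analyses: a 5-syllable core motif (the study population sang 4-7 syllable
#' motifs) of harmonic stacks and chirps, a soft introductory up-chirp, and
#' two novel broadband noise-burst types (labelled X and Y, after the novel
#' syllables of the example bird) appended at motif ends with elevated
#' rendition jitter.
#'
#' @param n_novel number of novel archetypes to include (0, 1 or 2).
#' @return list with elements `archetypes`, `grammar`, `jitter`, `novelty`
#'   (`NULL` when `n_novel = 0`).
#' @export
finch_study_setup <- function(n_novel = 2L) {
  stopifnot(n_novel %in% 0:2)
  archetypes <- list(
    syllable_archetype("i", "intro_note", 1500, 2600, duration_ms = 30, amplitude = 0.35),
    syllable_archetype("A", "harmonic_stack", 450, 450, n_harmonics = 8, duration_ms = 110),
    syllable_archetype("B", "chirp", 2200, 3900, duration_ms = 70),
    syllable_archetype("C", "harmonic_stack", 680, 520, n_harmonics = 6, duration_ms = 140),
    syllable_archetype("D", "chirp", 4600, 2500, duration_ms = 60),
    syllable_archetype("E", "harmonic_stack", 820, 820, n_harmonics = 5, duration_ms = 90)
  )
  grammar <- song_grammar(core_motif = c("A", "B", "C", "D", "E"))
  jitter <- rendition_jitter(f0_cv = 0.02, dur_cv = 0.05, amp_cv = 0.10)
  novel <- list(
    syllable_archetype("X", "noise_burst", noise_band = c(1000, 3000), duration_ms = 80),
    syllable_archetype("Y", "noise_burst", noise_band = c(4000, 7200), duration_ms = 120)
  )
  names(archetypes) <- vapply(archetypes, function(a) a$label, character(1))
  novelty <- if (n_novel > 0) novelty_spec(novel[seq_len(n_novel)]) else NULL
  list(archetypes = archetypes, grammar = grammar, jitter = jitter, novelty = novelty)
}
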