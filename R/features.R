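#' @name acoustic_features
#' @title Per-frame spectral features for syllable renditions
#'
#' @description
#' The similarity analyses operate on six per-frame features in the tradition
#' of feature-based song analysis (Sound Analysis Pro-style): pitch (dominant
#' cepstral peak), goodness of pitch (that peak's height), Wiener entropy
#' (log ratio of geometric to arithmetic mean of the band power spectrum;
#' 0 for white noise, strongly negative for pure tones), frequency
#' modulation (arctangent of the ratio of time- to frequency-derivative
#' norms of the spectrogram), amplitude modulation (time derivative of log
#' amplitude, 1/s), and amplitude (frame RMS in dB). Spectra use a single
#' Gaussian-windowed FFT per frame over a 300-8000 Hz analysis band.
NULL

FEATURE_NAMES <- c("pitch", "goodness", "wiener_entropy", "fm", "am", "amplitude")

gaussian_window <- function(n, sigma_frac = 1 / 6) {
  c0 <- (n - 1) / 2
  exp(-0.5 * ((seq_len(n) - 1 - c0) / (sigma_frac * n))^2)
}

#' Extract a feature track from a waveform
#'
#' @param w a [waveform()].
#' @param seg optional one-row segment (`onset_s`, `offset_s`) restricting
#'   analysis to one syllable; `NULL` analyses the whole waveform.
#' @param frame_ms analysis frame in ms (default 9.27 ms, 371 samples at
#'   40 kHz).
#' @param hop_ms hop in ms.
#' @param band analysis band in Hz, default `c(300, 8000)`.
#' @param id identity string stored in the track.
#' @return an object of class `feature_track`: list with `id`, `times`
#'   (frame centre times in seconds from waveform start) and `frames`
#'   (data.frame with one row per frame and the six feature columns).
#' @export
extract_features <- function(w, seg = NULL, frame_ms = 9.27, hop_ms = 1,
                             band = c(300, 8000), id = NA_character_) {
  x <- w$samples
  t0 <- 0
  if (!is.null(seg)) {
    i0 <- max(1L, floor(seg$onset_s[1] * w$sr) + 1L)
    i1 <- min(length(x), ceiling(seg$offset_s[1] * w$sr))
    x <- x[i0:i1]
    t0 <- (i0 - 1L) / w$sr
  }
  sr <- w$sr
  fr <- round(frame_ms / 1000 * sr)
  hp <- max(1L, round(hop_ms / 1000 * sr))
  if (length(x) < fr) stop("segment shorter than one analysis frame", call. = FALSE)
  n_frames <- (length(x) - fr) %/% hp + 1L
  starts <- (seq_len(n_frames) - 1L) * hp
  idx <- outer(seq_len(fr), starts, "+")
  frames_mat <- matrix(x[idx], nrow = fr)
  nfft <- 2^ceiling(log2(fr))
  win <- gaussian_window(fr)
  padded <- matrix(0, nrow = nfft, ncol = n_frames)
  padded[seq_len(fr), ] <- frames_mat * win
  spec <- stats::mvfft(padded)
  pow_full <- Mod(spec)^2 + 1e-30
  half <- nfft %/% 2 + 1L
  freqs <- (seq_len(half) - 1L) * sr / nfft
  in_band <- freqs >= band[1] & freqs <= band[2]
  pow_band <- pow_full[seq_len(half), , drop = FALSE][in_band, , drop = FALSE]

  # Wiener entropy: ln(geometric mean / arithmetic mean) of band power
  wiener <- colMeans(log(pow_band)) - log(colMeans(pow_band))

  # Cepstrum of the full log power spectrum, floored at -30 dB re the frame
  # peak: a deeper floor lets broadband spectral-envelope edges (band-edge
  # sinc lobes) swamp the harmonic-periodicity peak. The pitch is the
  # dominant *local* quefrency maximum in the pitch band -- the smooth
  # envelope decays monotonically in quefrency and must not be picked up.
  frame_max <- apply(pow_full, 2, max)
  lp <- log(pmax(pow_full, rep(frame_max * 1e-3, each = nfft)))
  ceps <- Re(stats::mvfft(lp, inverse = TRUE)) / nfft
  q_lo <- max(2L, ceiling(sr / band[2]))
  q_hi <- min(nfft %/% 2 - 1L, floor(sr / band[1]))
  qidx <- q_lo:q_hi
  ceps_q <- ceps[qidx + 1L, , drop = FALSE]        # row 1 is quefrency 0
  m <- nrow(ceps_q)
  is_lmax <- rbind(FALSE,
                   ceps_q[2:(m - 1), , drop = FALSE] >= ceps_q[1:(m - 2), , drop = FALSE] &
                   ceps_q[2:(m - 1), , drop = FALSE] >= ceps_q[3:m, , drop = FALSE],
                   FALSE)
  masked <- ifelse(is_lmax, ceps_q, -Inf)
  peak_rel <- max.col(t(masked))
  no_lmax <- colSums(is_lmax) == 0L
  if (any(no_lmax)) peak_rel[no_lmax] <- max.col(t(ceps_q[, no_lmax, drop = FALSE]))
  goodness <- ceps_q[cbind(peak_rel, seq_len(n_frames))]
  q_star <- qidx[peak_rel]
  # parabolic interpolation of the cepstral peak for sub-bin pitch
  can <- peak_rel > 1L & peak_rel < length(qidx)
  delta <- numeric(n_frames)
  if (any(can)) {
    i <- which(can)
    y0 <- ceps_q[cbind(peak_rel[i] - 1L, i)]
    y1 <- ceps_q[cbind(peak_rel[i], i)]
    y2 <- ceps_q[cbind(peak_rel[i] + 1L, i)]
    denom <- y0 - 2 * y1 + y2
    d <- ifelse(abs(denom) > 1e-12, 0.5 * (y0 - y2) / denom, 0)
    delta[i] <- pmax(-0.5, pmin(0.5, d))
  }
  pitch <- sr / (q_star + delta)

  # amplitude (unwindowed frame RMS, dBFS) and its log-derivative (AM, 1/s)
  rms <- sqrt(colMeans(frames_mat^2))
  amplitude <- pmax(20 * log10(pmax(rms, 1e-12)), -120)
  hop_s <- hp / sr
  lrms <- log(pmax(rms, 1e-12))
  am <- central_diff(lrms) / hop_s

  # FM: arctan of time-derivative norm over frequency-derivative norm of the
  # band spectrogram (central differences, one-sided at the edges)
  nb <- nrow(pow_band)
  dT <- if (n_frames > 2L) {
    cbind(pow_band[, 2L] - pow_band[, 1L],
          (pow_band[, 3:n_frames, drop = FALSE] -
             pow_band[, 1:(n_frames - 2L), drop = FALSE]) / 2,
          pow_band[, n_frames] - pow_band[, n_frames - 1L])
  } else if (n_frames == 2L) {
    cbind(pow_band[, 2L] - pow_band[, 1L], pow_band[, 2L] - pow_band[, 1L])
  } else matrix(0, nb, 1L)
  dF <- if (nb > 2L) {
    rbind(pow_band[2L, ] - pow_band[1L, ],
          (pow_band[3:nb, , drop = FALSE] -
             pow_band[1:(nb - 2L), , drop = FALSE]) / 2,
          pow_band[nb, ] - pow_band[nb - 1L, ])
  } else if (nb == 2L) {
    rbind(pow_band[2L, ] - pow_band[1L, ], pow_band[2L, ] - pow_band[1L, ])
  } else matrix(0, 1L, n_frames)
  fm <- atan(sqrt(colSums(dT^2)) / (sqrt(colSums(dF^2)) + 1e-30))

  frames <- data.frame(pitch = pitch, goodness = goodness,
                       wiener_entropy = wiener, fm = fm, am = am,
                       amplitude = amplitude)
  structure(list(id = id,
                 times = t0 + (starts + (fr - 1) / 2) / sr,
                 frames = frames),
            class = "feature_track")
}

central_diff <- function(v) {
  n <- length(v)
  if (n == 1L) return(0)
  d <- numeric(n)
  d[1] <- v[2] - v[1]
  d[n] <- v[n] - v[n - 1]
  if (n > 2L) d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / 2
  d
}

#' @export
print.feature_track <- function(x, ...) {
  cat(sprintf("<feature_track '%s': %d frames, %.1f-%.1f ms>\n",
              x$id, nrow(x$frames), 1000 * min(x$times), 1000 * max(x$times)))
  invisible(x)
}

#' Feature matrix of a track
#' @param track a `feature_track`.
#' @return numeric matrix, one row per frame, six feature columns.
#' @export
feature_matrix <- function(track) {
  as.matrix(track$frames[, FEATURE_NAMES])
}

#' Write a feature track to CSV
#'
#' One row per frame: `time_s` plus the six features, for inspection and
#' cross-language checks.
#' @param track a `feature_track`.
#' @param path CSV path.
#' @export
feature_track_write <- function(track, path) {
  utils::write.csv(cbind(time_s = track$times, track$frames), path,
                   row.names = FALSE)
  invisible(path)
}

#' Estimate robust per-feature scaling from a background corpus
#'
#' Heterogeneous feature units are made commensurable by robust
#' standardisation: per-feature median and MAD over all frames of the corpus
#' (MAD floored at a small epsilon). The same corpus supplies the background
#' distribution of frame-pair distances that calibrates the similarity
#' threshold, sampled here deterministically.
#'
#' @param tracks list of `feature_track`s with >= 100 frames in total.
#' @param n_background number of random frame pairs for the background
#'   distance sample.
#' @param seed integer seed for the background pair sample.
#' @return an object of class `feature_scaling`: `medians`, `mads`,
#'   `n_frames`, `bg_distances`.
#' @export
estimate_scaling <- function(tracks, n_background = 5000L, seed = 1L) {
  mats <- lapply(tracks, feature_matrix)
  all_frames <- do.call(rbind, mats)
  if (is.null(all_frames) || nrow(all_frames) < 100L) {
    stop("need >= 100 frames to estimate scaling", call. = FALSE)
  }
  medians <- apply(all_frames, 2, stats::median)
  # raw MAD (no Gaussian consistency constant): a unit-free robust scale;
  # the constant would rescale all features and the background distances
  # identically, leaving scores unchanged
  mads <- pmax(apply(all_frames, 2, stats::mad, constant = 1), 1e-6)
  scaled <- sweep(sweep(all_frames, 2, medians), 2, mads, "/")
  n <- nrow(scaled)
  bg <- with_seed(seed, {
    i <- sample.int(n, n_background, replace = TRUE)
    j <- sample.int(n, n_background, replace = TRUE)
    fix <- i == j
    if (any(fix)) j[fix] <- (j[fix] %% n) + 1L
    sqrt(rowSums((scaled[i, , drop = FALSE] - scaled[j, , drop = FALSE])^2))
  })
  structure(list(medians = medians, mads = mads, n_frames = n,
                 bg_distances = bg),
            class = "feature_scaling")
}

#' @export
print.feature_scaling <- function(x, ...) {
  cat(sprintf("<feature_scaling: %d frames, median background distance %.2f>\n",
              x$n_frames, stats::median(x$bg_distances)))
  invisible(x)
}

scale_frames <- function(mat, scaling) {
  sweep(sweep(mat, 2, scaling$medians), 2, scaling$mads, "/")
}
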