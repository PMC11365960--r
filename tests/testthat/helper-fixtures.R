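# Shared fixtures, built once per test run and cached.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, force(expr), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

# Feature tracks per type from jittered renditions of the default study
# archetypes (no corpus assembly/segmentation), plus a shared scaling.
# Returns list(tracks = label -> list of feature_track, scaling).
fx_rendition_tracks <- function(n_rend = 8L, seed = 420L) {
  cached(sprintf("rend_%d_%d", n_rend, seed), {
    setup <- finch_study_setup()
    arche <- c(setup$archetypes, setup$novelty$novel_archetypes)
    names(arche) <- vapply(arche, function(a) a$label, character(1))
    tracks <- lapply(arche, function(a) {
      lapply(seq_len(n_rend), function(i) {
        w <- synth_syllable(a, setup$jitter, noise_floor_db = -40,
                            seed = derive_fixture_seed(seed, a$label, i))
        extract_features(w, id = paste0(a$label, i))
      })
    })
    scaling <- estimate_scaling(unlist(tracks, recursive = FALSE), seed = seed)
    list(tracks = tracks, scaling = scaling)
  })
}

derive_fixture_seed <- function(seed, label, i) {
  as.integer((seed * 131L + utf8ToInt(substr(label, 1, 1)) * 17L + i) %% .Machine$integer.max)
}

# Identical (zero-jitter, noise-free) renditions of one harmonic archetype.
fx_zero_jitter_tracks <- function(n_rend = 10L) {
  cached(sprintf("zj_%d", n_rend), {
    a <- syllable_archetype("Z", "harmonic_stack", 600, 600, n_harmonics = 3,
                            duration_ms = 120)
    w <- synth_syllable(a, seed = 99L)
    lapply(seq_len(n_rend), function(i) extract_features(w, id = paste0("Z", i)))
  })
}

# Brute-force oracles for the sequence statistics: explicit enumeration with
# nested loops, independent of the package's vectorised implementations.
oracle_linearity <- function(bouts) {
  notes <- character(0)
  pairs <- character(0)
  for (b in bouts) {
    for (k in seq_along(b)) {
      if (!(b[k] %in% notes)) notes <- c(notes, b[k])
      if (k < length(b)) {
        pr <- paste(b[k], b[k + 1], sep = "\r")
        if (!(pr %in% pairs)) pairs <- c(pairs, pr)
      }
    }
  }
  length(notes) / length(pairs)
}

oracle_consistency <- function(bouts) {
  counts <- new.env(parent = emptyenv())   # source -> successor counts
  order_seen <- new.env(parent = emptyenv())
  total <- 0L
  for (b in bouts) {
    if (length(b) < 2L) next
    for (k in seq_len(length(b) - 1L)) {
      src <- b[k]; dst <- b[k + 1]
      total <- total + 1L
      if (!exists(src, envir = counts)) {
        assign(src, integer(0), envir = counts)
        assign(src, character(0), envir = order_seen)
      }
      cc <- get(src, envir = counts)
      oo <- get(src, envir = order_seen)
      if (!(dst %in% oo)) {
        oo <- c(oo, dst); cc <- c(cc, 0L)
        assign(src, oo, envir = order_seen)
      }
      cc[match(dst, oo)] <- cc[match(dst, oo)] + 1L
      assign(src, cc, envir = counts)
    }
  }
  typical <- 0L
  for (src in ls(counts)) {
    cc <- get(src, envir = counts)
    typical <- typical + max(cc)           # ties: earliest-observed wins,
  }                                        # max() takes the first maximum
  typical / total
}

random_bouts <- function(n_bouts, alphabet_size = 8L, max_len = 60L) {
  alpha <- LETTERS[seq_len(alphabet_size)]
  lapply(seq_len(n_bouts), function(i) {
    sample(alpha, sample(2:max_len, 1L), replace = TRUE)
  })
}
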