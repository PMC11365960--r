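#!/usr/bin/env Rscript

# Step 1: simulate the study's two recording epochs.
#
# Generates a baseline corpus (stereotyped 5-syllable motif, introductory
# notes, stutter-type branching) and a final corpus in which two acoustically
# novel noise-burst syllable types (X, Y) are appended after motif ends, the
# condition under which manipulated birds expanded their repertoires.
# Audio goes to scratch/ (regenerated on demand); ground-truth annotation
# tables and a bout summary go to results/.

suppressPackageStartupMessages(library(finchsong))

seed <- 1L
n_bouts <- 50L

setup <- finch_study_setup(n_novel = 2L)
dir.create("results", showWarnings = FALSE)
dir.create("scratch/audio", showWarnings = FALSE, recursive = TRUE)

corpora <- list(
  baseline = synth_corpus(setup$archetypes, setup$grammar, setup$jitter,
                          novelty = NULL, n_bouts = n_bouts, seed = seed),
  final = synth_corpus(setup$archetypes, setup$grammar, setup$jitter,
                       novelty = setup$novelty, n_bouts = n_bouts,
                       seed = seed + 1L))

for (ep in names(corpora)) {
  co <- corpora[[ep]]
  ground_truth_write(co$truth, file.path("results", paste0("truth_", ep, ".csv")))
  for (b in seq_along(co$waves)) {
    wav_write(co$waves[[b]], sprintf("scratch/audio/%s_bout%03d.wav", ep, b))
  }
  n_nov <- sum(co$truth$label %in% names(setup$novelty$novel_archetypes))
  cat(sprintf("%-8s: %d bouts, %d syllables (%d novel), %.1f s audio\n",
              ep, n_bouts, nrow(co$truth), n_nov,
              sum(vapply(co$waves, wave_duration, numeric(1)))))
}
cat("wrote results/truth_{baseline,final}.csv and scratch/audio/*.wav\n")
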