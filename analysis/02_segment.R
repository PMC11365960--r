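#!/usr/bin/env Rscript

# Step 2: amplitude-threshold segmentation against ground truth.
#
# Re-reads the WAV corpora written by 01_simulate.R, segments every bout with
# the automated percentile threshold and the 5 ms minimum-duration filter,
# and quantifies boundary recovery against the simulator's annotations.

suppressPackageStartupMessages(library(finchsong))

params <- segmentation_params()
for (ep in c("baseline", "final")) {
  truth <- ground_truth_read(file.path("results", paste0("truth_", ep, ".csv")))
  files <- sort(Sys.glob(sprintf("scratch/audio/%s_bout*.wav", ep)))
  stopifnot(length(files) > 0)
  all_segs <- list()
  err <- c()
  for (b in seq_along(files)) {
    w <- wav_read(files[b])
    segs <- segment_syllables(w, params)
    tb <- truth[truth$bout == b, ]
    segs <- label_segments(segs, tb)
    segs$bout <- b
    all_segs[[b]] <- segs
    if (nrow(segs) == nrow(tb)) {
      err <- c(err, abs(segs$onset_s - tb$onset_s),
               abs(segs$offset_s - tb$offset_s))
    }
  }
  segs <- do.call(rbind, all_segs)
  segments_write(segs, file.path("results", paste0("segments_", ep, ".csv")))
  cat(sprintf("%-8s: %d segments vs %d annotated; boundary error median %.2f ms, max %.2f ms\n",
              ep, nrow(segs), nrow(truth), 1000 * median(err), 1000 * max(err)))
}
cat("wrote results/segments_{baseline,final}.csv\n")
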