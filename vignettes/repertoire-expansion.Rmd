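---
title: "Detecting vocal repertoire expansion in adult zebra finch song"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting vocal repertoire expansion in adult zebra finch song}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finchsong)
```

## The question and the measurement problem

Adult zebra finch song is crystallised: a bird repeats a stereotyped motif of
4–7 syllables, preceded by a few soft introductory notes, with ~50 ms silent
gaps between syllables. Experimental manipulations of the song system can
cause adult birds to *add* syllable types to this otherwise fixed repertoire.
`finchsong` implements the measurement side of that phenomenon: given
recordings from a baseline epoch and a later ("final") epoch, decide which
syllable types in the final epoch are novel, count them, and characterise how
the additions change song syntax.

Two independent routes answer the "which types are novel" question:

1. **Feature route.** Syllable renditions are compared by a percent
   similarity score built on per-frame spectral features. For every
   pre-existing type $p$ we compute its *self-similarity* distribution (all
   pairwise scores among up to 10 renditions, summarised as mean $\mu_p$ and
   standard deviation $\sigma_p$). A candidate type $c$ is **novel** iff for
   every pre-existing type $p$
   $$\overline{\mathrm{cross}}(c, p) < \mu_p - z\,\sigma_p, \qquad z = 1.96.$$
   The criterion is applied one-sided below: novelty means *lower*
   similarity. Because the threshold $\mu_p - z\sigma_p$ falls as $z$ grows,
   a larger $z$ is a stricter criterion; verdicts are monotone
   (non-increasing) in $z$.
2. **Cluster route.** Every syllable rendition from both epochs is summarised
   by a fixed-length vector (mean and SD of each of six features plus
   duration, 13 values, z-scored), clustered by hierarchical density-based
   clustering, and a cluster counts as *new* when at least 95% of its members
   come from the final epoch. The two routes use disjoint machinery, so their
   agreement is an internal replication.

Sequence structure is quantified by within-bout transition matrices and two
classical stereotypy ratios, pooled over the analysed bout set:

$$\text{sequence linearity} =
  \frac{\#\,\text{different notes per song}}{\#\,\text{transition types per song}},
\qquad
\text{sequence consistency} =
  \frac{\sum \text{typical transitions per song}}{\sum \text{total transitions per song}},$$

where the *typical* transition of a source label is its modal successor.
Both equal 1 for a perfectly linear / perfectly consistent song. Where novel
syllables enter the song is summarised by a relative-position histogram:
bin 0 means immediately after the last syllable of a completed core motif,
negative bins fall inside the motif.

## The synthetic corpus: what it emulates and what it does not

The recordings behind the original study are not publicly deposited, so the
package ships a generative stand-in that defines the study conditions for
every test. A `song_grammar()` emits bouts of 1–4 introductory notes followed
by 2–4 renditions of a five-syllable core motif (`A`–`E`: harmonic stacks and
frequency chirps spanning the zebra finch range), syllables separated by
50 ms gaps, sampled at 40 kHz, with white background noise 40 dB below the
bout peak. Rendition-to-rendition variability is multiplicative Gaussian
jitter on duration (CV 0.05), fundamental frequency (CV 0.02) and amplitude
(CV 0.10). The repertoire-expansion condition (`novelty_spec()`) appends one
of two broadband noise-burst types (`X`, `Y`) after a motif rendition with
probability 0.6, with doubled jitter — novel syllables are both acoustically
unlike anything in the baseline repertoire and less stereotyped across
renditions, the two properties reported for real novel syllables.

Several generator choices deserve justification:

* **Branching is stuttering.** The grammar's `branch_prob` (default 0.1) is
  the per-position probability of *repeating* the current syllable rather
  than jumping to a random one. Syllable repetition is a naturally occurring
  zebra finch song variation, and it has a structural consequence we want
  the simulator to reproduce: with a five-note motif the baseline song
  exposes ten transition types (four within-motif, the motif restart, five
  self-transitions), i.e. linearity 5/10, and appending two novel types at
  motif ends adds two notes and four transition types (`E→X`, `E→Y`, `X→A`,
  `Y→A`), i.e. linearity 7/14. Linearity is therefore *structurally stable*
  under end-appended novelty while consistency necessarily drops (the
  `E→novel` transitions are atypical) — the qualitative signature reported
  for real birds, which a random-jump branching model would not reproduce.
* **Jitter magnitudes are free parameters.** The study does not quantify
  rendition-to-rendition acoustic jitter; the defaults above were chosen
  once so that zero-jitter self-similarity is exactly 100 and jittered
  self-similarity sits in the high-80s/90s, qualitatively matching the
  reported self-similarity ranges. They are exposed in
  `rendition_jitter()` and never tuned per analysis.
* **Occurrence probability 0.6** makes each novel type appear ~45 times in a
  50-bout epoch, safely above the clustering minimum cluster size (25) while
  remaining a minority of motif renditions. Sequence-level analyses that
  specifically need *rare* novelty use `occurrence_prob = 0.3` explicitly.
* **What is not emulated:** call repertoires beyond generic archetypes,
  biomechanically realistic syringeal synthesis, amplitude-dependent room
  acoustics, overlapping singers, and drift of pre-existing syllables.
  Passing the recovery tests therefore shows the pipeline is correct under
  its stated acoustic model, not that it is robust to every property of
  real recordings.

## Segmentation

Syllables are detected from an RMS amplitude envelope (5 ms frames, 1 ms
hop, dB full scale, clamped at −120 dB). The study reports only "automated
thresholds"; the default rule here tracks the noise floor: threshold =
envelope's 20th percentile + 10 dB. A `fixed_db` mode takes an absolute dBFS
threshold for exact reproducibility. Supra-threshold runs are merged across
gaps shorter than 5 ms (well below the ~50 ms syllable gap, so within-syllable
amplitude dips do not split syllables) and runs shorter than the 5 ms minimum
syllable length are discarded.

One numerical subtlety: with 5 ms analysis frames, a boundary is smeared by
up to half a frame on each side, so a 3 ms transient would *appear* ~7 ms
long and would wrongly survive the 5 ms duration filter. Detected runs are
therefore refined against a 1 ms fine envelope (0.25 ms hop) before the
duration filter, which brings boundary error to well under 5 ms at the 40 dB
SNR of the study conditions and restores the intended semantics of the
minimum-duration rule.

## Spectral features

Six per-frame features in the Sound Analysis Pro tradition drive similarity
scoring: pitch (dominant cepstral quefrency peak in 300–8000 Hz, parabolic
sub-bin interpolation), goodness of pitch (that peak's height), Wiener
entropy ($\ln$ geometric/arithmetic mean of the band power spectrum, ≤ 0,
near 0 for noise and strongly negative for tones), frequency modulation
(arctangent of the time- to frequency-derivative norm ratio of the
spectrogram), amplitude modulation (time derivative of log amplitude, 1/s)
and amplitude (frame RMS, dBFS). Frames are 9.27 ms (371 samples at 40 kHz)
with a 1 ms hop and a single Gaussian window — a deliberate simplification
of SAP's multitaper spectra; exact numerical parity with SAP2011 is a
non-goal, and only relative comparisons are treated as reproducible.

Numerical choices: the power spectrum is floored at −30 dB relative to the
frame peak before the cepstrum is taken (a deeper floor lets band-edge
envelope lobes swamp the periodicity peak), and the pitch picker takes the
dominant *local* cepstral maximum because the smooth spectral envelope
decays monotonically in quefrency. Unvoiced frames keep their cepstral pitch
estimate rather than being masked, avoiding missing-data logic downstream.

## Similarity scoring

Comparisons are conducted symmetrically across the time course of each pair:
both feature tracks are linearly rescaled to a common length (the rounded
mean of the two frame counts — deliberately *not* dynamic time warping, the
simplest contract consistent with symmetric time-course comparison), frames
are standardised by per-feature median and raw MAD estimated on a background
corpus (MAD floored at $10^{-6}$; all six features weighted equally), and a
frame pair counts as similar when its Euclidean distance falls below the
median (`q = 0.5`) of the background distance distribution of random frame
pairs. The score is 100 × the similar-frame fraction: 100 on identical
tracks, exactly symmetric, bounded in [0, 100]. Absolute score levels depend
on `q`, which is exposed in the configuration; all novelty decisions are
relative (candidate vs self-similarity statistics), so they are insensitive
to monotone recalibrations of the score.

Empirical cumulative density (ECD) curves of score distributions carry
pointwise 95% bootstrap bands (percentiles over 1000 resamples, seeded;
bands widened where necessary to bracket the point curve).

## Novelty detection details

The 1.96σ rule is evaluated against *each* pre-existing type's own
self-similarity dispersion by default (the candidate must diverge from all
of them); a pooled mode (one threshold from all self-similarity scores
pooled) is available since the original description is ambiguous on this
point. Missing cross-similarity evidence for any pre-existing type is an
error, not a silent pass. The dispersion entering the threshold is floored
at one percentage point (`min_std`), the quantisation scale of the score:
a perfectly stereotyped type with self-similarity exactly 100 ± 0 would
otherwise define a degenerate threshold from which *any* infinitesimal
score difference "diverges", and a significance rule with zero estimated
dispersion is not a usable test. The same rule with the call/introductory-note
repertoire as the pre-existing set answers "are novel syllables just calls"
— no extra machinery is needed.

For the cluster route no UMAP/HDBSCAN implementation exists in this
package's R dependency set, so both pieces are provided in-package:
a 2-D embedding by nonmetric MDS (classical-MDS/PCA initialisation,
`MASS::isoMDS` refinement) for visualisation, and a full hierarchical
density-based clustering (HDBSCAN with excess-of-mass cluster selection:
mutual-reachability distances, single-linkage hierarchy, condensed tree with
minimum cluster size 25, stability-based flat extraction). Clustering runs
in the 13-dimensional summary space rather than the 2-D projection, so
cluster counts cannot be corrupted by projection artefacts. The
variable-density design matters here: pre-existing types form tight clusters
(nearest-neighbour scale ~0.4 in z-units) while novel noise bursts are an
order of magnitude more dispersed; no single-radius density rule separates
the former without shattering the latter. The ≥95% final-epoch membership
rule for "new" clusters is a package choice; the original work reports no
purity number.

## Sequence statistics details

Transitions are counted within bouts only, never across bout boundaries.
Introductory notes are excluded by default (they are annotated separately
from song syllables) and can be included with a flag. "Per song" is read as
pooled over the analysed bout set, matching one value per bird per
condition; a per-bout mode exists. Modal-successor ties break to the
earliest-observed successor (the tie rule is undefined in the source
literature; the consistency *value* is tie-invariant, only the identity of
the typical transition depends on it). For the position histogram,
consecutive repeats of a label are collapsed before motif matching (so
stuttered renditions still count as completed motifs), motif occurrences are
matched greedily left-to-right on the novel-free label sequence, and each
novel occurrence is assigned to the nearest motif end (ties prefer the
preceding end). Occurrences in bouts with no completed motif are skipped
with a warning and reported.

## Problem sizes and determinism

The analysis scripts and tests run at the study scale of 50 bouts per epoch
(≈ 1000 syllables per epoch); parameter-recovery checks replicate over 10–20
seeds, and Monte-Carlo checks of generator calibration use 200 draws. Every
stochastic stage takes an explicit seed; `run_pipeline()` derives per-stage
seeds from the single config seed, and rerunning a config reproduces every
number bit-for-bit. The config hash recorded in each report ties outputs to
the exact parameter set.

## Known limitations

* Absolute similarity percentages are calibration-dependent (`q`, feature
  set, window choices) and are not comparable to SAP2011 output; only
  within-analysis contrasts are meaningful.
* Segmentation assumes a quiet, single-singer recording with a stable noise
  floor; it performs no bout detection across files and no overlap
  resolution.
* The cluster route needs enough renditions per type (min cluster size 25
  by default); genuinely rare novel types can only be found by the feature
  route.
* The synthetic generator's archetypes are spectrally idealised; real
  syllables with strong within-syllable structure (e.g. biphonation) are
  outside its vocabulary.
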