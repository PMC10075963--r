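---
title: "Orthographic stimulus statistics and ROI analyses for bilingual reading experiments"
author: "bilexread"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orthographic stimulus statistics and ROI analyses for bilingual reading experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`bilexread` implements the computational pipeline of a bilingual reading
experiment in the miniblock fMRI tradition: construction of letter-string
stimuli whose similarity to words of two languages is parametrically
manipulated, construction of the run schedules that present them, and the
region-of-interest (ROI) statistics used to analyze the resulting condition
amplitudes — word-similarity regression slopes, spatial gradients along the
Talairach Y axis, selectivity and language-dominance indices, a condition
contrast battery, an ROI-level GLM, and a nonparametric independent
component decomposition of voxel response profiles. A synthetic-data module
generates bilingual lexica and ROI cohorts with planted effects so that
every stage is testable end to end without any imaging data.

# The stimulus model

## Component statistics

For a lexicon of words with corpus frequencies (occurrences per million),
the package tabulates letter, bigram and quadrigram frequencies by
token-weighted counting: every contiguous, possibly overlapping occurrence
of an n-gram in a word contributes that word's corpus frequency. A string's
component statistic at a level is the arithmetic mean of the log10
per-million frequencies of all its contiguous n-grams at that level, with
unattested n-grams assigned a configurable floor (default `log10(0.01)` =
-2 per million: finite, and far below any attested n-gram, without
dominating a six-letter string's mean). Token weighting is the default
because corpus-frequency fields describe reader exposure; a type-weighted
mode is available for comparison. The alphabet is restricted to A-Z and
all strings are uppercased on ingestion.

## The 14-condition design

Candidate six-letter nonwords are every string over the alphabet that
contains at least one quadrigram attested in either language, contains no
embedded word of five or more letters, and is not itself a word. Twelve
nonword conditions cross the component level (letters L, bigrams B,
quadrigrams Q) with a 2 x 2 of per-language frequency (low-low "-",
high in the first language only "E", high in the second only "F",
high-high "+"); two real-word conditions (WE, WF) are matched on all six
component statistics to the corresponding one-language-high quadrigram
cells. The study value of 180 items per condition gives 2520 stimuli.

Several quantities in this construction are open design choices, set as
follows:

* **Frequency bands.** "High" and "low" are the outer quartiles of the
  candidate population per language and level, and the neutral band for
  the non-manipulated levels is the interquartile interval. Quantiles are
  computed on the sub-population above the unattested floor: more than a
  quarter of candidates are entirely unattested at the quadrigram level in
  one language (a string built around one language's quadrigram usually
  has none of the other's), so quantiles of the full population would pin
  the lower quartile to the floor itself and leave the low-low quadrigram
  cell empty by construction. All-floor strings belong to the low band by
  definition and are never neutral.
* **Decorrelation.** Within each cell, items are picked greedily to
  minimize the summed absolute Pearson correlation between the
  target-level statistics and every other-level statistic in the growing
  category; the achieved correlations are reported in the design
  manifest. In the letter cells the absolute cross-level correlations stay
  below 0.3 at the study scale.
* **Word matching.** WE and WF are selected greedily so that their
  category means of all six statistics approach the corresponding
  quadrigram cell's means; the quadrigram cells are in turn selected with
  a mean-targeting term that pulls them toward statistics real words can
  attain, alternating once between the two selections. The matching
  tolerance is 0.1 log10 units per statistic on category means; achieved
  deltas are reported.
* **Candidate pool.** Exhaustive enumeration of 26^6 strings is replaced,
  above a configurable cap (default 200,000), by a seeded sample that
  grows flanking letters around attested quadrigrams through the lexica's
  pooled bigram transitions, so the pool is dense in orthographically
  plausible strings; on small alphabets the enumeration is exhaustive and
  equals the brute-force filter exactly (this is property-tested). Cells
  that the pool covers thinly are supplemented by two further
  importance-sampling schemes — single-letter local-search variants of
  near-miss strings, and (for the quadrigram cells) single-end-letter
  variants of real words, which keep two of their three quadrigrams at
  word-level frequencies. Every proposal, whatever its origin, passes the
  same filters and the same fixed thresholds; the proposal distributions
  only concentrate the search and are never allowed to alter eligibility.

# The synthetic lexica

`make_synthetic_lexica()` emulates two related orthographies sharing an
alphabet. Each language owns an inventory of morpheme-like chunks
("morphs", 2-4 letters) sampled from a first-order letter chain; words are
concatenations of two or three morphs drawn with Zipf-weighted popularity,
and word frequencies follow a Zipf law (default exponent 1.0, top
frequency 40,000 per million, in the range of natural corpora). The morph
structure matters: in a plain letter chain, quadrigram frequency is the
product of bigram transitions, so strings with word-level quadrigram
statistics necessarily have extreme bigram statistics, and no nonword can
be matched to real words. Recurring chunks (think of -TION or -MENT)
concentrate quadrigram frequency mass without making bigram means extreme,
as real lexica do.

Divergence between the languages has two independent knobs — letter-level
(`divergence`, default 0.4) and transition-level (`pair_divergence`,
default 0.6) log-weight noise — on top of a shared core whose
concentration (default 0.8) controls how much the two languages prefer the
same letters and transitions. A small fraction of morphs (default 0.05)
and of whole words (default 0.02) is shared, standing in for cognate
morphology and loan words; shared words keep their relative frequency
order, so full overlap reproduces the first lexicon exactly. The defaults
were chosen once so that all twelve design cells are populated and the
word categories can be matched, and then held fixed; they are not tuned
per run. The acceptance analyses use 20,000 words per language, a scale
comparable to the word-form inventories of natural corpora.

What the generator does not emulate: morphology with positional syntax
(prefixes vs suffixes), accented letters, phonotactic constraints, and
any semantic structure. Passing design tests therefore show that the
pipeline's combinatorics and statistics behave as specified, not that the
synthetic orthography is linguistically faithful.

# Run schedules

Main runs follow the miniblock layout: 70 stimulus blocks of 12 stimuli
(150 ms on, 200 ms fixation; 4.2 s per block), each followed by a jittered
inter-block fixation of 3.8/5.8/7.8 s balanced to a mean of exactly 5.8 s
(23 of each plus one middle value, since 70 is not divisible by 3), seven
additional fixation-only blocks of 8/10/12 s composed as {8, 8, 10, 10,
10, 10, 12} (sum 68 s, mean 9.71 s), 16 s lead-in and 14 s lead-out:
798 s = 399 volumes at TR 2 s. Localizer runs use 45 blocks of 20 stimuli
(100 + 200 ms; 6 s), jitter 4/6/8 s (mean 6 s), 6 s lead-in/out: 552 s =
276 volumes. All durations live on a 50 ms grid and are assembled in
integer milliseconds, so events tile each run exactly.

Block order is randomized without immediate condition repetition (standard
practice, configurable in principle by reordering; the constraint is not
part of the timing arithmetic). Within a block, item order is found by
randomized backtracking so that consecutive strings never share a letter
at the same position; if a block's items admit no such order (possible
when a category contains single-letter variants of one another), the
condition's items are re-dealt across its blocks and ordering retried.
Two of the five blocks per condition and run carry a catch target
("######", a star in the localizer) replacing one stimulus at a random
position after the fifth; the checkerboard localizer condition is exempt.
Across the three-run session every stimulus is presented exactly once and
40% of stimulus blocks contain a catch target.

# The synthetic cohort and the ROI statistics

Each simulated ROI has a Talairach centroid (ventral occipitotemporal Y
uniform in [-75, -25] mm, matching the anatomical span of the ventral
reading pathway) and a voxel-by-condition beta matrix built from

    beta = baseline + slope(Y) * predictor + language/face terms + noise,

with `slope(Y) = gradient_coef * (Y - Y_posterior)` increasing linearly
toward anterior cortex, independent Gaussian voxel noise (the package does
not model spatial noise correlation), and, in the logographic-split
scenario, language patches with an additive preferred-language offset, a
response profile rising over the character hierarchy, and an elevated
localizer face beta. All planted parameters are stored in the cohort's
ground-truth record, so every downstream estimate can be checked against
what was planted.

The ROI statistics follow the analysis conventions of the field:

* the word-similarity predictor `[1 2 2 3 4 5 5 6 7 8 8 9 10 10]/10`
  (rising within each component level and across levels, no language
  difference) fitted by ordinary least squares per ROI, with
  Benjamini-Hochberg FDR across ROIs;
* one gradient regression coefficient per participant (ROI slope on TAL
  Y), tested against zero by a two-tailed one-sample t test; hemisphere
  comparisons are paired and restricted to participants with at least
  three right-hemisphere ROIs; lateral frontal ROIs are analyzed along the
  first principal component of their (Y, Z) centroid coordinates;
* the selectivity index `(word - other) / (word + other)` with the
  padding rule: if the smallest involved condition beta is negative, its
  absolute value is added to every involved condition first, bounding the
  index in [-1, 1];
* the language dominance score `(n1 - n2) / (n1 + n2)` from one-minute
  reading counts, correlated per merged region with per-pair condition
  differences (main-run WE-WF, LE-LF, BE-BF, QE-QF and the localizer word
  difference), FDR-corrected within region over the five pairs;
* ROI definition on a p-value map at p < 0.001 with connected clusters
  strictly larger than 4 voxels (6-connectivity by default, 26 available);
* an ROI GLM on the percent-transformed time course
  (`100 * (x - mean) / mean`) with two-gamma HRF-convolved block
  regressors (peak 6 s, undershoot 16 s, ratio 1/6 — the canonical form),
  optional z-scored confounds, and AR(2) serial-correlation correction by
  two-pass prewhitening: Yule-Walker coefficients from the OLS residuals,
  filtering of data and design, refit. All tests are two-tailed.

The forward simulator and the GLM share one design-matrix constructor,
and the simulator emits `x = baseline * (1 + (s - mean(s)) / 100)` — the
baseline is defined as the run's temporal mean — so at zero noise the
percent transform inverts the simulation exactly and betas are recovered
to machine precision. Degenerate inputs are reported as undefined (with a
warning) rather than silently coerced: zero-variance correlations never
come back as r = 0, and a constant coefficient vector yields an undefined
t statistic.

# Nonparametric component decomposition

The decomposition factors a voxels-by-conditions matrix into k canonical
response profiles and voxel weights. The subspace is fixed by the rank-k
singular value decomposition; the rotation within it maximizes the summed
non-Gaussianity of the weight columns, estimated nonparametrically as
negentropy via histogram entropy with Freedman-Diaconis binning of the
standardized weights. Optimization is by Jacobi-style sweeps over
component pairs with a 1-D line search per angle, restarted from random
rotations (default 10); the best solution is kept and components are
ordered by explained variance with the maximum-magnitude profile element
made positive. Because the rotation is orthogonal, the reconstruction
error always equals the rank-k SVD error. On Gaussian weights every
rotation is equivalent; the solver converges and reports nearly flat
restart objectives, which is the intended diagnostic for that degeneracy.
Localizer profiles for each component are obtained by least-squares
back-projection of the localizer betas onto the fitted weights.

# Problem sizes and reproduction

The packaged analyses run at these sizes, chosen as a balance between
statistical stability and desk-scale compute: candidate pools of 200,000
strings and lexica of 20,000 words for the full design (tens of seconds to
a few minutes per build, depending on how much cell enrichment a seed
needs); cohorts of 21 participants with 10 ROIs of 50 voxels (the study's
participant count); 20 replicate seeds for the gradient-recovery summary;
3000 voxels and 10 restarts for the decomposition checks.
`scripts/acceptance.R` recomputes the gradient-recovery mean and the
planted dominance correlation from scratch at exactly these sizes.

# Known limitations

The stimulus generator optimizes category means and correlations, not
item-level typicality; its pseudo-words are not guaranteed pronounceable.
The synthetic cohort plants linear gradients and additive language
effects — it cannot show that the analyses are robust to nonlinear
gradients, inter-regional correlation, or physiological noise structure.
The logographic stimulus hierarchy itself (stroke, radical and character
manipulations) is represented only as condition labels with planted
response profiles; constructing such stimuli requires script-specific
knowledge outside the scope of an algorithmic generator.
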