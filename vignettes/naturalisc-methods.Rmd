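---
title: "Methods: inter-subject correlation and semantic similarity in naturalisc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inter-subject correlation and semantic similarity in naturalisc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`naturalisc` analyses group differences in responses to a shared
naturalistic stimulus (for example, two groups of listeners following the
same audiobook) along two arms: voxelwise inter-subject correlation (ISC)
of BOLD fMRI time series, and semantic similarity of free-association
word lists collected per narrative segment. This vignette explains the
models and procedures, the tunable parameters, the synthetic-data
generators used to validate every stage, and the numerical and design
choices that were genuinely open.

## Inter-subject correlation

For each voxel, each functional run, and each unordered pair of subjects
within a group, the package computes the Pearson correlation of the two
time courses. With $n$ subjects this yields $n(n-1)/2$ pairwise ISC
values per voxel (276 for $n = 24$). Per-run correlations are combined
across runs on the Fisher-z scale,

$$\bar z = \frac{\sum_k w_k \,\mathrm{atanh}(r_k)}{\sum_k w_k},
  \qquad \bar r = \tanh(\bar z),$$

with weights $w_k$ equal to the run length in time points, so longer
measurements count more. Runs where a correlation is undefined
(zero-variance time course) drop out of that voxel's weighted mean;
undefined values are carried as `NA` sentinels, never as numbers.
Correlations of magnitude exactly 1 are clamped to $1 - 10^{-7}$ before
the transform so the z-scale stays finite.

### Circular-shift null

Statistical significance of within-group ISC is assessed against a
resampling null that rotates each participant's time series by a random
circular shift, drawn uniformly from $\{1, \dots, T-1\}$ per participant
per run (0 is excluded so no realization reproduces the observed data).
Rotation destroys alignment between participants while preserving each
series' autocorrelation, which is the property that makes a naive
parametric test on autocorrelated BOLD data invalid in the first place.

Each realization draws fresh shifts, picks an analysis voxel at random
(with replacement), and computes *the same statistic as the observed
map*: all pairwise correlations of the shifted series, Fisher-z
transformed, run-length weighted, averaged over runs, transformed back,
and averaged over pairs. Matching the null statistic to the observed
statistic is what makes the voxelwise p-values
$p(v) = (\#\{\text{null} \ge \bar r(v)\} + 1)/(N + 1)$ uniform under the
global null; pooling single-pair null values against a pair-mean
observed statistic would not be calibrated. Samples are pooled across
voxels and shifts into one empirical null, which assumes spatial
exchangeability after standardization -- a documented approximation, not
a theorem, on real data. Voxelwise p-values are corrected with
Benjamini-Hochberg FDR (`fdr_correct()`, default level 0.001 for maps).

### Cluster-based group contrast

Between-group differences are tested on pair-level Fisher z-values with
a pooled-variance two-sample t per voxel. Voxels with uncorrected
$p < \texttt{cdt\_p}$ (default 0.001, each tail separately) form
connected clusters (26-neighbour connectivity by default; 6 and 18
available -- the choice matters only for marginal, snake-like clusters).
The null distribution is the maximum suprathreshold cluster size over
*both* tails per permutation, which controls family-wise error across
the two directions jointly; each observed cluster's corrected p-value is
$(\#\{\text{null} \ge \text{size}\} + 1)/(P + 1)$. When the number of
distinct group assignments is at most the requested permutation count,
enumeration is exhaustive.

The exchange unit is the subject pair, i.e. pair-level z-values are
permuted between groups. Pairs sharing a subject are dependent, and
pair-level exchange ignores that. Under the global null of the
synthetic generator this is benign -- correlations of independent noise
series that share a subject are asymptotically uncorrelated, and the
measured FWER of the default pipeline is 0.05 -- but when a strong
shared signal is present the test should be read as descriptive rather
than exact. A subject-level relabeling alternative would require
correlations for cross-group pairs, which the pair-z container does not
hold; this is a known limitation of the contrast as specified.

## Preprocessing chain

The default order is: Savitzky-Golay detrending, nuisance-component
regression, DVARS computation, zero-phase band-pass, spatial smoothing.
All operators are deterministic.

* **Detrending** (`savgol_detrend()`): order 3, frame 240 s. The frame
  is converted to the nearest odd number of samples; boundary samples
  are fitted on asymmetric windows (the edge rows of the Savitzky-Golay
  projection matrix) so no data are discarded. The smoother is applied
  as an explicit linear map, which makes it one matrix product across
  all voxels.
* **Nuisance regression** (`maxcorr_denoise()`): for each subject, `k`
  (default 10) temporal components maximizing the Rayleigh quotient of
  own-nuisance covariance over others'-nuisance covariance (both
  $T \times T$) are found by generalized eigendecomposition and
  regressed out by OLS. A component present in everyone's data scores a
  quotient near 1 and is left alone, which is what protects
  stimulus-locked signal. The denominator covariance is ridged with its
  mean diagonal (argument `ridge`, default 1): the others'-nuisance
  covariance is rank deficient whenever the pooled nuisance series have
  fewer dimensions than time points, and with a vanishing ridge the
  maximizer escapes into its null space -- directions nobody penalizes,
  unrelated to the artifact. A ridge on the scale of the typical
  eigenvalue removes that escape route; the cost is shrinkage of the
  quotient, not of the data. Components default to per-run computation
  (reference conditions differ per run); `scope = "concatenated"` pools.
* **DVARS** (`compute_dvars()`): spatial *sample* standard deviation
  (divisor $N-1$) of each successive difference image. Scrubbing is
  deliberately not applied; per-run summaries are exported so groups can
  be compared.
* **Band-pass** (`bandpass_filter()`): 4th-order Butterworth, 0.08-4 Hz
  at 10 Hz sampling, applied forward-backward (zero phase).
* **Smoothing** (`gaussian_smooth()`): isotropic Gaussian,
  $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ voxels, truncated at
  $\lceil 4\sigma \rceil$, unit mass over support, zero padding, then
  re-masking; `normalize_mask = TRUE` divides by the smoothed mask so
  edge voxels are not dragged toward zero.

Voxels inside the white-matter or CSF masks are excluded from the ISC
analysis set (`analysis_voxels()`): series that were used to estimate
nuisance components should not also be tested.

## Semantic similarity of word lists

Each participant's word list for a segment is tokenized (lowercased,
punctuation stripped, stop-words removed; duplicates kept deliberately)
and mapped to the *sum* of the embedding vectors of its in-vocabulary
tokens -- so a repeated word counts twice, and out-of-vocabulary tokens
are discarded with a logged count. Embeddings are injected through the
`embedding_table` contract; the package never trains them (the
study-scale reference used a 500-dimensional skip-gram model, window 10,
minimum count 50, 5 passes -- recorded as metadata only). Within each
group and segment, cosine similarity is computed for every participant
pair with a usable vector; a group with fewer than two usable vectors
makes the segment untestable.

Per segment, the two groups' cosine sets are compared with a two-tailed
permutation t-test (Welch by default; pooled available). Two exchange
units are implemented:

* `exchange = "participant"` (default): participants are relabeled
  between groups and both cosine sets recomputed from the full cosine
  matrix. Under the null that participants are exchangeable this test is
  exact. It is the default because cosines sharing a participant are
  strongly dependent -- a participant whose vector sits close to the
  segment topic, or who simply wrote more words, raises every cosine
  they take part in -- and treating the pooled cosines as exchangeable
  understates the variance of the group-mean difference, inflating the
  rate of false flags well beyond the nominal FDR level in the
  generator's end-to-end validation.
* `exchange = "pair"`: cosine values exchanged between groups,
  mirroring the imaging contrast's pair-level convention; retained for
  comparability, exact only when cosines are genuinely exchangeable.

Segment p-values are BH-corrected over the testable segments (default
q = 0.05) and summarized three ways: group A more similar, group B more
similar, not significant. Word counts are compared with a two-tailed
Wilcoxon signed-rank test paired by segment totals (the natural pairing
unit, since the two groups contain different participants), and the
percent difference uses the larger total as the base:
$(\text{larger} - \text{smaller})/\text{larger} \times 100$, the
convention that reproduces the published summary for totals 18,724 vs
12,536 (33%).

## Synthetic data with known ground truth

### BOLD generator

`generate_group_bold()` mixes, per voxel, three unit-variance Gaussian
AR(1) processes ($\phi = 0.3$ by default, so resampling nulls are tested
under temporal autocorrelation): a stimulus-locked signal shared by all
subjects (variance fraction $s$), a group-specific signal (fraction
$g$), and subject noise. By construction the expected pairwise
correlation is $s + g$ within a group and $s$ between groups, which the
recovery tests check directly. White-matter and CSF masks occupy the two
opposite faces of the grid and carry pure noise plus optional
subject-specific artifact (with a configurable bleed into gray matter
for validating nuisance regression). Every series is standardized to
sample mean 0, variance 1 -- Pearson correlations are unaffected, and
downstream numerical behaviour is uniform. Defaults mirror the emulated
design: 24 subjects per group, 10 runs of 4.8-8.4 minutes at TR 100 ms.

The generator intentionally omits hemodynamic convolution, realistic
scanner-noise spectra, spatial correlation of noise, motion, and
registration error. Passing tests therefore demonstrate correctness of
the statistics under the stated generative model, not robustness to
everything real fMRI can do.

### Word-list generator

`generate_word_lists()` builds a synthetic unit-norm vocabulary (800
words by default), gives every segment a latent topic vector, and draws
each participant's tokens by nearest-neighbour lookup of noisy copies of
their topic (noise scale `topic_noise_sd = 0.6` relative to the
unit-norm topic; list lengths $1 + \mathrm{Poisson}(\lambda - 1)$ with
mean 6, about the per-segment rate implied by the emulated study's
totals). Nearest-neighbour sampling guarantees list vectors correlate
with topics by construction. Tokens are replaced by out-of-vocabulary
strings with probability `oov_rate` (default 0.02, matching the 98%
coverage the emulated study reports).

In designated divergent segments (40 of 101 by default) each
participant of the affected group receives an *individual* topic at the
configured cosine distance from the segment topic, in a random
direction. This is deliberate: rotating the two *group* topic vectors
apart symmetrically would leave both groups' within-group cosine
distributions identical and hence be invisible to an analysis that
compares within-group similarity between groups. Participant-level
dispersion lowers the affected group's internal similarity, which is
exactly the effect the segment test is built to detect, and mirrors the
direction-of-effect summary the behavioral arm reports.

## Numerical choices and problem sizes

* +1 smoothing in every resampling p-value keeps p off zero and inside
  $[1/(P+1), 1]$.
* Pair enumeration is lexicographic ($i < j$) for reproducible
  serialization; voxel order is the column-major order of brain-mask
  voxels (R's native array order).
* All randomness flows through R's RNG via explicit seeds; identical
  seeds give bit-identical datasets, null distributions and cluster
  tables.
* Degenerate inputs: zero-variance series give flagged `NA`
  correlations; zero-variance permutation denominators give t = 0 when
  the means agree; empty or all-OOV word lists become missing vectors
  excluded pairwise.
* Validation problem sizes were chosen to make Monte-Carlo bounds
  meaningful at interactive cost: null calibration uses a
  12x12x12 grid, 8+8 subjects, two 300-sample runs, 10,000 null
  realizations, 500 permutations and 500 replicates; recovery uses run
  length 2000 with 105 pairs; the behavioral arm runs at full study
  geometry (2 x 24 participants, 101 segments, 500-dimensional
  embeddings, 5000 permutations per segment).

## Known limitations

* Pooling the circular-shift null across voxels assumes spatial
  exchangeability after standardization.
* The cluster contrast's pair-level exchange ignores pair dependence;
  see above for when that matters.
* The t-test on 276 dependent pair values uses the naive two-sample
  degrees of freedom; the permutation reference distribution, not the
  t reference, carries the inference.
* Spelling correction, lemmatization and morphological analysis of the
  word lists are out of scope; input is assumed pre-corrected.
* Cluster peaks are reported in millimetre coordinates derived from the
  NIfTI affine (or voxel size); no anatomical-atlas labeling.
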