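---
title: "Detecting integrated and separated neural representations of overlapping events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting integrated and separated neural representations of overlapping events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

When two experiences share an element — a character B who first appears with
A and later with C — the brain can encode the second experience in two
complementary ways: it can *integrate* the overlapping episodes into a
shared representation (which supports inferring the indirect A–C
association) or *separate* them into distinct traces (which preserves
source details such as "B and C were actually seen together, A and C were
not"). `waversa` implements an encoding-phase EEG analysis that tracks both
processes over time: if, while a participant watches the BC movie, the
multivariate time–frequency pattern comes to resemble the stored AB
pattern, integration is at work; if it becomes actively anti-correlated
with it, separation is.

The experimental schema is an associative-inference design with naturalistic
movies: triads of AB, BC and XY movies (XY shares nothing with AB and serves
as a control), each movie 14 s long and repeated five times, with a fixed
segment schedule after movie onset — first Sim alone (0–2 s), first Sim in
context (2–5 s), fixation (5–6 s), second Sim alone (6–8 s), and both Sims
interacting in context (8–13 s). EEG epochs span −0.5 to 13.5 s around
movie onset.

## The analysis pipeline

`run_pipeline()` chains five stages, each of which is exported on its own.

**1. Morlet time–frequency decomposition** (`morlet_transform`). Complex
Morlet wavelets with 5 cycles on an integer 1-Hz grid from 3 to 30 Hz (28
bins — the only integer grid with that count), sampled every 0.02 s.
Wavelets are normalised to unit discrete energy so unit-variance white noise
has flat expected power of 1 across frequencies. Timepoints whose wavelet
support extends past the epoch edge are flagged invalid and excluded from
every downstream statistic rather than zero-padded silently. The epoch-mean
reference for the decibel transform (`db_normalize`,
`10·log10(P / mean_t P)` per channel × frequency) uses valid timepoints
only and includes the pre-stimulus part of the epoch; both choices are
configurable in principle but fixed here for reproducibility.

**2. Wavelet-coherence feature selection** (`wavelet_coherence`,
`participant_coherence_summary`, `select_template`). Movie-content-sensitive
time–frequency features are those whose signal is phase-stable across the
five repetitions of the same AB movie but not across different AB movies.
Magnitude-squared coherence |S(W₁·conj(W₂))|² / (S(|W₁|²)·S(|W₂|²)) is
computed per channel from the same 5-cycle Morlet family as the TFR, with a
smoothing operator S — a Gaussian over time whose SD is 3 wavelet periods at
each frequency, plus a ±1-bin boxcar over frequency. These smoothing widths
are the critical unstated degrees of freedom of any wavelet-coherence
analysis; the defaults follow common practice and are recorded in the
output. Per participant, coherence is averaged over all within-movie
repetition pairs (choose(5,2) = 10 per movie, 240 for the 24-movie design)
and all between-movie pairs (23 × 10 = 230 per movie, 5520 in total;
between-movie pairs use the same unordered repetition-index scheme, which is
the only convention consistent with those totals). A positive-tail
cluster-based permutation test of within > between, run separately inside
the four AB segment windows, yields one boolean template per segment.

The coherence maps live on a 0.1-s time grid rather than the RSA's 0.02-s
grid: the estimator already smooths over at least three wavelet periods
(≥ 0.1 s at 30 Hz), so a finer sampling of the coherence field carries no
additional information, and the template's time support only gates which
TFR samples enter the per-cell median below.

**3. Time-resolved RSA** (`extract_ab_features`, `similarity_timecourse`,
`baseline_contrast`). For each AB movie the dB cubes of its five repetitions
are averaged, masked by the template, and reduced to one value per
(channel, frequency) cell by the median over the template's time support —
a deliberately shift-robust summary, since repetitions are not perfectly
time-locked. Cells are concatenated channel head-to-tail (frequency
ascending within channel) into the anchor feature vector. The primary
anchor segment is the joint-interaction window (8–13 s), which contains the
full event; the other three segments run through the identical code path.
At every timepoint of a BC or XY epoch the same cells are extracted,
Pearson-correlated with the anchor, and Fisher z-transformed (|r| clipped
at 1 − 1e−7; zero-variance or edge-invalid timepoints propagate as missing,
never as zeros). Two baselines are subtracted in z space: the mean
similarity to all XY movies of the same repetition, and the mean similarity
to all non-corresponding BC movies — the second controls for
content-unspecific reinstatement. First-exposure (repetition-zero) BC/XY
trials are excluded throughout, because no reactivation of the AB movie can
exist before the association is known.

**4. Bayesian evidence accumulation** (`nig_prior`, `nig_update`,
`bf10_vs_zero`, `detect_windows`). At each timepoint the participants'
mean contrasts update an informative Normal-Inverse-Gamma prior
(α = 15, β = 15, µ₀ = 0, v = 30, with v the pseudo-observation weight on
the mean) by the standard conjugate formulas; sequential and batch updating
agree to machine precision. Evidence for a nonzero mean is the
Savage–Dickey density ratio of the marginal scaled-t distribution of µ at
zero under the prior versus the posterior — exact for this conjugate family,
and equal to the marginal-likelihood ratio whose point-null model inherits
the conditional variance prior IG(α + ½, β). Maximal runs with BF₁₀ ≥ 3 and
a consistent contrast sign that last longer than 0.1 s are reported as
similarity (positive) or dissimilarity (negative) windows; runs interrupted
by even a single sub-threshold sample are never merged.

The BF parametrisation deserves a note: with v read as a pseudo-observation
precision weight, the prior marginal of µ has scale sqrt(β/(αv)) ≈ 0.18,
so group means of order 1e−2 can never reach BF₁₀ = 3 regardless of how
consistent they are. Any monotone-equivalent BF definition shifts window
edges; this package therefore treats the BF machinery as exactly specified
(and oracle-tested) while making no claim that its window boundaries on
real data would coincide with any particular alternative implementation.

**5. Memory linkage and univariate contrast** (`mvnig_regression`,
`power_contrast`, `segmentwise_tests`, `power_similarity_link`). Per trial
and detected window, the window-averaged contrast is the dependent variable
of a conjugate Bayesian linear regression (MVNIG prior, Λ₀ = 30·I, α = β =
15, standardized coefficients; binary outcomes are modelled with the
Gaussian conjugate family, matching a linear-regression treatment of
accuracy). AC-association accuracy is the predictor of interest with
repetition order controlled; source-memory accuracy additionally controls
for AC accuracy. Participants with ceiling accuracy (> 0.9 on the
respective outcome) are excluded, and correct responses slower than 10 s or
given with "guessing" confidence are recoded as incorrect first. The
univariate stage averages linear-power cubes over all BC and all XY trials
(repetition zero excluded), forms (BC − XY)/BC per participant — the
asymmetric scaling by BC follows the printed formula — and runs two-sided
sign-flip cluster permutation against zero inside each segment window;
trial-level mean power inside each significant cluster then predicts the
matched window's (dis)similarity in the same regression framework.
Statistics run on the linear-scale index; dB versions are for display only.

## Cluster-based permutation statistics

`one_sample_cluster_test` / `paired_cluster_test` implement the standard
nonparametric familywise-error control: element-wise t statistics are
thresholded at the two-tailed t quantile with cluster-forming α = 0.05 (the
conventional default, since the method's description does not fix it),
supra-threshold elements are clustered under orthogonal (frequency, time)
adjacency plus the montage channel neighbour graph, cluster mass is the
summed t, and the null distribution is the maximum |mass| over random
sign-flips of the per-participant maps (positive and negative clusters are
formed separately and compared against the two-sided maximum). The observed
labelling always counts into the null (the "+1" convention), so p > 0, and
all 2ⁿ sign patterns are enumerated whenever that is cheaper than sampling.
Feature selection clusters span the channel dimension, because the template
must index individual channel–frequency–time cells downstream. Two
consequences of this construction are worth remembering: with n
participants the smallest attainable two-sided p is 2/(2ⁿ+1) (the global
sign flip always reproduces the observed mass), so group sizes below 6
cannot reach α = 0.05; and clusters bleed into contiguous regions of weak
but consistent contrast, so a selected template is intentionally a
*sensitive*, not a *selective*, mask.

## The synthetic-EEG generator

`generate_epochs` emulates the statistical structure the analysis assumes —
not biophysics. Each movie carries a signature: constant-modulus spectral
lines at 3, 5, 9, 16 and 28 Hz (one line per wavelet bandwidth, so each
analysis bin is dominated by a single line), whose phase trajectories drift
as Brownian motion with a 0.1-Hz Lorentzian linewidth. All lines of one
channel share a trajectory, and the per-line phase offsets are shared
across movies, which makes the wavelet's cross-line interference the same
fixed mixing operator for every movie. Repetitions of a movie reuse its
trajectories (up to ±0.05 s whole-signal jitter and fresh 1/f noise), so
within-movie pairs are phase-coherent where different movies decorrelate
within the coherence smoothing window — exactly the contrast the feature
selection needs.

Amplitudes are log-normal: cell amplitude = band amplitude × exp(δ), with
movie- and segment-specific deviations δ ~ N(0, 0.3²). Integration is
planted by adding a scaled copy of the corresponding AB movie's
joint-segment pattern to the BC movie's first-Sim segments
(δ → δ + g·u·δ_AB with g = 6/2.5 per unit of anchor pattern and a per-trial
gain u ~ U(0.85, 1.15)); separation adds the negative copy during the
second-Sim segment. The planted pattern correlation is g·u/sqrt(1+(g·u)²) ≈
0.97. Three structural choices matter and were calibrated by pilot runs at
the desk scale before the test suite was frozen, as the informative NIG
prior requires group-mean Fisher-z contrasts of order one to cross BF₁₀ = 3
with 12 participants:

* `anchor_pattern_scale = 2.5` enlarges the AB joint-segment pattern so the
  anchor and the planted target component pass through the same log-domain
  nonlinearity of the wavelet's line mixing; without it the measured
  correlation saturates near 0.7 however large the planted effect is.
* `segment_gain` weights epoch power away from the planted windows (AB
  joint segment × 0.5; BC fixation and joint segments × 2.5), because the
  dB reference is the epoch mean: a segment that dominates its own epoch's
  mean power reabsorbs its own pattern during normalisation.
* log-amplitude planting is additive, not variance-normalised: normalising
  the mixture keeps mean power comparable across segments but pushes the
  median amplitude below the noise floor once the planted variance is
  large, which destroys the separation (negative-correlation) effect first.

A side effect of log-normal planting is that BC segments carrying strong
planted patterns also carry more *mean* power (heavier amplitude tails), so
the univariate BC-vs-XY contrast on planted data shows broadband
differences. The univariate power manipulation therefore has its own
independent dial (`bc_power_effect`, a multiplicative amplitude gain on the
BC first-Sim segments) and is exercised with the RSA planting switched off.

Trial outcomes are Bernoulli draws through logistic links on the planted
per-trial (dis)similarity scalars, with monotone links for confidence and
response time and a slow-response tail so the 10-s/guessing recoding rule
has material to act on.

What the generator does *not* emulate: volume conduction and realistic
topographies (the montage is a synthetic grid), eye-blink or movement
artifacts, between-participant amplitude heterogeneity, or effect sizes on
the scale of real EEG similarity analyses (realistic baselined Fisher-z
similarities are of order 1e−2; the desk-scale defaults plant contrasts of
order 1 at n = 12 because the fixed informative prior makes smaller effects
undetectable by construction). Passing recovery tests on this
generator therefore demonstrates that the pipeline's statistics and
plumbing are correct, not that the method would detect effects of realistic
size in real recordings.

## Problem sizes and numerical choices

The package's default working scale is the desk profile: 12 participants,
6 triads, 8 channels, 100 Hz, 5 repetitions, 500 permutations — chosen so a
full pipeline run completes in well under a minute and the whole
calibration suite (10 planted and 20 null seeds, 200-run type-I study with
500 permutations each, 100 regression calibration runs) stays within a
desktop session. The full study scale (36 participants, 24 triads, 62
channels, 500 Hz) is a configuration switch over identical code paths.
The univariate cluster statistics subsample the 0.02-s grid by a factor of
5; the permutation t maps are block-processed to bound memory; inverse FFTs
for decimated outputs use exact spectral folding (decimating by s aliases
the spectrum onto N/s bins), and all convolution edges are either flagged
invalid (wavelets) or renormalised (coherence smoothing kernels).
Determinism is end-to-end: every stochastic step derives its seed from the
configuration seed, and identical configurations reproduce reports
bit-for-bit, which the test suite asserts.

## Known limitations

* Baselines are averaged in z space before subtraction; averaging in r
  space would differ in the third decimal at these magnitudes but is not
  implemented.
* The main RSA uses the anchor segment's template only; a union-of-segments
  template is a plausible alternative reading of the feature-selection
  step and is not implemented.
* EDF/BrainVision ingest is not provided; epochs enter through the native
  container (float64 payload + JSON sidecar + CSV trial table) or the
  generator.
* The evidence trace updates the prior with participant-level mean
  contrasts; updating with all trials per participant is a defensible
  alternative that would change window widths.
* The fixation segment is never tested in the univariate stage, and the
  topographical searchlight (`neighborhood_topography`) restricts itself to
  one-hop neighbourhoods.
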