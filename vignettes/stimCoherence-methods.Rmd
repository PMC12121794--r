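---
title: "Stimulation-evoked coherence analysis: models, parameters and design choices"
author: "stimCoherence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stimulation-evoked coherence analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimCoherence)
```

## The problem

Intracranial EEG (sEEG) patients implanted for epilepsy monitoring can be
recorded while a peripheral stimulus — here, vibrotactile stimulation of the
outer ear at one of five pulse frequencies (2, 6, 12, 20, 40 Hz) — is
switched on and off in five-second trials. The scientific question is
whether, and at which vibration frequency, stimulation changes functional
connectivity between brain regions, measured as magnitude-squared coherence
(MSC) between electrode contacts relative to a resting baseline.

`stimCoherence` implements the full chain: preprocessing of raw
multichannel recordings, epoch-wise MSC over all electrode pairs,
baseline-subtracted aggregation to anatomical region pairs, and the
nonparametric statistics used to summarize frequency-specific responses.
Because clinical recordings cannot be redistributed, the package ships a
synthetic-session generator with known ground truth so that every stage has
a parameter-recovery test surface.

## The estimator

For two epochs $x, y$ the package computes the Welch estimate

$$C_{xy}(f) = \frac{|P_{xy}(f)|^2}{P_{xx}(f)\,P_{yy}(f)} \in [0, 1]$$

with cross- and auto-spectra accumulated over $K$ Hamming-tapered segments
of 2.5 s with 70 % overlap. A 5-s epoch at 500 Hz yields $K = 4$ segments
(starts at samples 0, 375, 750, 1125 of the epoch) and a 0.4 Hz frequency
grid. Coherence is averaged over half-open canonical bands — theta $[4,8)$,
alpha $[8,13)$, beta $[13,30)$, broadband gamma $[70,170)$ Hz — the
half-open convention resolving the 8 and 13 Hz edges that would otherwise
belong to two bands. With a single segment the estimator is identically 1
for any inputs, so $K = 1$ is refused rather than silently returned.

Two estimator modes exist:

* **Per-epoch** (default): MSC per 5-s epoch, $K = 4$. This is what the
  responder analysis needs — Cohen's *d* between the stimulation and
  baseline *distributions* of per-epoch values requires a within-pair
  spread. The price is a large positive small-sample bias (for independent
  signals the per-epoch estimate averages ≈ 0.35, not 0). The bias is
  common to stimulation and baseline epochs and cancels in Cohen's *d* and,
  to first order, in the baseline-subtracted delta of equal-coherence
  conditions, but it shrinks per-epoch deltas of truly coherent pairs
  toward zero (a true coherence step of 0.25 appears as a per-epoch delta
  of roughly 0.13).
* **Pooled** (`pairConditionTable(pooled = TRUE)`): Welch segments
  accumulated across all valid epochs of a condition before forming
  coherence ($K \approx 120$ for 30 epochs), nearly unbiased and much less
  variable. Parameter-recovery tests that compare against the analytic
  coupling value use this mode; distribution-based statistics cannot.

For a synthetic coupled pair $x = a s + n_1$, $y = a s + n_2$ with shared
band-limited unit-variance source $s$ and independent like-spectrum noises,
the in-band coherence is $\bigl(a^2\sigma_s^2 / (a^2\sigma_s^2 +
\sigma_n^2)\bigr)^2$ (`expectedBandMsc()`); the matched-power case
$a^2\sigma_s^2 = \sigma_n^2$ gives 0.25 and is the calibration point of the
recovery tests.

## Preprocessing

The chain reproduces the study's order exactly: 0.5 Hz 4th-order
Butterworth highpass (zero-phase, forward–backward), exclusion of channels
whose 59–61 Hz Welch power exceeds the cross-channel median by more than
three mean absolute deviations (about the median — read literally; the
median-absolute-deviation variant is available via `dispersion =
"median"`), exclusion of contacts labelled white matter / ventricle /
unknown, common average reference (CAR) over the kept channels, 60 Hz notch
(2nd-order IIR, Q = 30, zero-phase), epoching (baseline cut into
consecutive non-overlapping 5-s epochs; one epoch per stimulation trial;
off-periods discarded), spike rejection, and downsampling to 500 Hz
(8th-order Butterworth anti-alias lowpass at 0.8 × the new Nyquist, then
decimation).

Spike rejection is per (channel, epoch): the keep mask drops every slot
whose absolute amplitude *strictly exceeds* 500 µV — an epoch peaking at
exactly 500 µV is kept, following the wording of the rule. Rejection is
evaluated on the preprocessed (post-CAR, post-notch) signal, consistent
with the narrative order of the steps; the exported `rejectSpikeEpochs()`
can equally be applied to raw epochs. Zero-phase filtering is used
throughout so that no condition-dependent phase distortion can enter the
cross-spectra.

## Statistics

All §-level procedures are implemented in-package with exact small-sample
paths:

* **Friedman** and **Kruskal–Wallis** tests with tie correction; complete
  ties return statistic 0 / p 1 with a warning rather than failing, because
  thresholded coherence maps can be constant.
* **Wilcoxon signed-rank** (paired or one-sample): zero differences dropped
  (classic convention; Pratt's method available), exact null distribution
  for $N \le 25$ without ties, tie-corrected normal approximation
  otherwise, no continuity correction by default (the convention of the
  MATLAB-style approximate method; a flag enables it). Effect size
  $r = |Z|/\sqrt{N}$. The continuity-corrected approximation tracks the
  exact path within 0.01 in *p* for $N = 20$–25; the uncorrected default
  within 0.025 — both bounds are asserted in the test suite.
* **Exact multinomial goodness-of-fit** by full enumeration of all
  $\binom{n+k-1}{k-1}$ outcomes, summing the probabilities of outcomes no
  more probable than the observed one (probability-ordering extremeness,
  with a $1+10^{-12}$ float guard). The two seven-subject worked examples
  evaluate to 0.624 and 0.016 at printed precision.
* **Cohen's d** with the $(n-1)$-weighted pooled SD; **Bonferroni**
  correction by multiplication and capping. Family sizes follow the study:
  $m = 5$ for the one-sample-versus-zero family (five vibration
  conditions), $m = 10$ for pairwise post-hoc comparisons of five
  conditions.

The responder rule is strict: an electrode pair is a responder only if
$d > 0.2$ (exactly 0.2 is not). The SNR of a condition is the mean over
subjects of its responder percentages divided by their SD (sample SD by
default; population SD available — the source does not specify, and the
same switch governs the 2-SD hub rule). The permutation test shuffles each
subject's condition labels independently; *p* is the fraction of
permutations whose SNR strictly exceeds the observed value. Because the
strict rule yields $p = 0$ for degenerate (constant) inputs, two
alternative estimators are provided: tie-counting (`mode = "gte"`, which
returns 1 in the degenerate case) and the add-one estimator
$(b+1)/(n+1)$ (`mode = "add-one"`), which cannot be exactly zero and is
exactly uniform under the null — the recommended choice when the p-values
feed further thresholding.

Hub detection thresholds region-pair deltas at the global mean + 2 SD of
the same (condition, band) distribution being thresholded; hub regions are
those appearing in at least two qualifying pairs. Seed maps report deltas
from a seed region to all covered regions masked at $|\Delta| > 0.01$
(strict), and the across-condition comparison is a Kruskal–Wallis omnibus
on the threshold-applied distributions with Bonferroni-corrected pairwise
rank-sum post-hocs gated on omnibus $p < 0.05$.

## The synthetic generator

`buildSession()` emulates the study design: a 3-min resting baseline, then
150 five-second trials (30 per condition, order randomized) interleaved
with 5-s off periods, at a native 2000 Hz. Channels are grouped into named
regions. The signal model is per-channel $1/f^{\alpha}$ Gaussian noise
(α = 1, SD 10 µV) plus a weak per-region shared $1/f$ source (SD 3 µV)
that produces realistic nonzero within-region baseline coherence; the
study's publication reports no baseline signal statistics, so these are
conventional electrophysiology-scale choices, fixed once. Couplings are
band-limited unit-variance sources (4th-order Butterworth bandpass of white
noise, renormalized) added to all channels of two designated regions only
during the ON epochs of one designated condition, with no onset ramp —
matching the epoch-level granularity of the analysis. Artifacts are a 60 Hz
sinusoid on designated channels and biphasic raised-cosine transients
(default width 40 ms) whose absolute peak equals the specified amplitude
exactly, so the 500 µV rejection boundary can be tested exactly. Off-period
data are generated but never analyzed, mirroring the design.

What the generator does *not* emulate: evoked potentials and onset
transients, nonstationary background (sleep/arousal state changes), real
interictal spike morphology and rate, volume conduction with distance
structure, and auditory confounds of the vibration device. Passing
recovery tests therefore demonstrate correctness of the estimator and
statistics under the stated signal model, not robustness to every
real-data pathology.

## Findings from the calibration experiments

Two properties of the analysis design itself — not of any implementation —
surfaced in the null-session experiments and are worth knowing when
interpreting results:

* **All-pairs one-sample tests are anticonservative at small montages.**
  Deltas of electrode pairs that share a channel are positively dependent,
  and CAR adds a small common-reference component to every pair. On
  20-channel null sessions the one-sample signed-rank test across all 190
  pair deltas rejects at roughly 12–20 % instead of 5 %; restricted to the
  10 disjoint pairs (independent by construction) it is calibrated (6 %
  over 100 seeds, inside the binomial interval). With clinical montages of
  ~174 contacts the shared-channel fraction per pair and the reference
  power are far smaller, but the effect does not vanish: brain-wide
  one-sample p-values should be read as descriptive rather than exactly
  calibrated. The acceptance suite asserts calibration on the disjoint
  pairs, where the nominal level is the correct expectation.
* **CAR redistributes strong shared sources.** Referencing subtracts the
  instantaneous channel mean, so a source present on a fraction $f$ of
  channels leaks into all others with amplitude $f$ times the source,
  creating spurious coherence of order $f^2$ between otherwise independent
  channels. In recovery experiments the coupled regions are kept to a
  small fraction of the montage (4 of 48 channels) so that leak-induced
  deltas stay below the 0.01 seed-map mask.

## Problem sizes used by the test suite

The tests run the full pipeline at reduced sizes chosen so the whole suite
completes comfortably on one CPU: null calibration uses 100 zero-coupling
sessions of 20 channels with 10 epochs per condition; coupling recovery
uses 20 sessions of 48 channels, 12 trials per condition and a 120 s
baseline at 500 Hz, with one ground-truth alpha-band coupling; the
estimator calibration uses 12 replicate pairs of 30 epochs. The
"sole surviving seed-map target" property is asserted on the across-seed
mean map (per-seed region-pair deltas at these sizes have an estimator
noise floor of ≈ 0.008 SD, the same order as the 0.01 mask; the study's
montages average over hundreds of electrode pairs and seven subjects,
which suppresses this floor) together with per-seed assertions that the
injected target always survives and is always the top-|Δ| pair.

## Numerical choices and degenerate inputs

* Band averaging uses the unweighted mean over bins with
  $\mathrm{low} \le f < \mathrm{high}$; a band with no bins on the grid is
  an error, not an empty value.
* Coherence values are clipped to $[0, 1]$ against floating-point spill.
* Pairs with no valid baseline epoch are excluded from baseline
  subtraction and reported; conditions with no valid epochs are flagged,
  never silently zero.
* Argmax ties in the best-frequency ranking go to the lowest frequency
  with a warning (ties cannot occur with continuous percentages but can
  with degenerate inputs).
* `exactMultinomial()` refuses outcome spaces above $2\times10^6$
  compositions; its enumeration is verified to sum to 1 within $10^{-12}$.
* Fixed seeds make sessions, pipelines and permutation tests bit-identical
  across reruns; RNG state of the caller is restored.

## Limitations

The package analyzes undirected, epoch-level linear coupling only: no
phase-lag or directed measures, no time-resolved coherence within the 5-s
epoch, no imaging or electrode-localization functionality (region labels
are taken from the channel table as given). The default 28-region grouping
is a placeholder of fourteen bilateral structures; real analyses should
supply their own parcellation-to-region mapping via `readRegionMapping()`.
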