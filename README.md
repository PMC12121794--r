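# stimCoherence

Stimulation-evoked functional connectivity analysis for multichannel
intracranial EEG (sEEG).

Epilepsy-monitoring patients can be recorded while a peripheral stimulus —
e.g. vibrotactile stimulation of the outer ear at 2, 6, 12, 20 or 40 Hz —
alternates between five-second ON trials and five-second off periods after a
resting baseline. `stimCoherence` answers the question *"which stimulation
frequency changes coupling between which brain regions?"* by computing, for
every electrode pair and five-second epoch, the Welch magnitude-squared
coherence

    C_xy(f) = |P_xy(f)|^2 / (P_xx(f) P_yy(f))        in [0, 1]

(2.5-s Hamming segments, 70 % overlap, K = 4 segments per epoch), averaging
it over canonical bands (theta [4,8), alpha [8,13), beta [13,30), gamma
[70,170) Hz), subtracting each pair's baseline coherence, and aggregating to
anatomical region pairs. On top of the connectivity deltas it implements the
full statistical battery of this analysis style:

* preprocessing: 0.5 Hz Butterworth highpass, rejection of channels with
  60 Hz power > median + 3 mean absolute deviations, common average
  reference, 60 Hz notch, 5-s epoching, rejection of channel-epochs
  exceeding 500 µV, downsampling to 500 Hz — all zero-phase;
* self-contained nonparametric tests: tie-corrected Friedman and
  Kruskal–Wallis, exact/approximate Wilcoxon signed-rank with effect size
  r = |Z|/√N, exact multinomial goodness-of-fit by full enumeration,
  Cohen's d, Bonferroni correction;
* responder classification (pairs with d > 0.2 stimulation vs baseline),
  per-condition SNR = μ/σ of responder percentages across subjects with a
  label-shuffling permutation test, best-frequency rankings, hub pairs
  (≥ 2 SD above the brain-wide mean) and seed-region maps masked at
  |Δ| > 0.01;
* a synthetic-session generator with ground-truth couplings, line-noise and
  spike artifacts, so every stage is testable without clinical data.

## Worked example

Simulate a 28-channel session with one ground-truth alpha-band coupling
between the left amygdala and the left ACC, active only during 20 Hz
stimulation, then run the analysis:

```r
library(stimCoherence)

cfg <- synthConfig(
  samplingRate = 500, baselineDuration = 120, trialsPerCondition = 12,
  regions = c("L-Amygdala" = 2, "L-ACC" = 2, "L-Hippocampus" = 8,
              "L-OFC" = 8, "L-Temporal" = 8),
  couplings = list(couplingSpec("L-Amygdala", "L-ACC", band = c(8, 13),
                                condition = "20Hz", gain = 2.5)),
  seed = 42)
session <- buildSession(cfg)
session$bundle
#> SessionBundle 'synthetic': 28 channels x 360000 samples @ 500 Hz (720.0 s)
#>   events: 12Hz=12, 20Hz=12, 2Hz=12, 40Hz=12, 6Hz=12, baseline=1

prep     <- preprocessSession(session$bundle, runConfig())
tab      <- pairConditionTable(prep$epochs,
                               scheme = bandScheme(theta = c(4, 8),
                                                   alpha = c(8, 13)))
regional <- regionize(baselineSubtract(tab), prep$channels)
round(deltaMatrix(regional, "20Hz", "alpha"), 3)
#>                L-ACC L-Amygdala L-Hippocampus  L-OFC L-Temporal
#> L-ACC          0.146      0.106         0.001 -0.016      0.001
#> L-Amygdala     0.106      0.138         0.016  0.005      0.005
#> L-Hippocampus  0.001      0.016         0.006  0.000     -0.001
#> L-OFC         -0.016      0.005         0.000 -0.001     -0.008
#> L-Temporal     0.001      0.005        -0.001 -0.008      0.008
```

The injected amygdala–ACC coupling stands out as a +0.106 coherence change
(the diagonal entries are the within-region pairs, which share the coupled
source too); all uncoupled region pairs stay near zero. The data-driven
summaries recover it:

```r
hubPairs(regional, "20Hz", "alpha")
#> HubResult: 1 pair(s) >= 0.07979; hub regions: none

sm <- seedMap(regional, "L-Amygdala")
sm[sm$condition == "20Hz" & sm$band == "alpha", ]
#>         seed condition  band        target      delta
#> 3 L-Amygdala      20Hz alpha         L-ACC 0.10600534
#> 4 L-Amygdala      20Hz alpha L-Hippocampus 0.01605884
```

The coupled pair is the single hub-threshold exceedance (it takes two such
pairs touching one region to declare a hub region), and the seed map from
the amygdala keeps the ACC as its dominant target — the small hippocampal
entry illustrates the estimator noise floor sitting near the 0.01 mask at
this reduced session size. `runPipeline()` chains all of the above for
multiple subjects and writes every table (pair and region deltas, responder
summaries, SNR/permutation results, hubs, seed maps, a run manifest and a
plain-text report) to an output directory; `writeSession()`/`readSession()`
serialize sessions as float32 + YAML + TSV bundles, and
`inst/cli/stimcoherence.R` exposes `simulate` and `run-all` subcommands for
shell use.

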