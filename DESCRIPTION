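Package: stimCoherence
Title: Stimulation-Evoked Intracranial Coherence Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of stimulation-evoked functional connectivity
    in multichannel intracranial EEG (sEEG) recordings. Implements
    preprocessing (highpass, line-noise channel rejection, common average
    referencing, notch filtering, epoching, amplitude-based trial rejection,
    downsampling), per-epoch magnitude-squared coherence via Welch
    cross-spectra, baseline-subtracted region-pair connectivity, and the
    associated nonparametric statistics: Friedman and Kruskal-Wallis tests,
    exact and approximate Wilcoxon signed-rank tests with r = |Z|/sqrt(N)
    effect sizes, exact multinomial goodness-of-fit by full enumeration,
    Cohen's d responder classification, signal-to-noise permutation testing,
    hub-pair detection and thresholded seed-region coherence maps. A
    synthetic-session generator with known ground-truth coupling structure,
    line-noise and spike artifacts supports parameter-recovery testing of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, signal, yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
biocViews: Electrophysiology, Coherence, TimeCourse, Preprocessing
RoxygenNote: 7.3.3
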