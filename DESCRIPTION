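Package: somnostat
Title: Sleep Homeostasis and Circadian Quantification from Epoch-Scored EEG
Version: 0.1.0
Authors@R:
    person("Somnostat", "Developers", email = "somnostat@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying sleep homeostasis and circadian
    rhythmicity in rodent electrophysiology studies built around a 72-h
    baseline / 12-h sleep-deprivation / recovery protocol.  Implements
    epoch-level EEG spectral analysis on a fixed 0.244-Hz FFT grid,
    vigilance-state time budgets, NREMS delta-power time courses with
    equal-epoch interval partitioning, slow-wave-energy accumulation,
    waking-band time courses during sleep deprivation, chi-square
    periodogram period estimation from wheel-running activity, one-way
    intraclass correlation statistics, and a dual-criterion (BH-adjusted
    t/ANOVA and rank-product PFP) differential-expression stage for
    expression matrices.  A seeded synthetic-data generator emulating
    genotype-dependent hypnograms, state-conditional spectra driven by a
    two-process homeostat, free-running activity rhythms and expression
    matrices with planted fold changes makes every stage verifiable
    without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
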