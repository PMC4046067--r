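---
title: "somnostat: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{somnostat: models, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

somnostat quantifies sleep homeostasis and circadian rhythmicity for a
classical rodent protocol: a 24-h baseline day, 12 h of enforced
wakefulness starting at light onset (zeitgeber time, ZT 0), and 36 h of
recovery, recorded as 4-s epochs scored wake (W) / NREM sleep (N) / REM
sleep (R) with matching EEG power spectra. This vignette explains the
models behind each stage, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the numerical
decisions a maintainer would want written down.

## The spectral grid

Epochs hold 4 s x 250 Hz = 1000 samples, but the conventional printed
resolution of 0.244 Hz implies a 1024-point transform; `epoch_psd()`
therefore Hann-windows the 1000 samples and zero-pads to 1024 (the
alternative — overlapping 1024-sample windows — would mix neighboring
epochs and contradict per-epoch scoring). Bin `k` sits at `k * 250/1024`
Hz and the retained analysis grid is bins 4–196 (0.98–47.85 Hz at 2-dp
printing, 193 bins).

Band membership compares bin-center frequencies *rounded to the printed
2-dp precision* against the closed band interval. This matters at one
place: bin 4 sits at 0.9766 Hz, below the printed 0.98-Hz delta edge; the
rounding rule keeps it inside, giving exactly delta = bins 4–16,
upper theta (8.5–11 Hz) = 35–45, beta-2 (20–35 Hz) = 82–143, and gamma-1
(35–48 Hz) = 144–196 after clipping to the retained grid (the nominal
48-Hz edge lies beyond the top retained bin).

State spectra are means over artifact-free epochs of one state,
expressed per bin as a percentage of the summed power over all 193 bins
(each normalized spectrum sums to 100). The REM theta peak frequency is
the argmax *within 5–9 Hz* so that broadband delta can never win; ties
break toward the lower frequency, and a `global = TRUE` escape hatch
searches the full grid.

## Time budgets and accumulated differences

`state_percentages()` counts artifact-flagged epochs with their scored
state: artifacts contaminate power estimates, not the visual state
scoring, so they are excluded only from spectral averages. REMS as a
percentage of total sleep time is undefined on a sleep-free bin
(deprivation blocks) and reported as `NA`, not 0.
`accumulated_state_difference()` matches each post-baseline hour to the
same ZT hour of the single baseline day and cumulates the per-hour
minute differences; incomplete trailing hours are dropped with a warning.

## Delta time course, rebound, slow-wave energy

NREMS delta power (mean power over bins 4–16) is averaged within
equal-epoch intervals: the artifact-free NREMS epochs of each 12-h window
are split chronologically into 12 (baseline light), 5 (baseline dark), 9
(first recovery dark), 11 (recovery light) and 6 (second recovery dark)
contiguous groups of size `floor(m/n)` or `ceiling(m/n)`. Remainder
epochs go to the *earliest* intervals, keeping the early-recovery
intervals — where the dynamics are fastest — at least as well sampled.
Interval timestamps are the mean ZT of member epochs (needed for
plotting; any convention would do).

Each subject's time course is normalized to its mean NREMS delta power
over ZT 8–12 of the baseline light period, the lowest level reached
during baseline. The immediate rebound is the first recovery interval as
a percentage of the last pre-deprivation interval. Slow-wave energy (SWE)
sums delta power over each hour's artifact-free NREMS epochs (an hour
without NREMS contributes zero energy, not a missing value), differences
against the matching baseline hour, cumulates, and scales by the total
baseline-day delta energy. The final accumulated value telescopes to a
direct non-cumulative computation, which the tests verify, and every
normalized output is invariant to a global rescaling of power.

Waking-band time courses during deprivation express mean
upper-theta/beta-2/gamma-1 power over artifact-free waking epochs — per
clock hour or per 36 equal-waking-epoch intervals — as a percentage of
the baseline-light waking mean. Epochs are weighted equally within an
hour (the plausible alternative, averaging within-hour interval means,
is indistinguishable at these epoch counts).

## The synthetic generator: a stated world

The generator's job is to produce data with the statistical structure the
analyses assume, under parameters fixed once from published group values.
It emulates:

* **Hypnograms** — a semi-Markov bout chain with geometric bout lengths.
  Occupancy targets per 12-h window are the published group-mean state
  percentages of the three genotypes (wild type and the 4- and 5-repeat
  PER3 VNTR knock-in lines); printed triplets can sum to 100.1%, so the
  loader renormalizes each row. Bout scales (light: W 65 / N 60 / R 25
  epochs; dark: W 250 / N 48 / R 16) were chosen once as mouse-plausible
  values satisfying the flow-balance feasibility constraints
  (`r_W <= r_N`, `r_R <= r_N`, routing probabilities in [0,1]); REM is
  entered only from NREM. Deprivation is forced wakefulness with an
  isolated NREMS leak (~1%, genotype-specific) and no REM. Artifacts are
  independent flags at rate 0.03 (97% artifact-free), not waveform
  corruption, because the pipeline consumes spectra.
* **Spectra** — state templates (1/f background; wake theta bump; REM
  theta peak at the configured frequency) with the NREM delta bins
  *exactly proportional* to a two-process homeostat S: rising toward the
  upper asymptote in wake with tau 8 h, decaying toward the lower
  asymptote in sleep with tau 1.5 h (asymptotes 0.05/1.0). The protocol
  gives no quantitative S time course for these mice; these constants are
  conventions, and only relative behavior is asserted in tests.
  Multiplicative lognormal noise (sd 0.2) on every bin.
* **Rebound calibration** — the published immediate rebound (198.15% for
  the 5-repeat line, 168.46% for the 4-repeat line) cannot coexist with a
  purely S-proportional delta series, because S decays within the first
  recovery interval. The generator therefore rescales the recovery-dark-1
  delta drive by one constant, computed against the same equal-epoch
  partitions the analysis uses, so the noiseless immediate rebound equals
  `100 * rebound_gain` exactly; `calibrate_rebound = FALSE` restores the
  pure S series (on which the conservation test runs). A side effect is
  that later recovery intervals ride at the calibrated level rather than
  the raw S level; the package treats the rebound as the calibrated
  quantity and the rest of recovery as qualitative.
* **Deprivation band gains** — waking upper-theta/beta-2/gamma-1 bins are
  multiplied by `1 + (g-1) * (1 - exp(-t/tau))` with tau = 1 h: an
  immediate, lasting increase whose peak equals the configured gain
  (upper-theta default 2.4, the published maximum fold increase).
* **Activity** — per-minute Poisson counts around a thresholded sinusoid
  with period `period_hr + light_slope * log1p(intensity)` (23.7 h +
  0.12 h per log-unit of mW/m^2), activity onset at subjective dark.
* **Expression** — per-gene Gaussian (log2) baselines, per-array offsets
  so percentile normalization is nontrivial, and planted +/- log2 fold
  changes with recorded truth labels.
* **Grouped values for ICC** — see below.

It does **not** emulate: raw EEG waveforms or EMG, state-transition
refractoriness beyond the bout model, circadian modulation of the
spectral templates, ultradian light-suppression behavior, probe-level
array structure, or any between-subject correlation. A green test
therefore establishes that the *analysis* recovers what the generator
planted under realistic sampling noise — not that the generator is a
faithful biophysical model.

## ICC calibration

The intraclass correlation here is the ratio of between-genotype to
total variance, estimated by one-way method-of-moments
(`sigma2_b = max(0, (MSB - MSW)/n0)`, CI from the F pivot, truncated to
[0, 1]). With only two groups the estimator is strongly biased at any
fixed true fraction: simulating random group effects with a true
fraction of 0.48 yields a mean estimate near 0.32, and naive fixed
effects near 0.43. Published ICCs *are* outputs of this estimator, so the
generator calibrates on the estimator scale: group effects are fixed at
+/- d with d solved — deterministically, via the noncentral-F
representation of the estimator — so that the expected estimate equals
the configured fraction. Fractions below the estimator's null mean
(~0.17 at 8 + 8; the truncation at zero gives the null a positive mean)
are unreachable and rejected with an explanatory error.

## Chi-square periodogram

For each candidate period P (whole minutes, default 20–28 h in 1-min
steps) the series is folded over its complete cycles and
`Q_P = K * N_P * Var(column means) / Var(x)`, compared against the
chi-square (N_P - 1) quantile at alpha = 0.05. One numerical choice
matters: Q scales with the amount of data actually used, so candidates
sitting at an integer number of complete cycles of the record use up to
one extra cycle and Q snaps the peak there (a noiseless 24.12-h sinusoid
in a 10-d record peaks at exactly 24.0 h). The peak is therefore selected
on the folded-variance *ratio* `Var(column means)/Var(x)` — Q divided by
the data-quantity term — while Q itself and its significance line are
unchanged. Free-running periods per light condition use the trailing 10
days of each condition.

## Differential expression

Arrays are normalized by shifting each sample's 75th percentile (log2
subtraction; percentile by linear interpolation, R quantile type 7; a
linear-scale division variant exists behind `scale = "linear"`). Genes
are tested by pooled-variance unpaired t (Welch behind a flag; one-way
ANOVA for >2 groups) with Benjamini–Hochberg correction across genes,
and by rank product: genes ranked by fold change within every
cross-group sample pair, RP = geometric mean of ranks, both directions.
A gene is differentially expressed when BH-adjusted p < 0.05 *or*
PFP < 0.015; zero-variance degenerate rows fall back to p = 1 and remain
reachable through the rank-product path.

The PFP null deserves a note. Permuting ranks independently within each
comparison understates the observed null's lower tail when all `n1*n2`
cross pairs are used, because pairs sharing a sample are positively
correlated — measured here as a ~3x discrepancy at the 0.1–1% null
quantiles and ~12% spurious PFP < 0.015 calls on pure-null matrices. The
default null therefore permutes sample labels and recomputes the full
statistic (pooling both directions); the independent-rank null remains
available (`null_method = "rank"`) and is the variant the exhaustive
5-gene enumeration oracle verifies.

One behavior worth knowing: anchoring the 75th percentile under strongly
asymmetric differential expression (many up-regulated genes in one group)
pulls null genes slightly in the opposite direction, so recovered "down"
counts run a little above the planted truth. This is a property of
percentile-anchor normalization, not a defect of the test stage.

Ranking for follow-up takes DE-flagged genes by decreasing absolute log2
fold change, ties broken by smaller adjusted p, then gene id, truncated
to the top 200 by default.

## Known limitations

* The generator's recovery delta level beyond the first interval is a
  by-product of the rebound calibration, not an independently calibrated
  quantity; SWE recovery trajectories are qualitative.
* Mixed-model ANOVAs of the original protocol are out of scope; the
  pipeline emits tidy long-format tables so they can be run externally.
* The chi-square periodogram's significance line treats candidates
  independently; the ~5% null exceedance is per candidate, not
  family-wise.
* Asymptotic Kruskal–Wallis p-values at very small group sizes deviate
  from the exact permutation distribution by up to ~0.1; the tests
  document this tolerance explicitly.
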