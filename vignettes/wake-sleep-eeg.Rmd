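---
title: "Wake and sleep EEG topography in cognitive decline: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wake and sleep EEG topography in cognitive decline: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleeptopo)
library(dplyr)
```

`sleeptopo` implements the statistical workflow of three-group
(Alzheimer's disease / mild cognitive impairment / healthy elderly)
wake–sleep EEG studies: macrostructure scoring, state-resolved band-power
topography, channel-wise group inference under false-discovery-rate
control, the EEG slowing index and the overnight delta-power change, and
the correlation analyses that tie these indices to each other and to
cognition. This vignette documents the models, the tunable parameters, the
numerical choices, and what the synthetic validation cohort does and does
not establish.

## Sleep macrostructure

A hypnogram is one stage code (W, N1, N2, N3, R) per scoring epoch
(default 30 s), with lights-off/lights-on indices delimiting the in-bed
period. `score_macrostructure()` computes the conventional variables over
that window. Three scoring conventions are deliberate choices, since
operational definitions vary across laboratories:

- **Sleep onset** is the first epoch of *any* sleep stage — N1 counts. No
  multi-epoch persistence rule is applied.
- **WASO** counts wake epochs strictly between sleep onset and the final
  sleep epoch; terminal wake before lights-on is excluded (it is neither
  latency nor intra-sleep wake). One **intra-sleep awakening** is one
  maximal run of one or more W epochs inside that interval.
- Metrics that are undefined on a night without sleep (latencies, WASO,
  stage percentages) are explicit `NA`, never silently zero; total sleep
  time and sleep efficiency are genuinely 0 in that case.

These conventions give the exact identity
TBT = SOL + TST + WASO + terminal wake, which the test suite asserts on
random hypnograms.

`anova_from_summary()` and `ttest_from_summary()` exist because published
macrostructure tables report only group means, SDs and n. With
SSB = Σ nᵢ(mᵢ − m̄)² and SSW = Σ (nᵢ−1)sdᵢ², the omnibus
F = (SSB/(k−1))/(SSW/(N−k)) is fully determined by the summary row, and the
pooled-variance t likewise. `reproduce_reference_table()` runs both against a
bundled reference table of a published 50/50/50 cohort; all rows whose
inputs survive 2-decimal rounding reproduce the printed F and t to two
decimals (three rows — N1%, N3%, REM latency — are rounding-limited in the
source and flagged `exact = FALSE`).

## Spectral estimation

Band powers are Welch estimates: 4-s Hann-windowed segments, 50% overlap,
mean-detrended per segment, one-sided density scaled so that its integral
over [0, fs/2] equals the signal variance. The 4-s window gives 0.25 Hz
resolution — finer than any band edge — and at the default 300 s of signal
per state yields ~150 averaged segments, i.e. a per-cell log₁₀-power
estimation noise of roughly 0.03–0.08, comparable to the table-mode
residual below. Band power is the trapezoidal integral of the density over
the half-open band [low, high); edges are interpolated so adjacent bands
tile exactly and band powers are additive over a partition.

The default band scheme is delta [0.5, 5), theta [5, 8), alpha [8, 12),
sigma [12, 16), beta [16, 25) Hz: contiguous half-open intervals whose
delta+theta union covers the low-frequency range whose elevation defines
EEG slowing, with sigma spanning the spindle band. Every analysis accepts
any valid `band_scheme()`; the scheme is a parameter, not an assumption.

Artifact handling is a single declared rule: consecutive epochs (default
4 s, matching the Welch window) are dropped when any channel exceeds
300 µV in absolute amplitude or is flat; the threshold is configurable and
the rule is exercised directly in tests. Group statistics operate on log₁₀
absolute power, which symmetrises the right-skewed power distribution;
linear power is retained wherever a ratio of powers is computed.

## Channel-wise inference and FDR

`anova_map()` runs a classical fixed-effects one-way ANOVA per channel ×
band cell of one behavioral state, on log₁₀ power. The FDR family is *all
channels × bands of that state's map* — one Benjamini–Hochberg step-up per
family, yielding a single data-dependent threshold per figure-equivalent,
never a hard-coded p cutoff. Post-hoc pairwise pooled-variance t tests
(two-sided, α = 0.05, uncorrected) are computed only where the omnibus
test survives FDR. Missing data are handled listwise per analysis, with the
excluded subjects named in a warning, so per-analysis Ns can differ exactly
as they do in real cohorts.

The Group × Time-of-day interaction for the overnight contrast is computed
as a one-way ANOVA across groups on per-subject difference scores
(AM − PM log₁₀ power). With a two-level within factor this is *exactly*
the mixed-design interaction F — the test suite asserts equality against
`aov(y ~ group * time + Error(subject/time))` at 1e−8 — while remaining
trivially vectorizable across channels.

Two numerical conventions: an all-identical sample yields F = 0, p = 1
(no variance to explain, not an error), and a zero-variance contrast with a
non-zero mean yields an infinite-t sentinel with p = 0 rather than a crash,
using the same degeneracy criterion as `t.test()`.

## The slowing index and the overnight delta change

The slowing index is (P_delta + P_theta)/(P_alpha + P_sigma + P_beta) on
*linear* absolute power — a ratio of powers as defined, so it is invariant
to overall scale (re-referencing gain, unit changes) and strictly monotone
in each constituent band. It is computed on state-pooled band powers (one
ratio per subject × channel × state), not averaged across epochs; with
stationary per-state spectra the two orders coincide in expectation and the
pooled form is the lower-variance estimator. All five powers must be
present and positive; otherwise the cell is `NA`, logged.

The overnight change is AM log₁₀(delta) − PM log₁₀(delta) per channel;
negative means delta activity fell across the night (intact sleep-related
restoration). Downstream correlation analyses seed from single
representative channels — F4 for the overnight delta change and O1 for REM
slowing, both configurable — matching the sites where these effects are
typically maximal.

## Correlations and the severity trend

Pearson correlations use the t transform on n − 2 df; Spearman is defined
as Pearson on average ranks with the same t-transform p, which makes the
rank-invariance property exact and testable. Deletion is pairwise-complete,
again so per-analysis Ns float. Correlation maps share the BH machinery of
the ANOVA maps (one family per map). A p-value that underflows to zero at
|r| = 1 is clamped to the smallest positive double so the step-up remains
well-defined.

The across-severity trend fits ordinary least squares of z = atanh(r) on
the group ordinal HC = 0, MCI = 1, AD = 2, reporting slope β and R² only —
descriptive quantification of how coupling strength grows with disease
severity, not inference, which is why no p-value is attached. MMSE
correlation maps pool all three groups (the clinically interesting
question is the continuum, and group-wise n would be too small for stable
maps); whether to control for group membership is left to the user, and
partial correlations are out of scope.

## The synthetic cohort: what it emulates

Because patient-level EEG from such cohorts is not publicly deposited, the
generator is a first-class module that encodes the study conditions. Each
subject carries a latent severity d ~ N(group mean, 0.3) with group means
HC = 0, MCI = 0.5, AD = 1; planted topographic effects scale with d at
0.3 log₁₀ units per unit severity:

| state | band | channels | direction |
|---|---|---|---|
| NREM | alpha | T3, T5 | down |
| NREM | sigma | posterior ring (T5, P3, Pz, P4, T6, O1, O2) | down |
| REM | delta | frontotemporal | up |
| REM | alpha, sigma, beta | T5, T6, O1, O2 | down |
| PM/AM wake | delta | frontotemporal | up |
| PM wake | alpha | O1, O2 | down |

A subject intercept u ~ N(0, 0.12) induces realistic within-subject
correlation across cells; residual cell noise has SD 0.08 (table mode).
Wake baselines put ~14 µV² in alpha and ~20 µV² in delta; NREM raises
delta to ~63 µV² and sigma to ~7 µV² — typical absolute magnitudes for
elderly scalp EEG. The overnight delta change at the frontal–central–P3
channels is drop(group) + coupling(group)·(d − mean d) + noise with drops
HC = −0.15, MCI = −0.08, AD = 0 log₁₀ units: healthy subjects lose ~30% of
waking delta power overnight, AD none. The AD coupling of 0.8 makes the
observed correlation between the overnight change and posterior NREM
high-frequency power ≈ −0.47 once session noise is included, the magnitude
reported in this literature; with this noise model the attainable ceiling
is ≈ −0.53. MMSE = round(clip(30 − 6·d + N(0, 1.5), 0, 30)), giving group
means near 30/27/24 and a strong pooled negative MMSE–slowing correlation
(by design somewhat stronger than clinical samples show).

Hypnograms use a two-phase model: a geometric onset run whose expected
length equals a gamma-distributed subject latency target (group means and
SDs from the bundled macrostructure table), then a row-stochastic Markov
chain over stages whose default rows equal the target stationary occupancy
— wake fraction ~0.21–0.24 of the sleep period, stage splits per group,
the subject's N3 percentage drawn from a group gamma. Monte-Carlo tests
confirm SOL and N3% recover their targets within 3 SEM.

Signal mode synthesizes each channel as a sum of band-limited Gaussian
noise components sharing one white-noise spectrum masked to disjoint bands,
each rescaled to its exact target variance — so total variance equals the
sum of band targets exactly, and Welch recovery is within 5%. Table mode
draws log₁₀ powers directly from the same model; both modes agree in
distribution (tested via group means on matched specs).

**What passing tests do not show about real data.** The generator is
stationary band-limited noise: no spindles or K-complexes as discrete
events, no 1/f background, no artifacts beyond the injected test spikes, no
circadian structure, no REM-latency realism (the occupancy chain produces
short REM latencies), and effect magnitudes are planted rather than
estimated from patients. Pipeline validation on this cohort establishes
*statistical correctness* (calibration, sensitivity, equivalences), not
clinical generalisability.

## Calibration properties and problem sizes

The test suite and the acceptance script exercise the pipeline at sizes
chosen to make the statistical claims sharp while keeping a full run on a
single core in minutes: 1000 null cohorts at n = 20/group for the
false-discovery calibration (observed rate of maps with any BH discovery
≈ 0.02–0.05, at or below the nominal 0.05 — below it because the shared
subject intercept induces positive dependence among cells, under which the
step-up is conservative); nine planted cohorts at n = 50/group for
sensitivity (≈ 1.0 at 0.3 log₁₀ effects) and specificity. Note that BH at
q = 0.05 *permits* an occasional false-positive cell outside the planted
regions — with ~9 strong true positives in a 95-cell family the expected
count of null-cell discoveries is ≈ 0.4 per map — so exact containment of
discoveries in the planted cells is itself a stochastic event (probability
≈ 0.6–0.7 under these conditions), and the suite tests it across
replicates rather than demanding it of every map.

## Known limitations

- EDF ingestion is not implemented; signals enter as in-memory matrices or
  via the generator, and the TSV band-power table is the interchange
  format between modules.
- The Welch estimator is the only spectral backend (no multitaper).
- Post-hoc t tests are uncorrected beyond the omnibus FDR gate, by design
  parity with the analysis convention this package mirrors.
- The severity trend is descriptive; comparing dependent correlations
  formally would need Steiger-type tests, which are out of scope.
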