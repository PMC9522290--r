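---
title: "Quantifying inter-scorer agreement in manual and computer-assisted PSG scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying inter-scorer agreement in manual and computer-assisted PSG scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psgagree)
```

## The problem

Scoring a polysomnographic (PSG) recording — assigning sleep stages and
marking leg movements, apneic-related respiratory events, EEG arousals and
oxygen desaturations over a whole night — is slow and subjective. When the
same night is scored by several trained technicians, their annotations
disagree to a degree that depends on the task, and the scoring itself takes
tens of minutes per task per recording. A computer-assisted
(*semi-automatic*) workflow, in which an automatic algorithm produces a
first-pass scoring that the expert then reviews and edits, promises both
faster scoring and better between-scorer consistency, because all scorers
start from the same draft.

`psgagree` implements the complete measurement framework for this question:
it represents multi-scorer annotation sets, discretizes them onto analysis
grids, quantifies pairwise agreement and its change between scoring
conditions, derives the standard diagnostic indices and their inter-scorer
reliability, and reproduces the difficulty-stratified procedure by which
study recordings are selected. A synthetic-study generator with explicit
scorer-corruption models makes every stage of the pipeline testable without
access to clinical data.

## Data model

An **annotation** is a labeled half-open interval `[onset, onset + duration)`
in seconds from recording start, with labels from a registered vocabulary
(stages `W/N1/N2/N3/R`, `lm-left`/`lm-right`, apnea subtypes, `hypopnea`,
`rera`, `arousal`, `desaturation`, lights markers). All scoring is
restricted to the time in bed (TIB) between the `lights-off` and
`lights-on` markers; events are clipped to it on input and zero-length
residues are dropped. Onsets are always recording-anchored (the EDF+
convention); TIB-relative times are derived, never stored. Two half-open
intervals that abut exactly are distinct — this makes overlap tests on a
discretized grid unambiguous and order-free.

Files are read either from a plain tabular dialect
(`label,onset_s,duration_s`) or from the EDF+ annotation (TAL) syntax —
onset with a `+`/`-` prefix, optional duration after a 0x15 byte, label
text terminated by 0x14, records separated by 0x00. Only the annotation
track is handled; the analysis consumes scorings, not signals. Because
exported label strings vary between scoring software, labels pass through a
user-extensible alias map (`register_aliases()`) before validation.

A study is the cross of recordings × scorers × methods (manual /
semi-automatic) × tasks (staging, leg movements, respiratory events, EEG
arousals), with recordings selected per task. `load_study()` assembles it
from a YAML manifest and reports missing cells rather than skipping them;
inconsistent lights markers across scorers of one recording are an error.

## Agreement model

Agreement is computed on task-specific grids: 30 s five-class epochs for
staging, and 0.5 s binary mini-epochs for the event tasks, where a
mini-epoch is `present` iff it has a positive-length intersection with a
scored event. A trailing partial epoch (TIB not divisible by the step) is
dropped; every scorer shares the TIB, so no pair is ever misaligned. From
each scorer pair's aligned sequences a k×k contingency table is built
(k = 5 or 2) and Cohen's kappa

$$\kappa = \frac{p_o - p_e}{1 - p_e}, \qquad
  p_o = \tfrac{1}{n}\sum_i n_{ii}, \quad
  p_e = \tfrac{1}{n^2}\sum_i n_{i\cdot} n_{\cdot i}$$

is computed, unweighted even for the five-class staging table. With 12
scorers there are 66 pairs per recording, hence 330 matched kappas per task
over 5 recordings. Degenerate tables — either rater constant, as happens
for all-absent event sequences on quiet recordings — are flagged; when
both raters are constant on the same category, kappa is defined as 1 for
perfect agreement and 0 otherwise.

Contexts restrict the compared epochs: for leg movements, wake and sleep
masks are taken from the shared pre-filled clinical hypnogram (the only
hypnogram common to all scorers in non-staging tasks — never a rescored
one); for respiratory events, label subsets
{apnea+hypopnea+RERA, apneas, hypopneas} are discretized separately. For
leg movements the left- and right-leg kappas are computed per channel and
averaged per pair before any statistics; the `n` attached to the averaged
result is the summed epoch count (the natural choice, though nothing
downstream depends on it).

## Diagnostic indices and ICC(A,1)

From each scorer's annotations the package derives sleep-quality parameters
(SE, SOL, WASO, stage-R latency, TST, TIB; sleep onset is the first non-W
epoch, and WASO is defined through the identity TIB = SOL + TST + WASO)
and event indices per hour of TST: AI, HI, AHI = AI + HI (RERAs are scored
with respiratory events but never counted in the AHI), ODI, ArI, LMI and
PLMI. Leg-movement indices follow the WASM2016 rules: movements on opposite
legs with an end-to-onset gap below 0.5 s merge into bilateral movements;
after combination, movements shorter than 0.5 s are discarded and duration
caps apply (10 s monolateral, 15 s bilateral, both configurable); periodic
movements are maximal runs of ≥ 4 with onset-to-onset intervals in
[10, 90] s. A movement is respiratory-related when its onset falls between
2.0 s before and 10.25 s after the end of a scored apnea/hypopnea; the PLMI
*includes* respiratory-related movements by default (a compatibility flag
reproduces the convention of the study this framework targets; switching it
off gives the conventional exclusion).

Inter-scorer reliability of each index is the two-way, absolute-agreement,
single-measures intraclass correlation ICC(A,1) (McGraw & Wong case A,1) on
the recordings × scorers matrix:

$$\mathrm{ICC}(A,1) = \frac{MSR - MSE}
  {MSR + (k-1)\,MSE + \tfrac{k}{n}(MSC - MSE)}$$

with 95% confidence intervals and a significance test of
`H0: ICC = r0` via the case-A,1 F approximation with Satterthwaite degrees
of freedom. The package tests one-sided against `ICC > r0`: the analysis
frames `r0` as a baseline to be exceeded — by default the semi-automatic
condition is tested against the ICC achieved under manual scoring
(`icc_r0_policy = "manual_baseline"`). No installed package provides this
variant with the r0 test, so it is implemented from the ANOVA mean squares
directly and cross-checked in the tests against an independent `aov()`
decomposition (to 1e-10) and against an external reference implementation.

## The comparison battery

Distributions are summarized as median and IQR (linear interpolation,
quantile type 7 — the most common default, chosen so results are
reproducible bit for bit). Manual vs semi-automatic differences are tested
with the paired Wilcoxon signed-rank test (zeros dropped; exact null for
n ≤ 25 — full sign-assignment enumeration up to n = 16 so tied ranks stay
exact, the signed-rank distribution otherwise; normal approximation with
continuity correction above) at α = 0.05 per test, with no
multiple-testing correction — each comparison is reported at face value.
Effect sizes are the paired Cohen's d on the differences
(`d = mean(d)/sd(d)`, sample sd): the tests are paired, so the
paired-differences variant is the consistent choice; its sign is positive
when the quantity is larger under manual scoring. Scoring-time gains are
ratios of median times, reported to two decimals. Variance differences use
the Brown-Forsythe test (Levene with median centering) after dividing each
group by its own mean: the goal of the normalization is to remove location
bias from a dispersion comparison, which "divide by mean" accomplishes
while keeping the statistic scale-invariant; degenerate denominators are
resolved explicitly (F = 0, p = 1 when both variances vanish; F = ∞, p = 0
when only the within-group deviations do).

## Recording selection

Study recordings are selected per task from a large candidate pool by a
difficulty surrogate: K_ac, the kappa between each recording's automatic
and clinical scorings, computed with the exact task discretization above.
The recordings nearest the 12.5th, 37.5th, 50th, 62.5th and 87.5th
percentiles of the K_ac distribution (linear interpolation) are selected
without replacement in ascending percentile order, ties broken toward the
lower recording id. Nearest-value matching (rather than rank position) is
the package's documented choice; the procedure is deterministic, and with
nine or more candidates the extremes are never selected — the point of the
design.

## The synthetic study generator

`generate_study()` produces a complete study at the design scale — 12
scorers × 2 methods × 4 tasks × 5 recordings, i.e. 40 exercises per scorer
— from one master seed, with every random draw routed through named
substreams so a fixed seed reproduces the study byte for byte.

**Ground truth.** Each recording's hypnogram is a first-order Markov chain
on 30 s epochs starting in W at lights-off (TIB 7.3 h, matching a typical
clinical night); events are homogeneous Poisson processes over sleep time
at configured rates, plus explicit periodic leg-movement trains (run
lengths 4–12, IMIs 15–45 s, partly bilateral) and desaturations coupled to
respiratory events. A fraction (0.2) of leg movements is placed during
wake, since leg activity — unlike the other event types — persists into
wakefulness. Because real study recordings come from different patients,
each recording draws its own severity factors (log-normal respiratory,
leg-movement and arousal severities; a wake-propensity draw governing sleep
efficiency): this between-recording variance is exactly what makes the
index ICCs meaningful, and without it they collapse.

**Scorers.** A scorer is a noise channel: stage epochs are resampled with
probability *e* from a confusion kernel (uniform over the four other
stages by default); events are kept with a sensitivity, their boundaries
jittered with Gaussian noise, and false positives added as a Poisson
process. Respiratory scoring uses per-label multipliers — apneas are
detected more reliably and delimited more sharply than hypopneas — which
reproduces the well-known apnea > hypopnea agreement ordering. The
semi-automatic condition is modeled as all scorers independently editing
one shared automatic draft (itself a corruption of the truth): the shared
anchor induces the positive between-scorer correlation that raises kappa.
This mechanism is a modeling choice, not an inference — the true dependence
structure between scorers editing a common draft is not identifiable from
aggregate agreement data.

**Calibration.** The corruption parameters per task and method are fixed
package defaults, chosen once so that a full-scale simulated study lands
near the agreement levels reported for experienced single-center panels
(`kappa_reference()`: manual/semi-automatic medians of 0.76/0.80 for
staging, 0.72/0.91 for leg movements, 0.55/0.66 for respiratory events,
0.58/0.65 for arousals). For staging this calibration has a closed form —
two independent symmetric-noise channels with error *e* give
`p_o = (1-e)² + e²/4` — which the tests verify by Monte Carlo; the binary
event tasks were calibrated by simulation. Scoring times are log-normal
with medians and IQR-derived spreads from `scoring_time_reference()`, plus
per-scorer pace and per-scorer-per-task proficiency factors shared across
the two methods, so the within-scorer pairing gains power exactly as it
does in the real design.

**What the generator does not emulate.** No signal-level realism (events
are placed uniformly in sleep rather than clustering in REM or
supine periods); no intra-scorer drift between the two scoring moments;
no systematic scorer bias (one scorer consistently over-calling); stage
confusions are uniform rather than concentrated between adjacent stages
(N1 is not preferentially confused with W and N2); and scorer errors are
independent across scorers given the input, except through the shared
draft. Passing tests therefore demonstrate that the measurement pipeline
is correct and well-calibrated, not that these levels of agreement will be
observed in any particular clinic.

## Numerical choices and degenerate inputs

* Epoch overlap requires strictly positive intersection; an event ending
  exactly at an epoch's start does not mark it (half-open convention).
* Trailing partial mini-epochs are dropped (`floor(TIB/step)`).
* Kappa degeneracy: flagged when either rater is constant; defined
  conventionally when chance agreement is 1.
* ICC is refused on an all-equal matrix (no subject variance) and on
  incomplete matrices; `r0` must lie in `[0, 1)`.
* Wilcoxon with every difference zero returns statistic 0, p = 1, flagged.
* Cohen's d with zero difference variance is undefined and flagged, not
  forced to ±∞.
* All-wake hypnograms leave SOL and stage-R latency undefined and SE = 0.
* Seeds derived from the master seed stay below 2³¹ (R's integer range).

## Problem sizes in the tests

The test suite exercises the full-scale study (12 × 2 × 4 × 5, TIB
7.3 h, 52 560 mini-epochs per scoring) once end to end — about half a
minute — and uses reduced designs (2–4 scorers, 1–2 h TIB) for the
module-level properties; Monte-Carlo checks use 10⁵ epochs for the
near-zero-kappa bound, 50-seed batches for Poisson concentration, 20-seed
batches for index-range coverage, and n = 5000 draws for the timing-median
recovery (within 5%). Exact Wilcoxon enumeration is verified against all
2ⁿ sign assignments for n ≤ 10.

## Known limitations

The framework measures agreement between scorings; it deliberately has no
notion of which scorer is *right*, and event-level matching schemes
(onset/offset tolerances, F1 scores) are out of scope — only the
epoch-overlap scheme is implemented. Apnea subtype labels are taken as
given, not re-derived. The semi-automatic improvement the generator
produces is built into its design; analyses of real studies should treat
the generator only as a verification harness, not as evidence.
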