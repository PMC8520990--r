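---
title: "Modeling and estimating cochlear gain reduction from forward masking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and estimating cochlear gain reduction from forward masking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mocgain)
```

## The scientific problem

The medial olivocochlear reflex (MOCR) is an efferent feedback loop from the
brainstem to the cochlear outer hair cells. Sound activates it with an onset
delay of roughly 25 ms, and its effect is to reduce the low-level gain of the
cochlear amplifier. Psychoacoustically, this gain reduction can be probed
with forward masking: a *precursor* sound, presented before a brief masker
and signal, elevates the signal's detection threshold, and the pattern of
that elevation across conditions discriminates gain reduction from the
competing account -- additivity of masking with a static cochlear
nonlinearity.

`mocgain` implements the whole chain needed to model, simulate and analyse
such experiments: a mechanistic listener model, power-spectrum-model
threshold predictions under both competing hypotheses, a Monte-Carlo
simulator of the adaptive tracking procedure, the estimation pipeline
(gain-reduction estimates, summary t-tests with Holm-Bonferroni correction,
floor filtering, mixed-effects growth models), and synthetic-cohort
generators that make every stage testable end to end.

## The listener model

### Cochlear input-output function

The basilar-membrane response at the place tuned to the signal frequency is
modeled as a two-segment ("broken-stick") input-output function
`io_function(G, c, BP)`: linear with slope 1 and gain `G` dB below the
breakpoint `BP` (dB SPL), compressive with slope `c` (0 < c <= 1) above it.
A two-segment form was chosen over smooth sigmoids because it makes the
gain-reduction identities exact and testable: reducing gain by
`dG` (`apply_gain_reduction`) lowers every output below the original
breakpoint by exactly `dG` and leaves every output above the pivot
`BP + dG/(1 - c)` untouched, so high-level responses are provably
unchanged. (For the degenerate fully linear curve `c = 1` no pivot exists
and the whole line is lowered; a "below-BP-only" shift would make the curve
discontinuous, which we do not allow.)

```{r}
io <- io_function(gain_db = 40, compression = 0.2, breakpoint_db = 40)
io_output(c(30, 40, 60), io)
io_output(c(30, 60), apply_gain_reduction(io, 10))
```

### Place excitation and frequency routing

A stimulus's drive at the signal place depends on its spectral relation to
the signal frequency (4 kHz throughout the default designs):

* a tone within one ERB of the signal frequency is *on-frequency* and passes
  through the (possibly gain-reduced) input-output function;
* a tone further away is *off-frequency*: nearly an octave below the signal
  it is processed linearly at the signal place, `level - A`, where the
  attenuation `A` is a free per-listener parameter (the package deliberately
  does not commit to an auditory-filter shape, so `A` is calibrated from
  matched-masker pairs rather than derived);
* a broadband noise enters at its dB/ERB level -- the level falling inside
  one equivalent rectangular bandwidth at the signal place,
  `ERB(F) = 24.7(4.37F + 1)` Hz and `dB/ERB = SL + 10 log10(ERB)` -- and
  then passes through the curve. Tail contributions outside the filter are
  ignored, consistent with the rationale of the dB/ERB conversion itself.

The one-ERB rule for "on-frequency" generalises the two frequencies the
default designs use (4 vs 2.4 kHz) to arbitrary stimuli.

### Gain-reduction rule

The mechanistic `gain_rule` assumes the output of the cochlear nonlinearity
is the local input to the efferent loop: `dG = clamp(s (E - E0), 0, cap)`,
where `E` is the precursor's place excitation at full gain, `E0` an
elicitation floor, `s` the elicitation slope, and `cap` the maximum gain
reduction (at most `G`). This reproduces the signature asymmetry: an
off-frequency precursor's excitation grows linearly with level (slope of
`dG`: `s`), an on-frequency precursor's excitation is compressed above the
breakpoint (slope `s*c`). With `s = 0.8` and `c = 0.41` the implied slopes
are 0.80 and 0.33 dB/dB. An empirical mode (per-class intercepts/slopes in
dB SPL for tones, dB/ERB for noise) is provided for descriptive fits; the
package supports both and does not force the broadband slope to equal the
on-frequency slope, because measured broadband growth can come out slightly
steeper and both parameterizations are legitimate.

### Detection stage

Detection follows the power spectrum model: the signal is detected when its
place output reaches the intensity sum of masker excitation and an internal
noise floor `N0`, plus a criterion signal-to-masker ratio `K` (default 0 dB,
configurable). `N0` is calibrated at construction so the model reproduces
the listener's quiet threshold exactly, which makes "quiet threshold" an
identity of the model rather than a fitted quantity. Under the
*gain-reduction* hypothesis the precursor reduces the curve for the signal
and any on-frequency masker, leaving off-frequency maskers untouched; under
*additivity* the curve is static and masker and precursor excitations sum
in intensity. Both branches are solved in closed form by inverting the
piecewise-linear curve (the nominal search range -20 to 120 dB SPL only
matters for saturation flagging). The discriminating prediction, which the
test suite asserts for every generated listener: with equally effective
on- and off-frequency maskers and a common precursor, additivity predicts
identical threshold shifts, gain reduction predicts a strictly larger
off-frequency shift whenever `dG > 0`.

## The adaptive-tracking simulator

Thresholds in the modeled experiments come from 3-interval forced-choice
(3IFC) 2-down/1-up tracking, which converges on the 70.7%-correct point.
The simulated psychometric function is a Gaussian CDF with chance level 1/3
and spread `sigma` (default 4 dB; the experiments constrain no particular
form, and a Gaussian CDF is the field's default). It is anchored so that
the probability correct at the true threshold is exactly `sqrt(1/2)`:
this makes the generative threshold and the tracking target synonymous,
which is what the 2-down/1-up rule requires.

Two procedure presets mirror the two designs: 50-trial runs with the step
dropping from 5 to 2 dB at the second reversal and the final even number of
2-dB reversals averaged (`staircase_config_50trial()`), and 12-reversal
runs with the step change at the fourth reversal and the final eight
reversals averaged (`staircase_config_12rev()`). Runs are excluded when the
reversal SD exceeds 5 dB (strictly -- an SD of exactly 5 passes) or fewer
than six reversals occurred. Masker tracking inverts the step polarity so
the track converges on the lowest masker level at which the fixed signal is
detectable; the direction convention is a package decision, since only the
tracked quantity is fixed by the designs. Between-run variability is a
single Gaussian offset per run (SD `run_noise_sd_db`), which reproduces
realistic between-run SDs without trial-level nonstationarity. Tracks start
10 dB above the generative threshold, with level bounds -20 to 120 dB SPL.

An exact oracle backs the simulator: `staircase_asymptote()` builds the
Markov chain over (level, consecutive-correct) states of the 2-down/1-up
automaton on a bounded grid and returns its stationary mean. The automaton
balances where `p^2 = 1/2`, i.e. at 70.7% correct, so the oracle sits at
the generative threshold; the test suite requires simulator/oracle
agreement within 0.5 dB across psychometric spreads of 2-8 dB.

## The estimation pipeline

* `gain_reduction_estimate()` is the masker-absent estimate: threshold with
  precursor minus quiet threshold, unclamped (floor handling is explicit
  and separate).
* `pooled_t_from_summary()` uses the pooled-variance (Student) t with
  `df = n1 + n2 - 2`. Pooled rather than Welch is deliberate: the degrees
  of freedom printed in the source data (e.g. `t(3)` for groups of 3 and 2)
  are only consistent with pooling.
* `holm_bonferroni()` applies the step-down correction. The family used by
  `reproduce_table1_stats()` comprises the ten per-participant matched-level
  tests plus the group test, which reproduces the published adjusted
  p-values; the family is a configuration choice, not a statistical
  necessity.
* `floor_filter()` keeps estimates strictly greater than 4 dB, removing
  floor effects before slope fitting.
* `fit_gain_reduction_lmm()` fits estimated gain reduction against
  uncentred level, precursor class (on-frequency tone as reference) and
  their interaction by REML, with by-participant random intercepts plus
  per-class offsets ("slopes" structure, two-class tonal design) or random
  intercepts only ("intercepts" structure, three-class design including
  broadband noise). Satterthwaite degrees of freedom and p-values come from
  lmerTest; non-convergence and singular fits are flagged, never silently
  replaced. The two random structures are explicit configuration: no
  backward-elimination model search is reimplemented, the final structures
  are fitted directly.

The packaged `table1.csv` fixture transcribes the published matched-masker
summary table. Run counts are 2 except where the source states otherwise:
3 for P5's 65-dB off-frequency precursor condition, and 4 for P2 (inferred
from the published `t(6)`; P2's counts are not fully specified, so P2's
statistic is reproduced only approximately and not treated as a headline
check). One known discrepancy is preserved rather than resolved: the
published table stars P3's 80-dB row, but the printed `t(2) = 5.23` arises
from the 75-dB row's summaries; `reproduce_table1_stats()` computes both.

## Synthetic data: what it emulates and what it does not

Two generator tiers separate failure diagnosis:

* **Direct tier** (`generate_threshold_dataset()`): draws gain-reduction
  points from the hierarchical linear model itself -- fixed effects,
  correlated by-participant intercepts and class offsets, residual noise --
  with defaults equal to the published tonal-design estimates
  (`cohort_params_tonal()`: intercept -4.32, level slope 0.33, off-tone
  offset -49.47, interaction 0.47; intercept variance 31.23, class-offset
  variance 16.18, correlation -0.02, residual 11.98; 7 participants,
  2 runs per condition, on-tone grid 20-90 dB SPL in 10-dB steps, off-tone
  60-95 dB SPL in 5-dB steps) and the broadband-design estimates
  (`cohort_params_bbn()`: 4 participants, random intercepts only, BBN
  24-64 dB SPL overall in 10-dB steps entering the model in dB/ERB; the
  64-dB cap avoids middle-ear-muscle-reflex contamination). Grid step
  sizes are package choices at typical psychoacoustic spacing; the ranges
  are the study conditions.
* **Full tier** (`generate_cohort()` + `generate_full_experiment()`):
  mechanistic listeners (G in 35-50 dB, c in 0.2-0.5, breakpoint 35-50 dB
  SPL, quiet threshold 5-20 dB SPL -- a plausible range, as individual
  quiet thresholds are not published numerically -- off-frequency
  attenuation 7-12 dB, elicitation slope 0.7-0.9 so the implied growth
  slopes bracket the empirical ones, cap 20-25 dB) run through the entire
  staircase machinery for every condition of all three experiment designs.

The generators emulate the *statistical* structure the analysis assumes:
linear growth of estimates with level, Gaussian participant heterogeneity,
Gaussian run noise. They do not emulate lapses of attention, learning,
trial-level nonstationarity, the frozen-noise response cue that forced one
participant's broadband data to be discarded in the source study, or any
spectral detail of the high-pass background noise (a metadata flag only).
Passing recovery tests therefore demonstrates that the pipeline is
consistent and unbiased *for data satisfying its own assumptions*, not that
those assumptions hold for any particular human dataset.

### Floor censoring and recovery bias

One deliberately preserved subtlety: the generative model is linear all the
way down, so at low precursor levels its mean sits below the 4-dB floor and
the floor filter truncates the estimate distribution from below. This
selection inflates low-level conditional means and attenuates recovered
slopes -- the mean recovered level slope is about 0.30 against a generative
0.33, the off-tone interaction about 0.41 against 0.47, and the broadband
interaction about 0.09 against 0.11 (all computed by
`simulate_lmm_recovery()` and the acceptance script; the recovered values
sit within the tolerances those checks state). In real data the floor
region is genuinely flat (no elicitation below threshold) rather than
linearly extrapolated, so the filter removes floor points without the same
truncation geometry. Accordingly, the package's *unbiasedness* property
test runs the recovery without the filter, where every fixed effect is
recovered with mean bias well under half a standard error, and the
*filtered* recovery is asserted at the tolerances quoted above.

## Numerical choices

* All logs are base 10; all levels are dB SPL unless labelled dB/ERB or
  spectrum level.
* Threshold equations are solved by exact closed-form inversion of the
  piecewise-linear curve; equally effective masker levels likewise (the
  documented 0.01-dB tolerance is the accuracy contract, not an iteration
  parameter).
* The psychometric anchor is `z0 = qnorm((sqrt(1/2) - 1/3) * 3/2)`
  (~0.1527), i.e. exactly the 2-down/1-up balance point rather than the
  rounded 70.7%.
* The stationary distribution of the tracking chain is obtained by direct
  linear solve of the balance equations with a normalisation row; the
  chain is irreducible on any bounded grid because the 3IFC chance floor
  keeps upward transitions possible everywhere.
* Staircase step bookkeeping: the step in force at a trial is determined by
  the number of reversals *completed before* that trial, so the reversal at
  which the schedule switches is still counted at the initial step size,
  and threshold averaging uses only reversals tagged with the final step.
* Seeds: every stochastic driver takes a single integer seed and derives
  per-run subseeds from it, making cohorts, datasets and full experiment
  suites bit-reproducible.

## Problem sizes used by the packaged checks

The test suite and the acceptance script use 250 simulated tracks for the
tracking calibration, 50 replicate cohorts per recovery study (7 or 4
participants, 2 runs per condition as above), and 150-participant cohorts
for the variance-component moment checks. These sizes give Monte-Carlo
standard errors comfortably below the tolerances asserted, and the whole
suite runs in well under a minute.

## Known limitations

* No travelling-wave, filterbank or otoacoustic-emission modeling; the
  off-frequency path is a single attenuation number.
* No time-course modeling of the efferent effect: the paradigm's timing is
  assumed to activate it fully.
* Residual on-frequency threshold shifts are reproduced only through the
  signal-inaudibility route (the internal noise floor); residual additive
  masking after gain reduction would require a temporal-window stage that
  is out of scope.
* The middle-ear muscle reflex is represented only as the 64-dB cap on
  broadband precursor levels.
* P2-style task-difficulty behaviour (high run-to-run variability) is
  representable only through an elevated `run_noise_sd_db`.
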