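---
title: "Detecting additional HRV reductions: models, algorithms, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting additional HRV reductions: models, algorithms, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(addhrvr)
```

## The problem

Vagally mediated heart rate variability (HRV), indexed here by the RMSSD
(root mean square of successive interbeat-interval differences, in ms),
decreases both under psychological stress and under physical load. An
ambulatory stress-detection algorithm that prompts a person (or logs an
event) whenever RMSSD drops will therefore mostly detect walking up stairs.
The idea implemented in this package is the *additional* HRV reduction
(AddHRVr): a drop of observed RMSSD below the level expected from current
metabolic demand, by more than a calibrated margin. Minute-level RMSSD and
activity energy expenditure (AEE, kcal/min from accelerometry plus
barometric pressure) are the only inputs; the package simulates, on recorded
or generated data, the online algorithm that a wearable could run in real
time, and then evaluates — over a whole grid of algorithm settings — how
well the resulting triggers predict objectively coded increases of stress.

## Calibration model

For each participant an ordinary least-squares regression over the valid
calibration minutes,

$$\widehat{\mathrm{RMSSD}}(t) = \beta_0 + \beta_1 \cdot \mathrm{AEE}(t),$$

gives the metabolically expected RMSSD. `fit_calibration()` fits this
(`predictor_kind = "linear"`), or the inverse variant
$\beta_0 + \beta_1/(\mathrm{AEE}+\varepsilon)$ in which the intercept is
interpreted as the HRV floor at unbounded movement. The inverse
regulariser $\varepsilon$ defaults to the 5th percentile of the positive AEE
values, keeping the reciprocal bounded at rest; the choice is exposed as an
argument.

Two unit conventions are worth spelling out. AEE is stored in kcal per
minute. Because activity monitors internally carry calories, a slope
"per 1000 kcal" in cohort tables is numerically identical to the slope in ms
per (kcal/min); `summarize_calibrations()` therefore reports the internal
slope unchanged under the column name `slope_per_1000kcal`. Second, the
Pearson correlation reported for each participant is always between RMSSD
and AEE itself (negative expected), regardless of predictor kind, so that
linear and inverse calibrations are summarised comparably.

Calibration uses the entire recording by default, as in retrospective
simulation of a full ambulatory day; `calibration_range` restricts it to a
sub-range for prospective designs where calibrating on the future is not
possible. Outlier screening (`screen_outliers()`) iteratively removes the
single worst minute with an absolute externally studentized residual above
4.0, capped at 5 removals. The threshold and cap are reproducible stand-ins
for the visual scatter-plot inspection traditionally used with such data;
under the default generator the mean number of removals per participant
stays well below 1, matching the near-zero removal rates typical of
device-preprocessed RMSSD series.

## Trigger algorithms

A minute is a *meaningful decrease* when

$$\mathrm{RMSSD}(t) < \widehat{\mathrm{RMSSD}}(t) - c \cdot
  \mathrm{SD}(\mathrm{RMSSD}_{\mathrm{cal}}),$$

with multiplier $c$ = 0.5 by default. A trigger fires at minute $t$ when at
least $k$ of the trailing $n$ minutes ($t-n+1, \dots, t$) are meaningful
decreases (`window_threshold` out of `window_length`) and strictly more than
`silent_min` minutes (default 20) have elapsed since the previous trigger.
The scan is strictly causal: no minute uses later data, no trigger can fire
before the first complete window, and invalid minutes count as
non-decreases while remaining inside windows, so behaviour under dropouts is
deterministic. The canonical settings grid enumerates all $n$ from 2 to 30
with $k$ from 1 to $n-1$: 435 settings (`enumerate_settings()`).

The *static* algorithm uses the calibration line as is. The *dynamic*
algorithm replaces the intercept with the mean of a trailing 60-min HRV
buffer so the expected-RMSSD line tracks slow drifts of HRV level. The
buffer logic guards against contaminating the baseline with
movement-suppressed HRV: the HRV buffer absorbs the minute's observed RMSSD
only while the mean of a trailing 40-min AEE buffer is below the mean
calibration AEE, and absorbs the static intercept otherwise. Both buffers
start at their neutral values (static intercept; mean calibration AEE).

Three details of the buffer arithmetic were genuinely open and are resolved
as follows. First, the dynamic prediction retains the slope term,
$\widehat{\mathrm{RMSSD}}(t) = \bar b(t) + \beta_1 \mathrm{AEE}(t)$ with
$\bar b(t)$ the HRV-buffer mean, so the dynamic algorithm degenerates
exactly to the static one whenever the buffer mean equals the static
intercept; dropping the slope would leave fast metabolic changes entirely
uncompensated between buffer updates. Second, buffers are lag-1: the
dynamic intercept for minute $t$ is computed before minute $t$'s values are
pushed, so a minute never dilutes its own detection threshold. Third,
invalid minutes push the neutral values. With these conventions a step
change of RMSSD under low AEE produces an exactly linear 60-minute ramp of
the dynamic intercept — a closed form the test suite checks.

## Stress transitions and event records

Objective stress is coded per minute as 0 (routine station work), 1
(routine operation) or 2 (emergency operation). `detect_transitions()`
run-length encodes the series and emits a transition at each boundary whose
flanking episodes *both* last at least 20 min. Requiring the minimum on
both sides (the conservative reading of a minimum-situation-duration rule)
guarantees that the follow windows of consecutive transitions cannot
overlap. A transition is an *increase* (direction 1) when the level rises.
`match_triggers()` marks a transition as triggered when at least one
trigger lies in the half-open follow window $(t, t+W]$, $W$ = 20 min by
default (40 min for the longer-effects variant); a trigger at the
transition minute itself belongs to the preceding situation.

## Step 2: bootstrap evaluation

For one algorithm setting, `bootstrap_setting()` computes each
participant's event records once (the engine is deterministic) and then
runs a participant-level bootstrap: each of `iters` (default 500)
iterations resamples participants with replacement, pools their events, and
fits the random-intercept logistic model

$$\Pr(\mathrm{direction}_{ij}=1) =
  \mathrm{logit}^{-1}(\gamma_0 + u_i + \gamma_1\,\mathrm{trigger}_{ij}),
  \quad u_i \sim \mathcal N(0, \tau^2),$$

via `lme4::glmer()` (Laplace approximation), Wald p-value on $\gamma_1$
(a likelihood-ratio option exists). Participants drawn more than once enter
as distinct grouping units, the standard cluster-bootstrap convention.
Power is the fraction of valid iterations with $p < 0.05$; the effect
estimate is the mean percentage change in odds, $(\mathrm{OR}-1)\times
100$, with 2.5/97.5 percentile bounds. An iteration is invalid when the
resample is degenerate — constant outcome, constant predictor, a zero cell
in the direction-by-trigger table (separation), or non-convergence — and a
setting whose valid fraction falls below one half is flagged unreliable.
With the intercept variance constrained to zero (or a single participant)
the model reduces to ordinary logistic regression and is fit with
`stats::glm()`; the test suite checks this limit against the closed-form
2×2 cross-product odds ratio.

`sweep_grid()` repeats this over the settings grid for one variant and
orders settings by power; `power_curve()` varies the number of resampled
participants per iteration to trace how large an online study would need to
be, reporting the smallest n crossing 0.70/0.80/0.90.

### What bootstrap "power" does and does not estimate

The bootstrap rejection fraction for a given cohort concentrates around
that cohort's *realised* sample association: writing $z$ for the realised
Wald statistic, the bootstrap power is approximately
$\Phi(z-1.96)+\Phi(-z-1.96)$. It is a sensitivity measure for the design at
hand, not a frequentist error rate: averaged over independent null cohorts
it approaches ≈ 0.17, not 0.05. Calibration of the underlying test is
therefore measured differently, by `null_rejection_rate()`: one model fit
on each of many independently generated cohorts. Under the null generator
(no planted effect) the static algorithm's rejection rate lands slightly
above the nominal level (≈ 0.09 rather than 0.05 at 38 participants): the
Wald z-test is mildly anticonservative at this cluster count, and the
procedure itself induces dependence the model ignores — transition
directions alternate within a person, and the silent period makes trigger
presence negatively correlated across adjacent follow windows. This mild
inflation is inherent to the prescribed test, worth remembering when power
estimates hover near a decision threshold.

A further finding from this calibration exercise: the *dynamic* algorithm
carries a structural association with transition direction even when no
stress effect is planted. During the transient after a metabolic
transition, the AEE buffer lags, the HRV buffer briefly absorbs
movement-suppressed RMSSD, and the threshold over-adjusts — so triggers are
systematically somewhat rarer in post-increase windows (about 12% vs 15%
under the default null generator). Detecting this kind of behaviour is
precisely what a null-generator calibration is for, and it should be kept
in mind when interpreting dynamic-variant odds ratios on real data.

## The synthetic-data generator

`generate_cohort()` draws, per participant: a calibration intercept from
N(51.05, 24.04) ms (truncated at 18) and slope from N(−5.96, 4.46) ms per
(kcal/min) (truncated at −0.4), matching the heterogeneity of a 38-person
firefighter calibration cohort; a semi-Markov stress schedule alternating
routine episodes with chains of operation episodes (shifted-geometric
durations floored at 20 min, mean operation duration 51 min, operations
hopping to the other operation level with probability 0.25), whose
stationary occupancy approximates the target 81.4% / 11.2% / 7.4% and
yields roughly 5 operations and 10 usable transitions per day; AEE as a
0.4 kcal/min resting baseline plus operation bursts (+1.2 and +1.9
kcal/min) and occasional exercise bouts, giving daily totals near 1000
kcal; and RMSSD as the calibration line plus AR(1) noise (marginal SD 11
ms, lag-1 correlation 0.6 — the simplest autocorrelated process that makes
moving-average buffers meaningful; white noise would make the 60-min buffer
trivially equal the intercept). The ground-truth stress effect subtracts
`effect_drop` ms (default 10, roughly 0.8 within-person residual SDs —
a strong but plausible stress reactivity) for `effect_duration` minutes
(default 15) after every upward level change; `effect_drop = 0` gives a
null cohort. About 1% of minutes are marked artifact-invalid.

What the generator deliberately does not emulate: circadian HRV structure,
respiration coupling, posture effects, device-specific artifact patterns,
or any correlation between stress schedules and time of day. Passing tests
on generated cohorts therefore demonstrate the correctness and statistical
behaviour of the pipeline under known ground truth — not that any
particular algorithm setting will attain a given power on real recordings.

## Problem sizes and numerical choices

The test suite and the acceptance script run the pipeline at the scales a
desk check needs: full 38 × 1440 cohorts for calibration summaries and
trigger counts; 200–500 bootstrap iterations for single-setting
evaluations; restricted grids (window lengths 2–5) when a sweep is
exercised end to end; 500 independent cohorts for the type-I calibration.
Engine correctness is checked against a naive full re-scan oracle on 1000
random series, and OLS against the closed form at 1e-9 relative tolerance.
Ties and degenerate cases are fixed as follows: a trigger is stamped at the
minute completing its window; refractoriness is strict (`> silent_min`);
windows are never compacted around invalid minutes; transitions at the
recording edges are not emitted; fits on fewer than 10 valid minutes are
refused.

## Known limitations

Calibrating on the full recording uses future data relative to any given
minute; prospective deployments should calibrate on an initial segment
(supported via `calibration_range`). The Wald p-values inherit the usual
small-cluster anticonservatism of GLMMs. The generator's unit scale for
AEE is self-consistent but conventional; absolute trigger counts on real
device exports depend on the device's own AEE scaling. And the bootstrap
power surface inherits all idiosyncrasies of the single cohort it is
computed from — which is exactly why the power-versus-n curve and the
cross-variant comparisons, not single power values, are the quantities to
interpret.
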