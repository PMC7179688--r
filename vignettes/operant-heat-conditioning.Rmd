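---
title: "Methods: closed-loop operant heat conditioning and its analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: closed-loop operant heat conditioning and its analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The experimental design this package models

A single fruit fly walks in a linear glass chamber (48.7 mm). A laser can
warm its body mildly — to roughly 26–27 °C, about 5–6 °C above room
temperature — far below the ≥37 °C stressors of classical paradigms. The
protocol has five sessions in fixed order: **Pre-test**, **Train 1**,
**Test 1**, **Train 2**, **Test 2**. Test sessions last 10 min and are never
heated. In Train sessions the fly's *own walking* triggers the heat: when it
has walked continuously for more than 0.5 s the operator turns the laser on,
and turns it off when the fly stops. The fly is also heated whenever it sits
within 3 mm of either chamber end, so it cannot escape the contingency by
parking at a wall. A Train session ends when the fly has collected 20 heat
episodes or has been continuously stationary for 8 min.

Each *train* fly runs simultaneously with two controls: a **yoked** fly that
receives a sample-identical copy of the train fly's laser sequence
(decoupling the amount of heat from its contingency on behaviour), and a
**blank** fly that is never heated. Walking is the fly's strong default in
this apparatus, so learning to walk *less* to avoid heat is
anti-instinctive: the interesting outcome is suppression of an innate
behaviour.

Because the original recordings are not publicly deposited, the package
pairs the analysis pipeline with a first-class synthetic-data generator
whose defaults emulate the study conditions. Every analysis component
accepts recorded traces in the same CSV dialect, so the pipeline applies
unchanged to real data.

## The simulated fly

The generator uses the most parsimonious mechanism that can express both
within-session and post-session activity suppression: a two-state
semi-Markov agent with a single scalar learning variable.

At each step of length `dt` the fly is either **walking** or **paused**.
Transitions are hazard-driven:

* walk → pause with constant hazard $\lambda_p$;
* pause → walk with hazard
  $\lambda_w \, e^{-\beta S} \, e^{-h t}$,

where $S \ge 0$ is the learned suppression, $\beta$ its behavioural weight,
and $h$ a slow habituation rate acting identically in every fly. Heat
received *while walking* accrues suppression, $S \mathrel{+}= \alpha\,dt$;
at all other times $S$ decays exponentially with time constant $\tau_S$.
Walking moves the fly at constant speed, reflecting at the walls with a
fresh random heading at each pause → walk transition; pausing holds
position. The same update rule applies to train, yoked and blank flies —
what differs is only the laser channel each one experiences. This is a
pairing-based (Hebbian-style) rule: any heat that happens to coincide with
walking teaches the fly, whether or not the fly caused it.

The virtual operator reproduces the manual control of the stimulus: the
trigger condition (continuous walking beyond 0.5 s, or presence in the 3-mm
edge zones) is applied with a uniform reaction latency of 0.3–0.8 s on both
onset and release. That latency is why the simulated train flies are heated
during most but not all of their walking: the heat misses the first second
or so of each walk bout and spills over briefly into the following pause.
Body temperature is modelled as a first-order relaxation between room
temperature and the heated set point; it is a diagnostic output only —
learning couples to the laser flag, because no temperature dependence of
learning is available to constrain anything richer.

### Default parameters and how they were chosen

| parameter | default | unit | rationale |
|---|---|---|---|
| `dt` | 0.01 | s | position-sensor cadence; fine enough to resolve the 0.5-s trigger |
| `walk_speed` | 10 | mm/s | typical adult walking speed |
| `pause_to_walk_rate` | 0.30 | 1/s | with the walk→pause rate, gives ~55–60% baseline activity and bouts of a few seconds |
| `walk_to_pause_rate` | 0.20 | 1/s | mean walk bout 5 s |
| `learning_gain` ($\alpha$) | 0.008 | 1/s | calibrated once so a full two-session training yields the reported train-group activity drop (≈ −0.37) |
| `suppression_decay` ($\tau_S$) | 3000 | s | learning persists across the 10-min test sessions with modest decay |
| `suppression_effect` ($\beta$) | 1.0 | — | scale absorbed into $\alpha$; kept at 1 |
| `habituation_rate` ($h$) | 1e-4 | 1/s | reproduces the mild (~0.05) activity decline of never-heated flies over a session sequence |
| `controller_latency` | 0.3–0.8 | s | plausible human reaction-time band |

The calibration targets were the published group-level statistics (baseline
activity near 55%, walking-conditional heat likelihood near 0.85 for train
flies versus ~0.2 while paused, the train-group activity difference near
−0.37, the blank-group decline near −0.06). Parameters were fixed after one
calibration pass and are not adjusted per analysis.

Cohorts are seeded hierarchically: one root seed draws independent child
seeds for every fly, so enlarging a cohort leaves the earlier triplets
bit-identical. Each triplet simulates the train fly first (its closed loop
determines the Train-session lengths), then the yoked fly against the
mirrored laser vector and the blank fly against an all-off vector, over the
same session windows.

A safety cap (default 1800 s) bounds a Train session in case a
parameterization satisfies neither termination rule; under the defaults it
is never reached. Edge-zone heat episodes count toward the 20-episode
quota, since episodes are defined simply as maximal laser-on runs. The
8-min stationarity rule is read as one *continuous* pause, not cumulative
stillness.

## Segmentation

The walking criterion is not part of the experimental definition, so it is
an explicit, logged analysis parameter. Per-sample speed is the first
difference $|\Delta x|/dt$; a sample is "walk" iff its speed is at least
`speed_threshold` (default 1 mm/s — an order of magnitude below real
walking speeds, an order above quantization noise). Runs shorter than
`min_bout` (default 0.2 s) are merged into their neighbours, shortest run
first, ties resolved by absorbing walk runs before pause runs (a tie
therefore tends to pause, the conservative direction for an
activity-suppression readout). The result is a contiguous, alternating,
half-open partition of the trace: walk time plus pause time equals the
trace duration exactly, a property the test suite asserts on every fixture.
No other smoothing is applied.

## Metrics

All metrics are defined on the segmentation and the laser channel:

* **Activity level** — the fraction of a session spent walking.
* **CAD** (cumulative active duration) — walk seconds accumulated from
  session start up to a cut time; non-decreasing and 1-Lipschitz in the
  cut. Because Train sessions end at different times for different flies,
  cross-group CAD comparisons use a *common cut*: the smaller of the
  configured value (163 s, the reference cohort's minimum) and the cohort
  minimum actually observed, which the pipeline recomputes and records in
  its manifest.
* **Conditional heat likelihood** — time heated while in a state divided by
  time in that state. If a state is never occupied in the window the
  conditional is *missing*, not zero.
* **ED** (exposure differential) — `P(heated|walking) − P(heated|pause)`,
  the contingency of heat on behaviour. For a never-heated window (blank
  flies, and any unheated session) the ED is missing: there is no
  contingency to measure, and the correlation analyses use yoked flies
  only. The whole-experiment ED pools occupancy and heat time across both
  Train sessions *before* dividing, keeping it a fraction of total time
  rather than an average of ratios.
* **AD** (activity difference) — a Test session's activity level minus the
  Pre-test level, reported as a plain number (a change of level, not a
  percent change). Negative AD means learned suppression.

## Curation

Flies inactive for strictly more than 90% of the Pre-test are excluded
(a fly at exactly 90% inactivity is retained — the rule is a strict
inequality), as are flies with incomplete attribute records or a flagged
procedure error; each exclusion carries exactly one primary reason, in that
order of precedence. Triplet members are curated independently: excluding a
train fly does not drop its yoked or blank partner, which is what the
unequal group sizes of operant data sets require.

## Inference

Group contrasts use the Kruskal–Wallis omnibus (midranks, tie correction,
chi-square approximation) followed by pairwise two-sided Wilcoxon rank-sum
tests — exact enumeration when both groups have ≤ 8 tie-free observations,
otherwise the normal approximation with continuity correction and
tie-corrected variance — Holm-adjusted by default, with unadjusted output
available. For small problems the package also reports exact
permutation p-values by full enumeration (Kruskal–Wallis at total n ≤ 10,
the two-group permutation test at total n ≤ 12), and the test suite checks
the large-sample paths against independent brute-force enumerators.

"Permutation-based confidence intervals" can name two different procedures,
so both are implemented and explicitly labelled: a with-replacement
bootstrap percentile interval of the median (10,000 resamples by default,
seeded, used for the reported group intervals and the CAD bands) and a
label-permutation test for two-group contrasts (10,000 permutations with
the plus-one correction, or exact enumeration). Significance tiers are
attached as stars: `*` < 0.05, `**` < 0.01, `***` < 0.001, `****` < 0.0001.

Correlation analyses (yoked AD against total heat exposure and against ED)
report Pearson's r, the least-squares slope and intercept, and the
two-sided t-test for zero slope.

## Numerical and design choices

* Times are 0-based; all intervals half-open; the final sample inherits the
  preceding sample's state so bouts exactly partition the trace.
* The canonical trace file is CSV with header
  `time_s,position_mm,laser_on,session`, fixed four-decimal formatting, so
  writing after reading is byte-stable.
* Degenerate statistics are errors or missing values, never silent zeros:
  zero-variance regressors and empty groups raise classed errors; unoccupied
  conditionals and never-heated EDs are `NA`.
* Bootstrap and permutation routines consume R's RNG only, so a single
  `set.seed` (or the pipeline's root seed) makes any run bit-reproducible;
  the run manifest captures the flattened configuration and seed.

## What the generator does and does not emulate

It emulates: the five-session closed-loop protocol with both termination
rules and the edge rule, operator latency (hence sub-100% conditional heat
likelihoods), laser mirroring to the yoked partner, a never-heated blank
partner, learning-driven activity suppression, and a shared mild
habituation. It does not emulate sensor noise (positions are exact, so
segmentation at the default threshold is essentially noiseless), spatial
preferences or thigmotaxis beyond wall reflection, inter-fly parameter
heterogeneity, or any temperature dependence of learning.

Two consequences are worth stating plainly. First, because learning here is
purely pairing-based, yoked flies — who are heated during roughly half of
their walking by chance — acquire more suppression than their real
counterparts showed; the simulated yoked decline overshoots, and simulated
AD is correlated with total heat dose, whereas the reference experiment
found no dose effect. Second, the ED→AD correlation among yoked flies,
while reliably negative in sign, is diluted by dose variance across
triplets, so its significance at a 125-fly cohort hovers near the 5% level
and is seed-dependent. Passing simulation tests therefore demonstrates that
the *pipeline* recovers the structure the generator puts in, not that the
generator is a complete model of fly learning.

## Problem sizes used by the test suite

Deterministic properties run on constructed traces of seconds to minutes.
Cohort-level checks use 60 triplets for contingency calibration, 125
triplets (the reference yoked sample size) for the pattern reproduction,
20 cohorts of 20 triplets for the no-learning null, and 500 replicates of
n = 200 at 10,000 resamples for the coverage of the bootstrap median
interval.
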