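---
title: "Methods: depth coding analyses and their synthetic test-bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth coding analyses and their synthetic test-bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(depthpop)
```

`depthpop` re-implements, as a reusable and tested pipeline, a family of
analyses of depth-related population coding in mouse primary visual cortex
(V1): selection of depth-sensitive cells from visual-cliff imaging, selection
of decision-phase cells in an active depth-discrimination maze, cross-session
stability tests, and population decoding of depth, choice and position. The
recordings such analyses are usually run on (miniscope calcium imaging plus
keypoint tracking) are rarely deposited; the package therefore ships a
synthetic session generator with planted ground truth so that every stage can
be exercised and falsified offline. This vignette documents the models, the
parameters that matter, the numerical choices, and — importantly — what the
synthetic world does and does not establish.

## The pipeline in one paragraph

Deconvolved event times are turned into sliding-window rates (1 s bin,
0.2 s step — `event_rate()`), z-scored per cell, and trial-normalized where
correct/incorrect groups of unequal size are compared. Visual-cliff sessions
at two apparent depths yield per-cell occupancy-normalized rate maps along
the axis perpendicular to the cliffside (`ratemap()`, 2.5 cm bins matching
the apparatus checkerboard); the *area score*
$(A_1 - A_2)/(|A_1| + |A_2|)$ contrasts the summed maps, and cells beyond
mean ± SD of the animal's score distribution are *DSVC* cells
(`classify_dsvc()`). In the variable spatial length maze (VSLM) each cell's
trace is related to the binarized head orientation (toward the correct /
incorrect arm) during the pre-entry dwell by a k-nearest-neighbour mutual
information estimate (`mi_knn()`, k = 3); cells outside the 95% interval of
a circular-rotation shuffle null are *DSVA* cells (`classify_dsva()`).
Stability and overlap questions use discrete, conditional and interaction
information on membership vectors (`mi_discrete()`, `cmi_discrete()`,
`joint_mi()`). Decoders: an in-repo Gaussian naive Bayes for depth
(`gnb_fit()`), kNN (k = 5) for choice over trial time, and a compiled
100-tree random forest over 2 cm position-bin classes for position
(`decode_position()`), with signed-error analyses on actual versus
goal-anchored *relative* positions (`relative_positions()`,
`error_sign_ratio()`).

## Estimators and numerical choices

**kNN mutual information.** For continuous trace $x$ and binary orientation
$y$ we use the entropy-based continuous/discrete estimator: for each sample,
the distance to its k-th nearest neighbour *within its class* defines a
radius, $m_i$ counts samples of any class strictly inside it, and
$\hat I = \psi(N) + \overline{\psi(k_i)} - \overline{\psi(n_{y_i})} -
\overline{\psi(m_i)}$, clipped at 0. All information quantities are reported
in nats (the source analyses never state units). The estimator assumes
tie-free continuous input; calcium traces carry Gaussian measurement noise,
which guarantees this in practice. Against a quadrature oracle for a
two-Gaussian mixture (class separation 2 SD, n = 5000) the estimate is
accurate to well under 0.05 nats.

**Shuffle null.** The null for trace/behavior MI circularly rotates the
neural series by a random offset of at least 1 s, preserving the trace
autocorrelation while breaking behavioral alignment; exactly which structure
the original shuffling preserved is unstated, so rotation is our declared
choice and full permutation is exposed (`method = "permute"`) — the latter
is also what membership-overlap tests use, since cell indices are
exchangeable. Nulls default to 1000 values pooled across cells (one
histogram per animal, matching how the selection was visualised); per-cell
nulls are a config switch. Selection is two-sided ("outside the 95%
interval"), with one-sided available.

**Area score.** The published formula is stated on whole "rate maps"; we
define the area $A_k$ as the sum of the normalized map over bins unmasked in
both sessions, giving one scalar per cell. Bins with under 0.2 s occupancy
are masked — transit bins otherwise contribute pure noise; whether the
original analysis masked at all is not stated. The score is antisymmetric,
bounded in $[-1, 1]$, scale-invariant, and equals $(1-g)/(1+g)$ for a pure
rate gain $g$ between sessions, so the planted gain of 3 puts depth-tuned
cells at ±0.5, far outside the mean ± SD band (which under a symmetric null
admits $2\Phi(-1) \approx 31.7\%$ of cells by construction).

**Gaussian naive Bayes.** Implemented from the likelihood formula with
maximum-likelihood (biased) variances, log-space posteriors, and a variance
floor of $10^{-9}\,\max_j \widehat{\mathrm{var}}(x_j)$ — the same smoothing
convention as the reference implementations it is verified against, so
log-posteriors agree to $10^{-9}$.

**Random forest.** No forest implementation exists in the pinned offline
environment, so `src/forest.cpp` implements CART/Gini trees with bootstrap
resampling, $\lfloor\sqrt p\rfloor$ features per split, nodes expanded until
pure or below two samples, one sample minimum per leaf and equal weights —
the printed settings of the original decoding. A self-contained linear
congruential generator makes fits bit-reproducible across compilers.

**Trial normalization.** The build contract's phrasing implied dividing
trial-aligned averages by the trial count twice; the source text says rates
were "normalized by trial count" so that correct and incorrect groups with
unequal trial numbers are comparable, i.e. aligned sums divided once (a
per-trial mean). We follow the source.

## The synthetic world

One simulated animal is a cell roster (classes: `depth_tuned`,
`choice_tuned`, `place`, `noise`) with lognormal rate heterogeneity
(σ = 0.4 log units — heavy-tailed population rates are universal in cortex,
and without them per-group rate scatter would be degenerate). Defaults:
baseline event rate 1 Hz (typical for task-engaged V1 deconvolved events),
place-field peak 3 Hz, field SD 5 cm, depth and choice gains 3, GCaMP6f-like
kernel τ = 0.4 s, trace noise SD 0.05 (kernel peak = 1), behavior at 50 Hz,
imaging at 30 Hz (the source never states its imaging rate; traces are in
arbitrary fluorescence units throughout). Footprint centroids live in a
608 px field of view and jitter by 2 px SD per session, well under the 10 px
cross-registration rule.

*Visual cliff*: a 60 × 60 cm arena, 30 cm concentric centre square, two
15-minute sessions. The trajectory is an Ornstein–Uhlenbeck-velocity walk
(stationary speed ≈ 10 cm/s) with reflecting walls; cliff avoidance has
three parts scaled by a per-session bias (defaults 0.2 at 30 cm depth, 0.5
at 90 cm): crossings onto the deep half are refused with that probability,
an escape drift pulls the animal back toward the shallow half while it is
deep, and deep-side movement noise is mildly damped. The drift matters:
damping alone is diffusive slowing, which *lengthens* deep residence and
cancels itself (we measured exactly that). Together these reproduce the
direction of the behavioral findings: lower deep-side
distance ratio, lower deep-side median speed, and deep-side travel more
concentrated in the centre band at the deeper setting. The centre-zone
metric is defined as deep∩centre path length over deep path length (the
phrasing "distance ratio in the centre zone of the deep side" is ambiguous;
this reading matches the reported direction under our avoidance model).

*VSLM*: per trial, a 1 s inter-trial phase, a 2–5 s start-box dwell with a
two-state Markov head-orientation series (mean bout 0.6 s; probability of
facing the correct arm 0.7 on correct trials, 0.3 on incorrect), a junction
crossing fixing t0, a run along the chosen arm (the rewarded arm is always
the 40 cm arm; its side is re-randomised each trial), and a 1 s reward
dwell. Planted accuracy (default 0.8) sets the correct-trial fraction.
Orientation is emitted directly as a binary series — the source analysis
itself binarizes head orientation, so simulating keypoint geometry for it
would add nothing testable.

*Linear track*: back-and-forth runs (default 60 cm — the source never
states the track length; 60 cm matches the maze-arm scale) with 0.5 s turn
pauses. Two behavioral realism ingredients matter downstream: goal-anchored
deceleration (speed ramps down over the final 10 cm to 40%, and up over the
first 4 cm) and a mixed population of direction-gated (half) and
bidirectional (half) place fields — both textbook findings on linear
tracks. Prospective coding is modelled as *anticipatory position coding*:
with lag $\ell$, cells fire by the upcoming position
$\mathrm{clip}(x + d\,\ell,\ 0,\ L)$ where $d$ is the running direction, so
firing leads each field centre by $\ell$ along the direction of travel and
saturates against the goal over the final $\ell$ centimetres; $\ell = 0$ is
pure allocentric coding.

### What the prospective signature does — and does not — do here

A decoder trained and tested on samples from the *same* stationary world
learns whatever stationary pattern-to-label map exists. A rigid displacement
of fields by the lag is therefore absorbed into the learned map and leaves
signed errors balanced; we verified this directly (flat sign fractions
across lags under sample-wise splits), and it is worth stating because it is
easy to assume otherwise. What *does* survive self-consistent training is
the interaction of degenerate pattern regions with occupancy priors: where
several positions share a pattern — the direction-pooling reflections of
bidirectional cells, the turn-adjacent windows that mix directions, and the
goal-side saturation zone where anticipated positions collapse onto the
goal — the forest's class votes are settled by occupancy, which the
goal-approach deceleration tilts toward the goal. In this world that
produces the qualitative signature of the original finding: on
relative-position decoding the positive ("decoded closer to the goal")
error fraction sits at roughly 0.54–0.57 across seeds while plain signed
errors on actual-position decoding stay balanced by left/right symmetry.

It does **not**, however, produce a fraction that rises monotonically with
the planted lag from exactly 0.5 at lag 0 — one stated acceptance criterion
expects that, and we leave it red rather than engineer it. The two demands
conflict: any occupancy asymmetry strong enough to bias degenerate votes
goalward acts at lag 0 as well (the confusion regions exist without any
lag), and the lag's own contributions (saturation zone growth, decaying
reflection confusions as displaced fields disambiguate direction) move the
fraction in opposite directions at different lags. We measured this across
five generator variants (with/without deceleration, bidirectional vs
direction-gated populations, anticipatory vs trailing displacement): lag-0
fractions land at 0.53–0.57 and the lag profile is U-shaped or decreasing,
never cleanly rising. In a real animal the analogous bias presumably rides
on behavioral and neural nonstationarities that a stationary generator
deliberately lacks.

For the track analyses we hold out contiguous 5 s blocks rather than fully
random samples: the 1 s windows at 0.2 s steps overlap fivefold, and
sample-wise splits leak near-duplicate windows across the train/test
boundary, letting the forest resolve even degenerate patterns by
memorisation and erasing every confusion-based effect. Sample-wise
splitting remains the default elsewhere, matching the original wording.

The signed-error conventions follow the figures they mirror: for
relative-position targets, positive means the predicted distance-to-goal is
smaller than the actual one; for actual-position targets the plain sign of
predicted − actual is used (its balance is the allocentric claim), with
projection onto the direction of travel available as an option.

## What a green test establishes — and what it does not

The generator emulates the *statistical shapes* the analyses assume:
Poisson events with planted tuning, causal-kernel traces with Gaussian
noise, realistic rates, bouts, dwell times and speed profiles, geometry and
per-session footprint jitter. It does not emulate pixel-level imaging,
CNMF extraction artefacts (crosstalk, duplicates), pose-estimation error
structure, reward-learning dynamics, slow drift, or any nonstationarity
across a session. A green recovery test therefore establishes that the
estimator/selection logic is correct and well-calibrated under its own
assumptions — not that those assumptions hold for any particular real
recording. Conversely the null-calibration tests (untuned cells selected at
~5% by a 95% interval; unbiased walks giving deep ratios of 0.5) would catch
machinery that manufactures selectivity from autocorrelation alone, which is
the main real-world failure mode this class of analysis has.

## Known limitations

- The kNN MI estimator is the plain continuous/discrete form; no bias
  correction beyond the digamma terms is applied, so per-cell MI values are
  comparable within a session but not across very different sample counts.
- Greedy nearest-pair cross-registration can swap members of footprint
  pairs closer than the jitter scale; optimal assignment would remove the
  (rare) swaps at extra cost.
- The area score aggregates whole maps; cells with spatially antagonistic
  but balanced depth modulation cancel to a score near 0 and are missed by
  design, mirroring the original statistic.
- Choice decoding reports accuracy from modest trial counts; with fewer
  than ~20 trials per class the time course is noisy, and the pipeline
  averages five splits per time bin to stabilise it.
- Everything downstream of event extraction trusts the event times; no
  attempt is made to re-detect events from traces.
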