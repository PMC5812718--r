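---
title: "Simulating multi-pipette autopatching control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating multi-pipette autopatching control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multipatchr)
```

## The problem

Blind in vivo whole-cell patch clamping proceeds through a fixed sequence of
stages: pipette quality control in the bath, descent to the target depth
under high positive pressure, a clog check against the surface resistance
("regional localization"), stepwise neuron hunting guided by the seal-test
resistance, gigaseal formation under suction and hyperpolarization, and
break-in by suction pulses. Running several such robots in the same
craniotomy couples them mechanically: one pipette's motion displaces tissue
and can dislodge the neurons the others are holding, and a contact that
waits for its gigaseal attempt degrades. How the pipettes' stationary and
moving tasks are scheduled against each other therefore determines the
yield of the whole array.

`multipatchr` reproduces this control problem entirely in software: a
stochastic **virtual rig** stands in for pipettes-in-tissue, a
discrete-event **controller** implements the coordination strategies, and
**campaign statistics** aggregate trials into the stage funnel a rig
operator would report. Because the rig is synthetic, coordination policies
can be exercised over tens of thousands of trials with exact
reproducibility, something impossible on hardware.

## The seal-test signal chain

The controller never sees ground truth; it sees resistances estimated from
square-wave seal tests, and the package models that chain explicitly.

* **Stimulus** — 10 mV, 10 Hz square wave sampled at 15 kHz
  (`square_wave_stimulus()`). The 10 mV figure is interpreted as the
  *peak-to-peak* command amplitude, so that resistance is the applied
  voltage divided by the peak-to-peak current with no factor of two. This
  convention is applied consistently everywhere.
* **Forward model** — `synthesize_current()` returns the resistive plateau
  `V/R` plus a first-order capacitive transient at each voltage edge with
  time constant `R*C` and amplitude `dV/R` (so each edge delivers the
  charge `dV*C`), plus Gaussian noise of a chosen RMS.
* **Filters** — a 13-tap triangular moving average (half-width six samples,
  linear weights normalized to unit sum, reflect padding at the edges) and
  a first-order exponential smoother with a 1 ms time constant
  (`triangular_moving_average()`, `exponential_settle_filter()`). The
  exponential filter's published description gives a single time parameter
  only; a causal first-order IIR smoother is the one digital filter with
  exactly that parameterization, and is what is implemented. Both filters
  have unit DC gain.
* **Estimator** — `estimate_resistance()` measures each cycle's
  peak-to-peak current as the difference of plateau means over the last
  25% of each half-cycle (after transients have settled) and takes the
  median across cycles; this is robust to residual capacitive spikes.
  A zero peak-to-peak current raises a `measurement_failure` condition: it
  indicates an amplifier or valve fault, not a resistance.
* **Averaging** — every resistance consumed by the control logic is the
  arithmetic mean of five consecutive estimates (`averaged_resistance()`).

Units are fixed throughout: mV, pA/nA, MOhm, seconds. No unit inference is
performed.

## The virtual rig

`tissue_model()` holds the stochastic structure of pipette-tissue
interaction. Each default is either a maximum-likelihood proportion of a
recorded stage count or a single modelling choice, made once:

| parameter | default | provenance |
|---|---|---|
| clog on descent | 31/164 | observed blockage rate at localization |
| seal success, immediate | 77/133 | gigaseal rate of the interleaved strategy, whose attempts start with no waiting |
| seal success decay | 0.70 per minute of waiting | chosen so that the multi-minute waits typical of the synchronized strategy drop the per-pipette seal yield of waiting pipettes to roughly the recorded 8/49, once combined with dislodgement |
| dislodge per waiting episode | 10/49 | fraction of waiting pipettes whose resistance fell back to its pre-contact baseline |
| replay recontact | 27/59 | fraction of contacts re-established after the 30 um retract-and-replay manoeuvre |
| held-seal loss | 5/77 | gigaseals lost while waiting for break-in |
| break-in per pulse | `1 - (1 - 52/72)^(1/10)` | calibrated so a 10-pulse attempt on a *retained* seal succeeds with probability 52/72, which together with the 5/77 loss channel reproduces the 67.5% attempt-level break-in rate |
| encounter hazard | 0.005 per 2 um step | not directly recorded; chosen so the median hunt is ~140 steps (~280 um) and a full four-pipette trial stays in the reported ~10 min range |
| contact ramp | +0.15 MOhm/step for 4 steps, then plateau | guarantees the 0.25 MOhm/3-step detector fires on a true contact |
| seal growth | saturating, 15 s time constant, 1.5x boost under suction or holding <= -35 mV, asymptote 1500 MOhm (success) or +60 MOhm (failure) | chosen so a success-fated attempt passes 1 GOhm within the 60 s schedule and a failure-fated attempt stays below a 100 MOhm rise at the 35 s checkpoint |

Pipette bare resistances are drawn uniformly from the 5–9 MOhm fabrication
range, while the controller's QC acceptance range is the wider 3–9 MOhm;
the two ranges are deliberately kept distinct.

Dislodgement is evaluated once per *waiting episode* (the whole period a
held contact is exposed to other pipettes' movement), not per 2 um step,
because the recorded 10/49 figure is an episode-level fraction. Whether
dislodgement also occurs during a neighbour's gigasealing suction is not
resolvable from the available observations; it is modelled as
movement-only. Every stochastic draw consumes one global RNG stream in a
fixed, documented order (QC measurements, clog draws, localization
measurements, detection-step draws, then variant-specific fate draws), so
a seed reproduces a trial bit for bit.

Within a trial the controller advances hunting in *bouts*: the number of
steps to each pipette's next encounter is drawn from the geometric
distribution implied by the per-step hazard, which is distributionally
identical to stepping one Bernoulli draw at a time (the geometric
distribution is memoryless) and keeps ten-thousand-trial ensembles cheap.
The per-step operation `hunt_step()` remains the rig's ground-truth
definition and the two paths are tested against the same closed forms.

## The controller

`run_trial()` executes one full trial. The common prologue applies QC
(inclusive 3–9 MOhm), descends at 200 um/s under +800 mBar, drops to
+25 mBar, and deactivates any pipette whose resistance rose by strictly
more than 0.35 MOhm. Detection requires the last three step-to-step changes
of the averaged resistance to be non-decreasing (each change above a
-0.01 MOhm noise tolerance; strict monotonicity on noisy data would never
fire) with a cumulative rise strictly above 0.25 MOhm. All thresholds
resolve boundaries the way their verbal definitions do: QC inclusive,
localization and detection strictly greater-than.

The gigasealing program (`gigaseal_schedule()`) is the fixed 60 s sequence:
10 s at low positive pressure, 5 s atmospheric, 10 s low suction, an
instantaneous switch to atmospheric plus -35 mV holding, a 30 s linear ramp
to -70 mV, and a 5 s hold. The six durations must total 60 s, which forces
the pressure-release/voltage-switch step to be instantaneous; the ramp
therefore begins 25 s into the schedule. An optional abort policy
terminates an attempt at 35 s when the resistance rise is below 100 MOhm,
mirroring the operator's manual override.

Three coordination strategies are implemented:

* `sync_all` — hunt independently, deactivate each detecting motor, then
  gigaseal all pipettes simultaneously off the shared valve bank (all
  pressure switches carry identical timestamps). Held contacts are exposed
  to dislodgement and to the waiting decay.
* `retract_replay` — each detection retracts the pipette 30 um; when all
  are done, all advance 30 um together and seal synchronously. Replayed
  contacts are only re-established with probability 27/59.
* `interleaved` — all pipettes step together; any detection halts
  everything, the detecting pipette seals alone (waiting time zero), and
  the rest resume. Gigasealed pipettes hold at -70 mV, keep maturing, and
  are immune to motion artifacts; break-in is simultaneous at the end.

Simultaneous detections are resolved by lowest pipette index — a
deterministic tie-break where the underlying procedure is silent. A pipette
that exhausts its hunting budget (3000 um of travel past the start depth by
default, chosen so fewer than one hunt in a thousand ends empty-handed) is
deactivated. The synchronized variants run the identical 60 s schedule —
the development record states the earlier iterations sealed "identically",
and no alternative schedule is documented. Break-in at "the operator's
command" is modelled as immediate, with a configurable delay.

Every phase change is validated against the declared transition graph
(`phase_transitions()`); an illegal transition raises a
`protocol_violation` condition rather than proceeding silently.

## What the simulation does and does not show

With the default calibration the interleaved strategy's simulated gigaseal
rate among active pipettes is ~58% and its per-pipette whole-cell rate
~32%, matching the stage counts it was calibrated from — that is a
consistency check of the funnel arithmetic, not an independent prediction.
The informative outputs are *comparative*: the synchronized and
retract-and-replay strategies land far below the interleaved strategy
(~35% and ~17% simulated gigaseal yield), reproducing the recorded
*ordering* of the three development iterations. The absolute levels of the
two synchronized variants are not forced to their historical values
(~22% and ~20%): those campaigns were run under earlier surgical
preparations, whereas the rig models a single condition; in particular the
rig gives a non-waiting pipette its full 58% success probability where the
historical synchronized campaign recorded 36.8% for its immediately sealing
pipettes. The package asserts the ordering, and reports the levels.

The rig also simplifies real tissue in ways worth keeping in mind: no
spatial 3-D mechanics or brain pulsation (awake-like motion is only an
elevated dislodge probability), no biophysics beyond a lumped R/C circuit,
no electrode drift or amplifier artifacts, and dislodgement collapsed to
one draw per waiting episode. Passing tests demonstrate that the control
logic is faithful to its specification and statistically consistent with
the recorded stage counts — not that the rig predicts biology.

## Numerical and testing choices

Measurement noise defaults to 0.005 MOhm SD, small against the 0.15
MOhm/step contact ramp. Trial timing uses 0.5 s per 2 um
advance-and-measure step (a cadence the hardware description does not pin
down) and 200 um/s descent; simulated interleaved trials then take ~6.5
min of robot time, consistent with reported trial times once manual
pipette installation is excluded. Test ensembles use 10,000 trials for the
coordination invariants, 5,000 trials per variant for the ordering
comparison, 200 replicate campaigns of 41 trials for calibration coverage,
and 1,000 seeds for the signal-chain bias check; these sizes put 3-sigma
binomial bands well inside the effects being asserted while keeping the
whole suite to a few minutes.

```{r}
yield_stats(make_anesthetized_fixture())
```

The deterministic fixtures above encode the published campaign counts
exactly; the pipette-level and trial-level awake fixtures are kept separate
because the printed pipette-level count (67/388) and trial-level counts
(37 singles + 17 duals/triples) are mutually inconsistent, and the 14/3
dual/triple split of the awake multi-recording trials is an arbitrary legal
choice no statistic depends on.
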