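---
title: "Metrology of instrumented-insole gait parameters: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metrology of instrumented-insole gait parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insolemetry)
```

## The measurement problem

Pressure-sensing insoles with 18 capacitive cells per foot, sampled at
110 Hz with 8-bit digitization, estimate two families of gait quantities:
the spatio-temporal phase durations of each gait cycle (stance, swing,
single support, double support) and the vertical ground reaction force,
approximated by the summed cell pressure in kg/cm². Before such a device
can be used to monitor patients, two metrological questions must be
answered: how repeatable are its outputs across repeated tests
(*repeatability*), and how large a true change can it resolve
(*responsiveness*)? This package implements that analysis end to end —
including a synthetic dual-foot recording generator with known ground
truth, because raw recordings from such protocols are generally not
publicly deposited and every downstream stage must still be testable.

The experimental design the package emulates is a single-subject protocol:
6-minute walk tests (TDM6) under eight conditions — overground, a dual-belt
treadmill with equal belt speeds (1.2 m/s), and six conditions in which one
belt is sped up by 16%, 33% or 50% (1.4, 1.6, 1.8 m/s) to induce a
controlled gait asymmetry — with three trials per condition
(`condition_presets()`).

## Event detection

Gait events are detected on the summed cell signal $S(t)$ (the sum of the
18 cells of each frame; when a recording carries 8-bit raw counts the sum
is taken on that scale, since the detection constants live there):

* **Initial contact** at sample $t$ when $dS/dt > 0.2$ at $t$ and
  $S > 50$ at $t + 100\,\mathrm{ms}$;
* **Toe-off** at sample $t$ when $S < 30$ at both $t$ and
  $t + 100\,\mathrm{ms}$.

At 110 Hz the 100 ms look-ahead is exactly 11 samples; other rates round
to the nearest sample. $S$ is smoothed with a Savitzky–Golay filter
(window 11, order 3 — both configurable, as the device's actual settings
are unpublished). Within any maximal run of samples satisfying a
predicate the first sample is reported, like events are debounced by
100 ms, and the final look-ahead window of a recording cannot host
detections.

Two numerical choices deserve explanation:

* **Derivative scale.** $dS/dt$ is the first difference *per sample*, not
  per second. On the 8-bit count scale a per-second scaling at 110 Hz
  would multiply single-count quantization flicker by 110, pushing it far
  above the 0.2 threshold; per-sample differencing keeps the threshold
  meaningful. The choice is recorded in `detection_thresholds()` so it
  can be flipped.
* **What gets smoothed.** The amplitude tests use the smoothed sum, but
  the derivative test uses the *unsmoothed* sum by default
  (`smooth_derivative = FALSE`). A centred least-squares filter leaks a
  sharp loading edge backwards by up to half a window; with an edge of
  tens of counts per sample, that pre-echo crosses the tiny 0.2 slope
  threshold two to three samples before the foot actually touches down,
  and every detection would be systematically early. Differencing the raw
  sum restores one-sample accuracy while the 50/30 amplitude rules still
  benefit from smoothing. Setting `smooth_derivative = TRUE` reproduces
  the fully-smoothed variant.

A third, structural choice: the double-bump force profile re-loads the
forefoot mid-stance, so the IC predicate also fires on the second lobe's
rising flank. These within-stance episodes are suppressed by the
alternation constraint in `build_event_sequence()` (events must alternate
IC, TO, IC, …), which drops them into a diagnostics counter rather than
the event list.

## Cycle parameters

A gait cycle is ipsilateral IC → next ipsilateral IC; the first and last
cycles of every trial are discarded (boundary effects). Per cycle
(`compute_phase_durations()`):

* stance $= TO - IC$, swing $= IC' - TO$;
* **double support** is the time within $[IC, TO)$ during which the
  contralateral foot is also in stance, computed by interval
  intersection. Normal gait contributes two sub-periods per cycle (one at
  each end of stance); they are **summed** — reported double-support
  durations of ~310 ms against ~730 ms stances (about 43% of stance) are
  only consistent with the summed reading;
* single support $= \mathrm{stance} - \mathrm{double}$, attributed to the
  supporting foot. By construction single + double = stance and stance +
  swing = cycle hold to machine precision, and the pipeline asserts them
  on every run. A cross-check follows from the geometry: one foot's
  single support equals the other foot's swing, up to detection jitter.

**Mean force during single stance** is the arithmetic mean of the
smoothed summed pressure over the samples in the cycle's single-stance
interval(s), divided by a configurable normalization (`force_scale`,
default 1) because the device's exact 18-cell-to-kg/cm² mapping is
unpublished. **Force curves** are linearly interpolated onto 101 evenly
spaced points across stance — not the full cycle, since the signal is
identically ~0 in swing; both grid size and the stance-only convention
are configurable.

## Reliability and responsiveness statistics

For each parameter, foot and condition, with $\sigma_i^2$ the sample
variance (denominator $n_i - 1$; the source protocol does not state the
denominator, this is our choice) across the cycles of trial $i$:

$$\mathrm{SEM} = \sqrt{\tfrac{1}{n}\sum_{i=1}^{n} \sigma_i^2}, \qquad
\mathrm{MDD}_{95} = 1.96\,\sqrt{2}\,\mathrm{SEM}, \qquad
\mathrm{ES} = \frac{\bar{x}_\mathrm{asym} -
\bar{x}_\mathrm{without}}{\sigma_\mathrm{without}}$$

For the force parameter the SEM is computed at each of the 101 normalized
stance instants and then averaged (`curve_sem()`). Repeatability uses the
average-measures consistency intraclass correlation from a two-way
mixed-effects ANOVA, $\mathrm{ICC}(3,k) = (BMS - EMS)/BMS$, with rows the
cycle indices truncated to the minimum common cycle count across the
three trials and columns the trials. What the source protocol paired
across trials is unstated; pairing by cycle index is isolated in one
function (`cycle_trial_matrix`) so alternatives (e.g. per-minute means)
can be plugged in. Note a structural consequence for *synthetic* data:
our generator draws cycles independently around a trial mean, so rows
carry no stable effect, the consistency ICC of simulated conditions is
near 0, and high ICCs like those observed on real walkers (where slow
physiological drifts correlate cycles of the same rank) are *not*
reproduced — recovery of known ICCs is instead tested with
`simulate_parameter_table()`, which draws from the two-way model
$y_{ij} = \mu + s_i + e_{ij}$ with closed-form
$\mathrm{ICC}(3,k) = \sigma_s^2/(\sigma_s^2 + \sigma_e^2/k)$.

Aggregation rules (`aggregate_report()`): reported means and sds are of
the per-trial means; the MDD row of each parameter uses the **largest**
SEM across feet, and the pooled treadmill-asymmetric group uses the
largest SEM across all six asymmetric conditions; effect sizes are
computed per asymmetric condition, foot and duration parameter against
both reference conditions (overground, O–TA, and symmetric treadmill,
T–TA), with a census of classification bins. Force is excluded from
effect sizes: force profiles are individual-specific, so standardized
differences on them are not meaningful in a single-subject design.
Classification bins are closed on the lower edge of the higher category
(ICC 0.80 → "very good", |ES| 1.2 → "very large"); the conventional
strict-inequality phrasing leaves boundaries unassigned, so a tie-break
had to be chosen and documented. Percent columns are computed from
unrounded values internally; the display formatter
(`format_value_percent()`) derives the percent from the *rounded* value
so that printed cells are self-consistent (0.86/8.13 → "10.58%").

## The synthetic-data generator

`simulate_condition()` emulates the study conditions with a steady-state
alternating-gait model. Both feet share one cycle duration (~1.145 s at
1.2 m/s, i.e. a ~64% stance fraction giving the conventional
730/415/310 ms stance/swing/double-support split); the contralateral IC
sits at 50% of the cycle. Per trial, trial effects are drawn for cycle
duration, stance duration and force amplitude (between-trial sds ~10 ms /
0.03 kg/cm², on the scale of reported trial-mean spreads); per cycle,
step-to-step noise is added (within-trial sds ~5–8 ms, matching reported
treadmill SEMs of ~3–6 ms; the overground condition inflates step noise
8× and trial effects 1.7×, reflecting that unpaced walking is far noisier
step-to-step than trial-to-trial). Each stance is rendered as a
double-bump profile — two Gaussian lobes at 28% and 72% of stance over a
plateau, with a short loading/unloading ramp and a small contact floor so
that touchdown and lift-off are abrupt on the sampling grid — distributed
over 18 cells in three region groups (heel/midfoot/forefoot) whose
envelopes shift activation from heel to forefoot through stance. The
profile targets *plausibility*, not biomechanical validity: capacitive
summed-pressure profiles are known not to match force-platform curves,
and no published profile model exists for this device.

Split-belt asymmetry: the foot on the faster belt reduces its stance
fraction by `asym_stance_gain` (0.33) per unit of speed ratio above 1,
the non-driven foot barely (0.04), and the cycle shortens mildly with
mean speed. Because double support in steady alternating gait equals
stance_left + stance_right − cycle, shortening the driven stance
automatically shrinks double support *for both feet* — the two
qualitative findings the pipeline is required to reproduce (driven-foot
stance reduction growing with the speed ratio; bilateral double-support
reduction) emerge from one mechanism. One caveat is worth stating
plainly: with a common cycle duration, a shorter driven stance forces a
*longer* driven swing; published single-subject tables that pool
conditions can show all driven-leg phases shrinking together, but that
pattern cannot hold cycle-for-cycle in steady state, so the package's
directional checks deliberately cover stance, single support and double
support only.

The gain 0.33 was fixed once so that the 50% condition produces a
driven-leg stance reduction of the same direction and order as reported
single-subject values (~580 vs ~710 ms); reproducing those means is
explicitly not claimed. Identical configuration and seed give
bit-identical output; trials use deterministic substreams of the
condition seed.

### What passing tests do and do not show

The generator reproduces: sampling geometry, 8-bit quantization,
double-bump stance loading, two variance tiers (within/between trial),
phase geometry with exact ground truth, and belt-speed-induced stance
asymmetry. It does not reproduce: the covariance structure of real gait
(e.g. physiological regulation that makes real double-support less
variable than its ingredients, or slow drifts that correlate cycles
across trials and produce high real-data ICCs), turning during overground
walking, fatigue/accommodation, or validated GRF shapes. Tests passing on
synthetic data therefore validate the *algorithms and statistics*, not
the device.

## Problem sizes and tolerances

The test-suite and the acceptance script run trials of 60 s (~52
cycles/foot/trial; the protocol value of 360 s is the generator default)
— large enough that every stochastic check has comfortable margin while
the whole suite stays fast. Event-recovery is asserted to 1 sample
(9.1 ms) on zero-noise data and 2 samples MAE under realistic noise; ICC
recovery on 500×3 tables to ±0.05 of the closed-form 0.75; SEM recovery
to 10% at 200×3; the phase identities to 10⁻⁹ ms. Degenerate inputs
(empty event lists, cycles without single support, stances of < 2
samples, missing ICC cells beyond 25%) are flagged or rejected with
informative errors rather than silently patched.

## Known limitations

* Single-virtual-subject design: like the protocol it mirrors, nothing
  here generalizes across subjects; SEM/MDD values describe the
  instrument + algorithm chain, not a population.
* The 3-trial sd used as the effect-size denominator is itself very noisy
  (a χ₂-distributed estimate), so individual simulated effect sizes can
  be extreme; the census over all 96 cases is the stable summary.
* The CSV schema is a documented stand-in; the real device export layout
  is proprietary and unpublished.
* Threshold units: whether the device applies its 0.2/50/30 constants
  to raw counts or calibrated pressure is unpublished; we default to raw
  counts when present, and both channel and constants are configurable.
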