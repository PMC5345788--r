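---
title: "Measuring GABA-A mIPSC decay kinetics from synthetic voltage-clamp recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring GABA-A mIPSC decay kinetics from synthetic voltage-clamp recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Miniature inhibitory postsynaptic currents (mIPSCs) are the spontaneous,
action-potential-independent currents carried by synaptic GABA-A receptors in
whole-cell voltage-clamp recordings. Their decay time course is the standard
functional readout of synaptic GABA-A receptor kinetics: it shortens during
development and is prolonged by positive allosteric modulators such as the
neurosteroids allopregnanolone and ganaxolone. The decay is summarised by the
weighted decay time constant

$$\tau_w = \tau_{fast} P_1 + \tau_{slow} P_2,$$

where $\tau_{fast}$ and $\tau_{slow}$ are the two time constants of a
biexponential fit
$y(t) = A_{fast} e^{-t/\tau_{fast}} + A_{slow} e^{-t/\tau_{slow}}$ to the
decay of the *mean* mIPSC of a neuron, and $P_1, P_2$ are the proportions of
the decay carried by each component. Because raw recordings for this kind of
study are typically not deposited, the package pairs the analysis pipeline
with a synthetic trace generator whose ground truth is known exactly, so that
the whole chain - detection, per-event kinetics, averaging, fitting, model
selection, cohort statistics - can be validated closed-loop.

## The synthetic event and what it emulates

`event_waveform()` builds the canonical event: a saturating-exponential rise
$1 - e^{-t/\tau_{rise}}$ (default $\tau_{rise}$ = 0.3 ms, giving a 10-90%
rise time of about 0.66 ms, safely below the 1 ms acceptance bound for
somatically generated events) joined *at the peak* to an exact biexponential
decay with amplitude fractions $p_{fast}$ and $1 - p_{fast}$. We deliberately
did not use the common product form
$(1 - e^{-t/\tau_{rise}}) \times \text{decay}(t)$: with a product, the
post-peak samples are only asymptotically biexponential, whereas the
piecewise form makes every post-peak sample lie exactly on the model the
kinetics module fits. That keeps the closed-loop contract sharp - on
noiseless input the fitted parameters must reproduce the generator's to
fractions of a percent, with no modelling slack to hide implementation
errors. The junction leaves a slope discontinuity at the peak; after the
2 kHz acquisition filter it is invisible.

`simulate_sweep()` draws Poisson event onsets, log-normal peak amplitudes
(strictly one-signed and right-skewed, like real minis), adds white Gaussian
baseline noise, and low-pass filters the whole trace (signal plus noise) with
a 4-pole Butterworth at 2 kHz applied forward-backward. Zero-phase filtering
is our choice: it leaves onset times and rise midpoints unbiased, which
matters because events are later aligned on the rise midpoint. A ground-truth
table records every injected event.

### Generator defaults the source data do not fix

The study conditions fix the cohort sizes and the group means and SDs of
$\tau_w$; they do not state event frequencies, amplitude distributions or
noise levels. Those defaults are ours, chosen once to be typical of good
adult whole-cell recordings and then left alone:

| parameter | default | why |
|---|---|---|
| amplitude mean | -40 pA (CV 0.4, log-normal) | typical mIPSC amplitude scale; CV of real mini distributions |
| event rate | 1.2 s^-1 | mini frequency in the usual 0.5-5 Hz range; keeps most events isolated |
| injected events per cell | 120 | leaves >= 50 accepted, non-overlapped events after detection losses |
| sampling rate | 10 kHz | 5x the 2 kHz filter corner |
| baseline noise SD | 1.5 pA white (about 1.05 pA after the filter) | a -5 pA threshold then sits at about 4.7 filtered-noise SD, the regime in which threshold detection is usable at all |
| tau decomposition | $p_{fast} = 0.55$, $\tau_{fast} = 0.4\,\tau_w$ | mid-range amplitude fractions; $\tau_{slow}$ then follows exactly from $\tau_w$ |

Cohort presets (`preset()`) carry the printed group values for the spinal
lamina II and nucleus reticularis developmental series. The adult cortex
control levels anchor the percent-of-control treatment arms but are not
printed in the available text; they are synthetic (flagged as such on the
preset) and chosen in the physiological range for mature cortical neurons
(ob/ob control 9 ms, WT 11 ms). Treatment presets are defined as
multiplicative $\tau_w$ shifts of their control (362% and 534% for 100 and
300 nM allopregnanolone incubation), applied proportionally to both decay
components. The printed dispersions of those effects are percentage points on
the percent-of-control scale, so the treated across-cell SD is that fraction
of the *control* mean.

Per-cell $\tau_w$ jitter is carried by $\tau_{slow}$ alone (one-knob
identifiability: $\tau_{fast}$ and $p_{fast}$ stay at the preset), scaled so
the across-cell SD of true $\tau_w$ equals the printed group SD. Per-cell
seeds hash both the master seed and the preset name, so different cohorts
simulated from one master seed are statistically independent.

## Detection

`detect_events()` works on the baseline-subtracted trace. A candidate is a
sample that is below the amplitude threshold (default -5 pA) *and* was
reached on a steep downstroke (a drop of at least 60% of the threshold over
the preceding 0.5 ms, measured on a 0.3 ms-smoothed copy, with an adaptive
floor of four SDs of the differenced noise). The downstroke condition plays
two roles: it suppresses noise re-crossings while an earlier event's tail
hovers near threshold, and it exposes events that arrive while the trace is
still below threshold - such riding events never re-cross the absolute
threshold and a plain crossing detector silently merges them into their
host, which contaminates the mean event's tail. The onset is localised by
walking back to the last sample inside the baseline noise band (or to the
local maximum for riding events; never past the previous trigger), and the
peak is the minimum of the excursion.

Acceptance applies the printed criteria: peak amplitude at least -5 pA,
duration (onset to return within one noise SD of baseline) longer than 2 ms,
10-90% rise time at most 1 ms. The study's manual inspection step is
replaced by two automatic screens: the excursion must also reach the
threshold relative to the immediately pre-onset level (a noise dip riding on
a decaying tail does not), and the waveform must correlate with the
canonical event template (default r >= 0.5). Events with a neighbouring
onset within 300 ms before or 150 ms after are measured but flagged
`overlap` and excluded from mean-event construction; the asymmetry reflects
that a *preceding* event contaminates through its long decay tail whereas a
*following* event matters only inside the averaging window.

Recording-level QC is strict-boundary: a recording is invalid when the
series resistance changed by more than 20% or exceeded 15 MOhm; exactly 20%
or exactly 15 MOhm still passes.

### Baseline

A single running median is robust but biased: the decaying tails of the
events themselves drag it down wherever events cluster, and the subtraction
then clips the slow component of the mean event (we measured several percent
of $\tau_w$). The pipeline therefore runs two passes: a 0.4 s running median
locates the events, then `refine_baseline()` masks each event from 2 ms
before its onset to about 12 median T70s after it, averages the remaining
quiet samples in 100 ms blocks, and interpolates across the masked gaps. The
final detection and averaging pass uses the refined baseline.

## Averaging and fitting

`average_events()` aligns accepted, non-overlapped events at the interpolated
50% point of their baseline-to-peak rise and averages them pointwise on a
common grid (10 ms before to 150 ms after the midpoint), with sub-sample
alignment by linear interpolation. `decay_fit()` fits the mean event from its
peak to the end of the grid - the decay window is bounded in practice by the
neighbour-exclusion rule, which guarantees 150 ms of uncontaminated decay.

Both decay models are linear in their amplitudes, so the fits profile the
amplitudes out in closed form (variable projection) and optimise only the
time constants: a golden-section search on $\log\tau$ for the
monoexponential, and Nelder-Mead over $(\log\tau_{fast}, \log\tau_{slow})$
for the biexponential, multi-started from the best cells of a coarse
log-spaced grid plus two heuristic starts around the monoexponential
solution. Amplitudes are constrained to the sign of the peak (a component
that would flip sign is clamped to zero), $\tau_{fast} < \tau_{slow}$ is
enforced by sorting, and because the biexponential family nests the
monoexponential, the reported biexponential SSE is never allowed to exceed
the monoexponential SSE. We moved to this scheme after bounded
Levenberg-Marquardt proved fragile precisely in the configuration the F test
cares about most - monoexponential truth, where the two components collapse
and the Jacobian is singular.

Model selection uses the extra-sum-of-squares F test,
$F = [(SSE_{mono} - SSE_{bi})/2] / [SSE_{bi}/(n-4)]$, with SSEs recovered
from the residual SDs as $SSE = sd^2 n$, at $\alpha = 0.05$ (the
significance convention used throughout; the variance-ratio form of the test
is a possible alternative reading of "an F test on the residual SDs", but
the extra-sum-of-squares form is the standard nested-model test). The SSEs
fed to the test come from the same tau search run *without* the amplitude
sign constraint: the nested F test is calibrated for unconstrained
least-squares families, and clamping amplitudes at the zero boundary under a
monoexponential truth removes part of the attainable noise improvement - we
measured type-I error near 2.5% with constrained SSEs (confirmed against an
independent bounded-least-squares implementation) versus the nominal 5%
without the constraint. The reported parameters remain the sign-constrained
ones; on genuinely biexponential data the two searches coincide.

For biexponential winners, $P_1 = A_{fast}/(A_{fast} + A_{slow})$ - the
amplitude-fraction reading of "proportions of the decay"; the area-fraction
alternative is available via `p_definition = "area"`. Mono-selected cells
report $\tau_w = \tau$ so cohorts mix model classes coherently. Simulated on
monoexponential-truth mean events sampled at the filter bandwidth (0.5 ms)
with independent noise of realistic mean-event magnitude, the test selects
the biexponential in about 5% of runs at $\alpha = 0.05$ and in essentially
100% of well-separated biexponential runs. One caveat is worth knowing: on a
mean event sampled at the full 10 kHz acquisition rate, the 2 kHz-filtered
residuals are strongly autocorrelated and the iid-based F test becomes
anti-conservative; this never matters for the cohorts simulated here (whose
decays are unambiguously biexponential, with enormous F), but a borderline
mono/bi decision on oversampled data should be made at bandwidth-matched
sampling.

Cells enter cohort statistics only with at least 50 accepted events
(excluded cells are logged with a reason), matching the per-recording event
quota of the study design.

## Cohort statistics and behaviour

`cohort_compare()` wraps the classical battery - Student's t (pooled
variance), paired t, one-way ANOVA, and a repeated-measures ANOVA with
subject as the error stratum - and runs a hand-implemented Newman-Keuls
studentized-range stepdown (with harmonic-mean n for unbalanced groups) when
a one-way omnibus is significant; the stepdown is cross-checked in the test
suite against an independent implementation. Treatment effects are expressed
as percent of control with a delta-method SE. Comparisons labelled
"repeated-measures across strains" in the source figures involve cells that
are not actually measured repeatedly; the design argument makes the choice
explicit instead of guessing.

The behavioural module scores the three nociception assays: tail-flick
latency with a 15 s cutoff, expressed either as the baseline-subtracted
maximum possible effect (default) or as a simple percentage of the cutoff
(both readings of the assay description are implemented; the report names
the mode); von Frey response frequencies out of 10 presses per subject, with
the wild-type filament probabilities 20/40/60/90% for the
0.16/0.4/0.6/1 g filaments; and rotarod latencies censored at 300 s, with
the 6-to-50 rpm accelerating schedule (the increment interval is not stated;
the default 27 s spreads the 11 steps over the trial and affects only the
speed helper, not any statistic). Censored latencies enter the rank tests at
the cutoff with mid-rank tie handling. The behavioural generator draws
truncated-normal latencies (rotarod group values are the published ones;
tail-flick group means are plausible synthetic defaults) and Binomial(10, p)
von Frey counts, with elevated ob/ob probabilities for the sub-threshold
filaments (synthetic; only the direction is published).

## Problem sizes, determinism, degenerate inputs

The validation suite simulates the full printed cohort sizes (13-32 cells
per group, 120 injected events per cell at 10 kHz) for the spinal, nRT and
ob/ob series; F-test calibration uses 1000 monoexponential-truth
replicates. All simulation is seeded; identical (config, seed) pairs yield
bit-identical traces, and the RNG state of the caller is never disturbed.
Degenerate inputs have defined behaviour: a perfect biexponential fit
reports an infinite F and selects the biexponential; equal residual SDs
select the monoexponential with p = 1; all-tied paired differences give a
degenerate signed-rank p = 1 with a warning; an event truncated before 70%
decay keeps its amplitude and rise but flags T70 as missing; fewer than two
usable events refuse to average.

## What passing tests do and do not show

The generator emulates Poisson-arriving, template-shaped events with
stationary log-normal amplitudes on a flat, Gaussian-noise baseline. Real
recordings add slow baseline wander, seal and access-resistance drift,
multiquantal and electrotonically filtered events with variable rise,
temperature drift, and non-Gaussian artifacts (pipette relaxation, perfusion
transients). Recovery of preset kinetics here therefore validates the
*pipeline arithmetic* - detection rules, alignment, fitting, selection,
statistics - not robustness to every pathology of real data; the
template-correlation artifact screen in particular is a stand-in for, not a
replica of, expert visual inspection. Within that scope the pipeline
recovers cohort mean $\tau_w$ with a residual systematic error of about
0.3% (dominated by the 2 kHz filter, which the real experiment shares) and
per-cell noise well under the designed across-cell spread.
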