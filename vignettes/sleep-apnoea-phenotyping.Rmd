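---
title: "Sleep-apnoea phenotyping: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep-apnoea phenotyping: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepbreathr)
```

sleepbreathr turns three raw channels — whole-body plethysmograph airflow,
EEG and EMG — plus tracked maze trajectories into the standard phenotyping
read-outs for rodent sleep-disordered breathing: per-breath tidal volume
(V~T~), respiratory frequency (*f*) and minute ventilation
(V~E~ = V~T~ × *f*); a 5-s-epoch hypnogram over WAKE/NREM/REM/DOUBT;
apnoea/hypopnoea events with the apnoea–hypopnoea index (AHI) per hour of
sleep; Barnes-maze search strategies and Y-maze novelty preference; and the
group-level reporting conventions (normality-gated test choice, median with
the R~70~ spread). This vignette explains the models behind each stage, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical choices a maintainer would want recorded.

## Breath segmentation and ventilation

Airflow is segmented into breaths by locating inspiration peaks and pairing
each with the end-expiration trough that follows; V~T~ is the peak-minus-
trough amplitude converted to mL by the chamber's volumetric calibration and
standardised to body mass (mL·kg^−1^). Per-breath minute ventilation is
`vt * 60 / ibi`, so V~E~ = V~T~ × *f* holds exactly at the breath level, and
1-minute windows aggregate *f* as the mean of instantaneous rates.

Two bandwidths are involved, both zero-phase 4th-order Butterworth filters:

* a 20 Hz low-pass (`lowpass_hz`) defines the working trace;
* an 8 Hz "measurement band" (`amplitude_lowpass_hz`) on which peaks are
  localised and amplitudes are read. Rodent breathing sits below ~2.5 Hz, so
  8 Hz preserves the waveform; on wider bands, noise raises secondary maxima
  on breath flanks (inflating the count) and reading extremes at
  noise-jittered indices biases small-breath amplitudes upward — which
  matters because hypopnoea detection compares V~E~ against a 50% criterion.
  Amplitudes are the regional extremes of the smooth copy over each breath's
  own peak/trough region, which removes the curvature loss a point read
  would incur.

Breaths smaller than `min_amplitude_fraction` (default 0.3) of the median
amplitude are rejected — first against the recording-wide median (so bursts
of noise-born candidates cannot drag a local reference down to their own
level), then against a ~10 s rolling median for local adaptivity. Both
references scale with the trace, so detection is invariant to channel gain.
On clean traces you can lower the fraction (e.g. 0.02) to resolve the tiny
breaths inside deep apnoeas.

A sigh is an augmented breath with V~T~ above `k_sigh` (default 2) times the
rolling 60-breath median — the usual doubled-V~T~ convention, since sighs are
counted but not formally defined in this field's protocols. Sigh rates are
expressed per hour of sleep plus quiet wakefulness; operationally the
denominator is every epoch except active wakefulness (scored sleep, DOUBT
epochs — which at bout boundaries are overwhelmingly sleep — and WAKE epochs
with below-median muscle tone).

Resting (quiet-wakefulness) parameters are read on the earliest ≥ 60 s run
of non-sleep epochs with below-median WAKE muscle tone, reflecting the
convention of measuring respiratory parameters during calm wakefulness at
the start of a session. Resting *f* is computed by counting peaks over the
spanned time ("breaths per minute"), which is robust to occasional short
inter-breath intervals that would inflate a mean of reciprocals.

## Sleep staging

EEG is band-filtered into delta (0.5–4 Hz; the nominal 0 Hz edge of the
0–4 Hz delta band is raised to 0.5 Hz because a 0 Hz band-pass edge is not
realisable and DC drift should not count as delta) and theta (6–10 Hz). The
squared band signals and the squared EMG are smoothed by a first-order
exponential smoother with τ = 5 s (the stated smoothing time constant; the
smoother type is our choice, being the simplest causal RC analogue) and
sampled at the midpoints of 5 s epochs.

Classification applies rules in a fixed order per epoch:

1. **WAKE** iff EMG RMS > `emg_hi` — wakefulness is muscular, whatever the
   cortex does;
2. else **NREM** iff delta power > `delta_hi`;
3. else **REM** iff theta:delta > `td_hi` and EMG RMS is in the bottom
   decile (theta dominance with atonia);
4. else **DOUBT**.

Thresholds are per-recording feature quantiles, making the hypnogram
invariant to any affine channel rescaling by construction. The quantile
defaults are calibrated to the control sleep architecture
(WAKE/NREM/REM ≈ 46/48/6%): the WAKE rule must pass the WAKE share of
epochs, so `emg_hi` sits at the 54th percentile (1 − 0.46), and the NREM
rule must pass the NREM share, so `delta_hi` sits at the 52nd
(1 − 0.46 − 0.06); `td_hi` is the 75th percentile of the theta:delta ratio.
A quantile placed materially above the complement of a state's prevalence
caps how much of that state can ever be labelled, which would bias the
AHI's sleep-hours denominator; this is why the defaults are tied to the
architecture rather than chosen round numbers. All three are configuration
keys.

DOUBT epochs are excluded from state-fraction denominators and from total
sleep (sleep = NREM + REM), consistent with normalising the AHI "per hour of
total sleep". No post-hoc label smoothing is applied by default.

Because the smoother is causal with τ = 5 s, the first epoch of every bout
carries the previous state's band power (61% of the step remains at the
epoch midpoint). Transition-adjacent epochs are therefore excluded when
computing staging accuracy against a reference, and properties of the form
"every NREM epoch has delta > theta" are asserted on all epochs *except*
bout-initial ones — with this smoothing they cannot hold at the boundary,
whatever the stager does.

## Respiratory events and the AHI

A respiratory disturbance is a reduction in minute ventilation of more than
50% (hypopnoea) or more than 90% (apnoea) sustained for at least 1.8 s — a
duration chosen in the source protocol as roughly three breaths at the
rat's ~105 min^−1^ respiratory rate, and close to the ~1.875 s at which a
linear extrapolation of published desaturation-versus-apnoea-length data
reaches a 4% desaturation. `calibrate_min_event_duration()` implements that
extrapolation for any calibration line; the default remains 1.8 s exactly.

The reference ("baseline") V~E~ at each breath is a rolling median over the
preceding 60 s, computed twice: a provisional pass marks candidate events,
which are masked before the final pass so deep events cannot depress their
own baseline. Evaluation is breath-by-breath, which is what makes 1.8 s
events resolvable at ~100 breaths·min^−1^. Candidate runs separated by a
single breath are merged before the duration test (hand scoring would not
split an event on one noisy recovered breath). An event's span runs from
half a typical breath before its first low peak to just short of the first
recovered peak — a breath's V~E~ describes ventilation over its whole
inter-breath interval, which matters when one long interval spans an entire
apnoea because the in-event breaths fell below the amplitude gate.

Events take the state of their onset epoch; onsets in WAKE are discarded,
and onsets in DOUBT defer to the nearest scored sleep label (covered epochs
first, then immediate neighbours). Per-state counts and per-state dyspnoeic
seconds are each normalised by **total** sleep hours, so NREM and REM
figures sum exactly to the totals — the convention that per-state rates
share the whole-sleep denominator. An arousal is a transition into WAKE
from any non-WAKE label; an event is arousal-linked when one occurs within
15 s of its end, and the arousal is classed as post-event hyperpnoea when
mean V~E~ in the 5 s before it exceeds 1.2 × baseline.

## The synthetic-data generator

No raw recordings accompany the source study, so validation rests on a
generator whose defaults encode the two study arms:

| parameter | sham | dta (lesioned) |
|---|---|---|
| resting *f* (min^−1^) | 95 | 105 |
| resting V~T~ (mL·kg^−1^) | 3.6 | 2.3 |
| WAKE/NREM/REM (%) | 46/48/6 | 51/45/3.9 |
| injected events (h^−1^ sleep) | 9 | 30 |
| sighs (h^−1^ sleep+quiet wake) | 13 | 14 |

(The lesioned arm's printed state percentages sum to 102; they are
normalised onto the simplex.) Other defaults are realistic choices fixed
once: 3 h recordings at 100 Hz; mean NREM/REM bouts of 65/30 s (rat sleep is
fragmented on the minute scale); 10% relative airflow noise; 70/30
NREM/REM split of injected events (matching the printed per-state rates,
whose REM density far exceeds REM's share of sleep time); hypopnoea depths
uniform on 0.55–0.85 and apnoea depths on 0.91–0.98 with a 30% apnoea
fraction; event durations 2–4 s.

Sleep architecture is a semi-Markov alternation WAKE → NREM → (WAKE or
REM), REM → WAKE, with exponential dwell times. Given target fractions and
the NREM/REM dwell means, the WAKE dwell mean and the NREM→REM branching
probability are derived from the stationary-fraction constraint, so
long-run fractions converge to the targets by construction. REM entered
only from NREM is the usual rodent convention; REM ending in wakefulness
matches REM's arousal-prone termination. Every recording opens with a
scripted 120 s calm-wakefulness bout (the resting-measurement window), and
each WAKE bout is marked quiet or active (40/60), giving the bimodal
muscle tone that the quiet-wakefulness rules key on.

The airflow waveform is a raised-cosine cycle per breath — one inspiration
peak, one expiration trough, peak-minus-trough equal to the breath
amplitude, which is the minimal morphology consistent with the V~T~
definition. Injected events scale breath amplitude by (1 − depth), so
instantaneous V~E~ falls to exactly (1 − depth) × its local level; injected
event counts are deterministic (`round(rate × sleep hours)`) so that
recovery tests measure detection error rather than Poisson noise, while
sighs are Poisson (their recovery is tested against a Poisson band). A
configurable fraction of REM events is scripted to terminate in an arousal:
the event ends 6 s before the bout does, breaths are amplified 1.5× for
12 s after it (post-event hyperpnoea persisting into the awakening), and
such events are only placed before *active* WAKE bouts, because an
apnoea-triggered awakening is a startle arousal with immediate muscle tone.
EEG is unit-RMS band-limited noise scaled by state-dependent envelopes
(delta RMS 10/30/8 µV and theta 12/10/30 µV in WAKE/NREM/REM); EMG is white
noise at 30/20/8/1.5 µV RMS for active-WAKE/quiet-WAKE/NREM/REM.

What the generator does **not** emulate: airflow morphology beyond a single
peak–trough per cycle (no sniffing, grooming or movement artifacts), EEG
spindles/transients, gradual state transitions (envelopes step at bout
boundaries; only the 5 s analysis smoother softens them), thermoregulatory
drift, or any SpO₂/effort channel. Passing recovery tests therefore shows
the pipeline implements its stated rules faithfully under realistic rates,
amplitudes and noise — not that it is robust to every artifact of real
plethysmography.

## Maze scoring

Barnes-maze geometry is the standard 122 cm / 20-hole table; a visit is
entry of the tracked point into a hole's 4.5 cm radius, and exit errors are
exit-hole visits before the terminal one. Strategy rules are applied in
precedence order spatial > serial > random (the published definitions are
neither exclusive nor exhaustive, so the most specific rule wins):
spatial = first hole within ±2 of the exit and the whole path inside the
90° exit quadrant (points within a quarter-radius of the centre exempt,
as trials start there); serial = a run of ≥ 3 hole visits stepping ±1
around the ring; random = ≥ 2 open-field crossings, a crossing being entry
into the inner half-radius disc that leaves at > 90° from where it entered.
Trajectories matching nothing fall back to `random` with a `fallback`
attribute, so forced labels remain identifiable. The Y-maze two-paw entry
rule is approximated by 10 cm penetration along the arm axis with a 5 cm
exit hysteresis; novelty preference is novel/(novel+open) per metric and
the discrimination ratio is novel over all three arms. Occupancy heat maps
assign each sample its interval to the next, so cell mass sums exactly to
trial duration on any grid.

## Group statistics

R~70~ is the 15th-to-85th percentile range — the central 70% of the sample,
roughly ±1 SD for Gaussian data. Percentiles use the Hazen convention
(linear interpolation at plotting positions (i − 0.5)/n), the only common
convention under which `r70(1:100)` is exactly 70; it is recorded in every
comparison's metadata so values are reproducible elsewhere. The test
family is gated by a Shapiro–Wilk test on the *control* group (where the
null phenotype lives): Gaussian controls give an unpaired Student t-test
with mean ± SD summaries, otherwise Kruskal–Wallis with median + R~70~.
A strict mode gates on both groups. Repeated-measures ANOVA families used
for longitudinal designs carry no bespoke computation and are left to
standard routines.

## Problem sizes and numerical conventions

Recovery properties are exercised on 3 h recordings at 100 Hz (about 19,000
breaths and 2,160 epochs each) across 20 seeds for the lesioned arm — the
full study operating point — with shorter 30–60 min recordings used where
only mechanics are under test. Epochs are half-open `[5i, 5(i+1))`,
0-based; all timestamps are seconds from recording start; trailing partial
epochs are dropped. Ties in peak detection resolve to the earliest sample.
EDF output is 16-bit with 1 s records, implemented minimally in-package;
round-trips are exact to one quantisation step. On these sizes a full
simulate-plus-analyse cycle takes a few seconds on one core.

Known limitations: staging systematically under-reports REM by its
bout-initial epochs (a 30 s REM bout loses roughly its first epoch to the
smoothing carry-over), so detected REM fractions sit ~1–2 percentage
points below scripted values — within the tolerance the recovery tests
assert, but visible; very shallow hypopnoeas (depth just above 0.5) are
intrinsically near-threshold at 10% noise and dominate the few misses;
and the WAKE-rule quantile calibrated to the control architecture slightly
under-labels WAKE on the lesioned arm (which has more wakefulness),
inflating DOUBT rather than corrupting sleep denominators.
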