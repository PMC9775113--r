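---
title: "Detecting and characterizing nanopore translocation events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterizing nanopore translocation events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanopulse)
```

## The signal model

A nanopore sensor records the ionic current through a single nanoscale
aperture under a bias voltage. Each molecule transiting the pore transiently
blocks part of the current, producing a downward pulse on an otherwise
stable open-pore baseline. Within a short analysis window the recorded
current decomposes as

$$ I(t) \;=\; I_0(t) \;+\; \sum_{k} I_{\mathrm{event},k}(t) \;+\; I_n(t), $$

where $I_0$ is the open-pore baseline (slowly drifting), the
$I_{\mathrm{event},k}$ are the molecular pulses, and $I_n$ is noise. The
package's job is to invert this decomposition: estimate $I_0$ and the noise
scale $\sigma$ locally, delimit each pulse, and summarize it by four
features — dwell time $\Delta t$, mean blockade amplitude $\Delta I$, peak
deficit, and the event charge deficit
$\mathrm{ECD} = \int \Delta I(t)\,dt$ (reported in fC; 1 pA·ms = 1 fC).
The ECD is the physically interesting one: a molecule that translocates
folded shows roughly twice the amplitude for half the dwell, so its ECD is
unchanged, whereas a molecule trapped at the pore mouth accumulates a far
larger ECD. The ECD distribution therefore discriminates free translocation
(one peak) from trapping (extra peaks).

All indices in the package are 0-based and all spans half-open `[s, e)`, so
$\Delta t = (e - s)/f_s$ exactly and spans concatenate without off-by-one
corrections. The canonical units are pA for current, Hz for rates, ms for
dwell and fC for charge.

## Moving-window baseline with iterative event decoupling

The trace is split into contiguous windows of `window_ms` (default 50 ms), a
horizon over which the baseline is effectively constant; a trailing
remainder of up to half a window is absorbed into the last window. Per
window the package iterates:

1. estimate $I_0$ as the mean and $\sigma$ as $1.4826 \cdot \mathrm{MAD}$
   of the unmasked samples (the robust scale resists event samples that
   escaped masking far better than the SD);
2. set the double thresholds $u_0 = I_0 - k_0\sigma$ (trigger, default
   $k_0 = 5$) and $u_1 = I_0 - k_1\sigma$ (boundary, default $k_1 = 2$),
   mirrored above the baseline for current-enhancing polarities;
3. scan for candidates, track their boundaries back toward the baseline;
4. mask the detected event spans *and* every sample farther than
   $k_1\sigma$ from the current baseline (a symmetric clip), and repeat
   until the baseline moves by less than the tolerance (0.2 pA by default)
   or `max_baseline_iters` is reached.

The symmetric clip in step 4 is what makes the decoupling converge for long,
comparatively shallow blockades: a trapped molecule can occupy a third of a
window while sitting only ~5 noise SDs below the baseline, which inflates
the first-pass MAD enough that the $k_0$ trigger never fires; masking on
threshold crossings rather than only on completed detections removes that
mass progressively. Because clipping at $\pm k_1\hat\sigma$ truncates the
noise distribution, the MAD of the kept samples underestimates $\sigma$ by a
known factor; the truncated-normal consistency correction (≈1.055 at
$k_1=2$) is applied from the second iteration so that the false-trigger rate
of the $k_0$ threshold is preserved. The clip presumes the clipped fraction
is a minority; if it would remove more than half the window (as in
noise-free data, where any drift exceeds $k_1\sigma$), it is skipped and
only detected events are masked. With Gaussian noise and the default
$k_0 = 5$, a trigger requires a $5\sigma$ excursion
($P \approx 3\times10^{-7}$ per sample), keeping false events well below one
per $10^6$ samples.

A window more than 90% masked has no stable baseline and is reported as an
error rather than silently producing thresholds from event samples.

## Candidate detection, track-back, and merging

A candidate is a maximal run of samples beyond the boundary threshold $u_1$
containing at least one sample beyond the trigger $u_0$ — the hysteresis
pair rejects noise dips that reach $u_1$ but never $u_0$. Two candidates
separated by a single boundary-crossing sample share that crossing and are
one event. The raw pair $(S_1, E_1)$ then gets a track-back: $S_2$ walks
left from $S_1$ while samples stay on the event side of $I_0$, $E_2$ walks
right symmetrically. In noise the walk terminates within a sample or two
(each baseline sample sits above $I_0$ with probability one half), and on
noise-free data the low-pass filter's overshoot stops it at the edge, so the
extension cap only needs to bound pathological widening; it defaults to ten
filter rise times. A much tighter cap (on the order of the rise time
itself) demonstrably fragments shallow events whose interior hovers between
the two thresholds: the walk is cut short while the signal is still
continuously below $I_0$, and one molecule surfaces as several short
candidates.

Candidates flagged open at a window edge are concatenated with their
continuation in the next window, and tracked spans that meet or come within
two rise times of each other (the minimum separation at which the filtered
current can return to baseline and leave it again) are coalesced. Events
still open at the first or last edge of the trace are discarded — a
truncated event has no defined dwell or ECD.

## Boundary correction

Thresholds bias boundaries inward (the edge samples between $u_1$ and the
baseline belong to the pulse) and the anti-aliasing filter delays the
return to the open state. Two corrections refine the tracked pair:

* **Second-difference refinement.** The trace is smoothed by a zero-phase
  spectral low-pass with a raised-cosine roll-off from `fc_smooth` to
  `1.2 * fc_smooth` (DC gain exactly 1; the taper avoids the Gibbs ringing a
  brick-wall cutoff would inject right next to pulse edges — the package's
  realization of a Fourier-series fit, which acts as a low-pass filter).
  $S_3$ and $E_3$ are the extrema of the discrete second difference
  $d_2[i] = x[i+1] - 2x[i] + x[i-1]$ of the smoothed signal within
  `edge_search_halfwidth_samples` of $S_2$/$E_2$ — the maximum-curvature
  corners of the filtered edge. Ties break earliest for the start and latest
  for the end, biasing toward wider events and so conserving charge. The
  second difference is taken on the smoothed signal because the raw $d_2$ at
  100 kHz is noise-dominated.
* **Rise-time end correction.** The hardware low-pass (cutoff `fc_hw`) has a
  10–90% rise time $\tau_r = 0.35/f_c$; for a symmetric (zero/linear-phase)
  filter the 50% point of a step response marks the true edge time. $E_4$ is
  the first crossing of the half-recovery level $I_0 - \Delta I/2$ within
  $\pm\tau_r$ of $E_3$ (at 100 kHz and 10 kHz this is a ±4-sample search);
  without a crossing, $E_4 = E_3$. The half-crossing rule was chosen over a
  fixed $\pm\tau_r$ shift because it is the standard unbiased edge estimator
  for symmetric filters and needs no assumption about which side of the edge
  the extremum search landed on. Both $E_3$ and $E_4$ are retained in the
  event provenance so either convention can be recovered downstream.

Features are computed on the **raw** samples within $(S_3, E_4)$, using the
owning window's $I_0$: smoothing redistributes charge, so boundaries may come
from the smoothed signal but integration must conserve the raw charge. The
ECD is the trapezoid rule over the samples of the half-open span, which
pins the consistency bound
$|\mathrm{ECD} - \Delta I \cdot \Delta t| \le \mathrm{peak}\cdot(1000/f_s)$
asserted for every event. $\Delta I$ (the headline amplitude) is the mean
deficit; the peak is exported separately. Events shorter than
`min_duration_samples` or touching the trace edges are dropped.

## ECD statistics

`fit_ecd_mixture()` fits univariate unequal-variance Gaussian mixtures for
$K = 1..k_{\max}$ and selects $K$ by
$\mathrm{BIC} = -2\log L + (3K-1)\ln n$ (computed by the package from the
model log-likelihood so the selection rule is explicit). Component fits use
model-based EM with deterministic hierarchical initialization (mclust), so
no random restarts are needed and results are reproducible; a $K$ that fails
to converge is excluded with a warning. BIC over Gaussian mixtures is the
standard consistent rule for counting modes in this family; one component
indicates a single freely translocating population, more components flag
trapping. `gate_events()` sorts events into rectangular dwell–amplitude
gates, and `match_to_truth()` greedily pairs detections with simulator
ground truth by start-time proximity (default tolerance 0.5 ms — simpler
than interval overlap and adequate for non-overlapping simulated events;
precision over an empty detection set is defined as 1 so the harness is
total).

## What the simulator emulates — and what it does not

`synthesize_trace()` builds baseline (constant plus a sinusoidal drift whose
period is much longer than a window, to exercise the per-window tracking)
minus rendered pulses, passes the pulse component through a zero-phase
4th-order Butterworth low-pass at `fc_hw` (the baseline lies fully in the
passband), and adds white Gaussian noise afterwards so that `sigma_pA` is
the observed trace SD. Pulse shapes: flat rectangles (linear molecules), a
two-level template at twice then once the nominal depth (folded molecules),
and long pulses with a ±20% whole-period sinusoidal fluctuation (trapped
molecules; the fluctuation integrates to zero so the analytic ECD is
unchanged). In the `linear_plus_folded` preset the folded nominal depth is
$\tfrac{4}{3}$ of the linear one at half the dwell, which makes the folded
*mean* deficit exactly twice the linear one and the true ECDs of the two
populations exactly equal — the construction behind the
conformation-invariance check.

Deliberate idealizations, and what they imply about the tests:

* Noise is white and added post-filter; real recordings have colored (1/f
  and dielectric) components. The detector only consumes a per-window
  $\sigma$, but passing tests say nothing about noise whose in-band
  correlation time rivals the dwell.
* The hardware filter is zero-phase so ground-truth boundaries stay aligned
  with the filtered edge midpoints; a causal amplifier chain would shift
  every edge by its group delay (a constant offset the corrections would
  absorb into both boundaries). A Butterworth was used; its few-percent step
  overshoot means the instantaneous minimum of a noise-free pulse slightly
  exceeds the nominal depth even though the plateau matches it.
* Dwell times are log-normal. The spread of the free and folded populations
  (`sigma_log = 0.1`) was set so that the product
  amplitude × dwell — the ECD — has negligible skewness: the regime being
  emulated is a homogeneous sample whose free-translocation ECD histogram is
  single-peaked and approximately normal, and with a log-normal dwell the
  product's skewness grows quickly with `sigma_log` (at 0.25 the skewness is
  near 1 and a two-component mixture genuinely fits better even on the true
  ECDs). Trapped dwells use a wider `sigma_log = 0.3` at a 15 ms median,
  at least ten times the free mean dwell.
* Amplitudes are phenomenological (no pore-conductance physics) and are
  truncated below at half their mean, so a few percent of simulated events
  sit only ~2.5–4 noise SDs deep — deliberately at the detection limit.

Problem sizes used throughout the tests: 100-event traces of 2–5 s at
100 kHz (0.2–0.5 M samples), a 10 s noise-only trace (1 M samples), and
twenty seed replicates for the peak-counting comparison; these keep the full
suite in the low minutes on one core while leaving every per-trace quantity
at the scale a real recording session would produce.

## Numerical choices and edge cases

* $\sigma$ is floored at $10^{-6}$ pA so thresholds remain ordered on
  constant data; a constant window converges in a single iteration via an
  exact fixed-point check on the mask.
* The baseline tolerance is stored as 0 in the configuration, meaning
  "0.2 pA"; any positive value overrides it.
* Uniform time axes are required only to 1% relative step tolerance on
  two-column input; gap-free recording is assumed.
* `refine_edges()` falls back to $(S_2, E_2)$ if the refined pair collapses,
  and never moves an edge by more than the search half-width (asserted per
  event).
* The mixture's BIC uses $p = 3K - 1$ free parameters; weights are reported
  in increasing order of component mean.

## Known limitations

* Events with amplitude near $u_1$ (≲3 noise SDs) have boundaries dominated
  by noise; they may fragment or their tails may be clipped. The package
  mitigates but cannot eliminate this — sub-threshold analysis needs a
  different detector class (e.g. CUSUM-style level fitting, which is out of
  scope here, as is any multi-level sub-event segmentation).
* A trapped event longer than half a window can straddle two windows with
  high occupancy in each; if neither window can decouple it, the event is
  lost. Widening `window_ms` helps at the cost of baseline-tracking
  resolution.
* BIC peak counting at ~100 events occasionally prefers two components for
  a genuinely single population (heavy sample tails); the seed-replicated
  property quantifies, rather than hides, this rate.
* Only current-decrease (blockade) and current-increase (enhancement)
  polarities are supported, as a sign flag; bipolar or multi-level events
  are not modeled.
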