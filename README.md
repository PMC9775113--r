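# nanopulse

Event detection and feature extraction for nanopore (resistive-pulse)
ionic-current recordings.

A molecule transiting a nanopore transiently blocks the open-pore current,
leaving a downward pulse buried in noise on a drifting baseline. `nanopulse`
turns a raw current trace into a table of molecular events for people who
analyze single-molecule nanopore experiments: it tracks the local baseline in
a moving window with iterative event decoupling, detects pulses with a
double-threshold (hysteresis) trigger plus track-back, refines each event's
edges on the smoothed signal (second-difference extrema, then a rise-time
end correction), and reports per event the dwell time, mean and peak
blockade amplitude, and the event charge deficit.

## The method in brief

Within an analysis window the current decomposes as
`I(t) = I0(t) + Σ I_event,k(t) + I_n(t)`. Per window the package estimates
the baseline `I0` (mean) and noise scale `σ` (1.4826·MAD) on event-masked
samples, sets the threshold pair

    u0 = I0 − k0·σ   (trigger, default k0 = 5)
    u1 = I0 − k1·σ   (boundary, default k1 = 2)

and iterates estimation and detection until the baseline decouples from the
events. Boundaries are staged `S1/E1 → S2/E2 → S3/E3 → E4` (threshold
crossings → track-back to baseline → second-difference curvature extrema →
half-recovery rise-time crossing), and features are integrated on the raw
samples within `(S3, E4)`. The headline feature is the event charge deficit

    ECD = ∫ ΔI(t) dt      (1 pA·ms = 1 fC),

which is invariant to molecular conformation — a folded molecule doubles the
amplitude for half the dwell — so its distribution separates free
translocation (one Gaussian peak) from trapping at the pore mouth (extra
peaks). `fit_ecd_mixture()` counts those peaks with BIC-selected 1-D
Gaussian mixtures.

A synthetic-trace generator with ground truth (`sim_scenario()`,
`scenario_preset()`, `synthesize_trace()`) and a truth-matching harness
(`match_to_truth()`) are first-class parts of the package.

## Worked example

```r
library(nanopulse)

sc  <- scenario_preset("free_linear", seed = 1)   # 100 events, 2 s @ 100 kHz
sim <- synthesize_trace(sc)
ev  <- detect_events(sim$trace)
ev
#> <pore_events> 100 event(s) from 104 candidate(s) in 40 window(s)
#>   baseline iterations: mean 4.17; median window sigma 20 pA
#> <event_table> 100 events from 200000 samples @ 100000 Hz
#>   dwell_ms: median 1.01; amp_mean_pA: median 97.33; ecd_fC: median 96.69

match_to_truth(ev$table, sim$truth, tol_ms = 0.5)
#> <truth_match> TP 100, FP 0, FN 0 | recall 1.000, precision 1.000
#>   median |dwell err| 0.036 ms, median |ECD rel err| 0.028

fit_ecd_mixture(as.data.frame(ev)$ecd_fC, k_max = 4, seed = 1)
#> <ecd_mixture> 100 value(s), chosen K = 1 (BIC)
#>   component 1: weight 1.000, mean 96.98 fC, sd 14.82 fC
```

All 100 simulated events are recovered with no false positives; dwell is
right to a few hundredths of a millisecond, the charge deficit to ~3%, and
the ECD distribution is, as expected for a single freely translocating
population, best described by one Gaussian component. On the
`with_trapping` preset the same mixture fit selects two or more components.

`plot(ev)` draws the dwell–amplitude scatter, `plot(ev, "ecd")` the ECD
histogram, and `summary(ev)` prints feature quartiles and window
diagnostics.

## Command line

A thin CLI wraps the same functions (installed at `exec/nanopulse`, or call
`nanopulse::cli_main()`):

```sh
nanopulse simulate --preset free_linear --seed 1 --out trace.csv --truth truth.csv
nanopulse detect trace.csv --out events.csv --log detect.log
nanopulse stats events.csv --ecd-mixture --kmax 4 --seed 0 --out stats.json
nanopulse evaluate events.csv truth.csv --tol-ms 0.5
```

Input formats: two-column CSV/TSV (`time_s, current_pA`) or little-endian
float32 binary with a JSON sidecar (`fs`, `units`, `polarity`).

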