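# hpdlfp

Quantification of epileptiform activity in intracranial LFP recordings from
rodent epilepsy models, plus a seeded simulator that makes the whole
pipeline testable without animal data.

## The problem

In the intrahippocampal kainate model of temporal-lobe epilepsy, chronic
depth-electrode recordings from the injected hippocampus show three kinds of
epileptiform activity: isolated sharp **spikes**, **spike trains**, and
**hippocampal paroxysmal discharges (HPDs)** — the standard readout for
drug-resistant focal seizures. Drug studies in this model compare event
rates and spectral power in a fixed post-injection window against the
pre-injection baseline of the same session. `hpdlfp` implements that
analysis chain as a reusable, tested R package:

* **Spike detection** by the mode-based rule used in this literature: the
  recording (bandpassed 0.5–70 Hz, 2nd-order Butterworth, zero-phase) is
  cut into 1 s segments; the mode *m* of the per-segment extrema sets the
  threshold at 2*m* in the spike-polarity direction, with a 70 ms
  refractory period.
* **Event classification**: spikes chained at gaps ≤ 1/1.33 Hz form
  spike trains (≥ 3 spikes, 1–10 s, ≥ 1.33 Hz) and HPDs (≥ 10 s).
  Alternative literature definitions — SLEs (≥ 3 s), ≥ 5 s/≥ 5 Hz, and
  ≥ 20 s/10–20 Hz — are selectable profiles.
* **Generalized-seizure flagging**: high RMS simultaneously on all channels
  followed by post-ictal suppression; seizure-positive sessions are
  excluded from event-rate (but not spectral) comparisons.
* **Spectral summaries**: 10 s sliding Hann-window PSD (5 s step), band
  powers over delta/theta/alpha/beta/gamma (1–4, 4–8, 8–13, 13–30,
  30–80 Hz, half-open edges), log10 transform, coastline (line length),
  and normalization to the pretreatment spectral maximum.
* **Treatment analysis**: 59 min pre (−64 to −5 min) vs post (+35 to
  +94 min) windows, high/low-HPD group assignment at the > 50 s/h cutoff,
  paired pre/post tables with Šídák-adjusted thresholds, and a Pearson
  chi-square on generalized-seizure occurrence across treatments.
* **Synthetic LFP**: 1/f background + theta oscillation, Poisson event
  schedules with exact ground-truth spike times, biphasic spike templates,
  generalized seizures with suppression epochs, and piecewise rate
  multipliers emulating drug effects.

See `vignettes/hpdlfp-methods.Rmd` for the model, parameter rationale and
limitations.

## Worked example

Simulate 20 minutes of a chronically epileptic animal, detect events, and
summarize:

```r
library(hpdlfp)

truth <- sample_schedule(event_schedule(), duration = 1200, seed = 42)
rec <- synthesize_recording(truth, background_params(), n_channels = 3, seed = 43)
print(rec)
#> <lfp_recording> 3 channel(s), 1200 s at 500 Hz, start 0 s
#>   hippocampus_ipsi   n=600000  range [-181.6, 94.1] uV
#>   hippocampus_contra n=600000  range [-94.3, 84.2] uV
#>   cortex             n=600000  range [-102.7, 94.2] uV

res <- detect_events(rec)
res$baseline
#> polarity negative, mode -32 uV, threshold -64 uV
table(res$events$kind)      # vs ground truth: 4 hpd, 36 spike_train
#>         hpd spike_train
#>           4          36
summarize_rates(res$events, c(0, 1200))
#>   n_spike_trains dur_spike_trains n_hpds dur_hpds
#>              108          346.134     12  160.182   (per hour)
```

The detected mode (−32 uV) is the amplitude of a typical per-second minimum
of the background; every deflection beyond twice that is a spike. All 40
scheduled trains/HPDs are recovered; rates are scaled to per-hour (12 HPDs/h
totalling 160 s/h — a "high-HPD" animal, > 50 s/h). Spectral summary of the
same channel:

```r
bs <- band_power_summary(bandpass(rec_channel(rec), 500), 500)
bs$bands
#>    band      power  log_power
#> 1 delta 15.0226907  1.1767477
#> 2 theta 18.7745987  1.2735707
#> 3 alpha  4.8269859  0.6836760
#> 4  beta  3.2522092  0.5121785
#> 5 gamma  0.6599222 -0.1805072
```

Power (uV²/Hz) peaks in theta, where the simulated 7 Hz background
oscillation lives; `log_power` is the log10 value used for pre/post
comparisons. A full treatment session — injection at 64 min, suppressant
effect, exclusion rule, paired summaries — runs through
`simulate_session()`, `evaluate_session()`, `paired_prepost_summary()` and
`occurrence_chisq()`; the `lfp_cli()` entry point exposes `convert`,
`simulate`, `detect`, `spectra` and `treatment-report` subcommands for file
workflows (CSV/EDF/RDS recordings, TSV annotations, YAML parameters).

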