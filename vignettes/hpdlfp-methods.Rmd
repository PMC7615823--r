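---
title: "Methods: mode-based LFP event detection, spectral summaries and treatment analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mode-based LFP event detection, spectral summaries and treatment analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpdlfp)
```

## Scope and model of the data

`hpdlfp` quantifies epileptiform activity in chronic intracranial LFP
recordings from rodent epilepsy models of the intrahippocampal-kainate type:
depth electrodes in both hippocampi plus a cortical screw electrode, sampled
at 500–512 Hz, amplitudes on the order of tens to hundreds of microvolts.
The unit of analysis is a session: a multi-channel recording, an injection
time, and a 59 min pre-treatment window (64–5 min before injection) compared
against a 59 min post-treatment window (35–94 min after injection, the time
of peak drug effect after i.p. administration; the first 35 min are skipped
to avoid solvent and handling effects).

Three event classes are quantified on the ipsilateral hippocampal channel:

* **epileptiform spikes** — sharp transients whose amplitude exceeds twice
  the mode of the per-second signal extrema, at least 70 ms apart;
* **spike trains** — at least 3 spikes lasting 1–10 s at a mean rate of at
  least 1.33 Hz;
* **hippocampal paroxysmal discharges (HPDs)** — the same trains with a
  duration of at least 10 s; the standard readout for drug-resistant focal
  seizures in this model.

**Generalized seizures** — high-amplitude high-frequency discharges on all
channels followed by post-ictal suppression — are flagged on the whole
montage. A session with a generalized seizure in the post window is excluded
from event-rate comparisons (the post-ictal depression corrupts the counts)
but never from spectral comparisons.

## The detection chain and its numerical choices

1. **Bandpass.** Second-order Butterworth, 0.5–70 Hz, applied forward and
   backward (zero phase) so spike peak times are not lag-shifted. The
   zero-phase double pass squares the magnitude response; the contract
   tested is response-based (passband within 5%, 120 Hz below 15%, DC
   removed). Edges are padded by 1 s of odd reflection. With no
   signal-processing dependency available, the bilinear-transform design is
   implemented in the package and was cross-checked against an independent
   reference implementation during development.

2. **Mode baseline.** The filtered window is cut into non-overlapping 1 s
   segments; per-segment minima and maxima are histogrammed with 1 uV bins
   *centered* on integer multiples of the bin width. Centered bins make the
   degenerate case exact: minima all equal to −10 uV give mode −10 and
   threshold −20, as the definition demands. Ties between equally populated
   bins resolve toward the larger magnitude (the more conservative, higher
   threshold). The mode is re-estimated per analysis window (pre and post
   each get their own baseline) to guard against slow drift; a shared
   baseline is available as a flag.

3. **Polarity.** The side (minima vs maxima) with the larger-magnitude mode
   wins. On near-symmetric background the two modes differ only by histogram
   noise (1–2 bins), so modes within 20% of each other are treated as
   indistinguishable and the decision falls to the 99th-percentile tails of
   the two extremum distributions — spikes inflate the tail on their side by
   a factor of ~3 while leaving the mode untouched. This refinement is the
   package's own: the bare larger-|mode| rule flips polarity on about half
   of all simulated sessions, which is an estimator artifact, not a property
   of the data. A manual per-animal override (`polarity = "negative"` /
   `"positive"`) matches how polarity is set in practice.

4. **Spikes.** Local extrema in the polarity direction crossing the 2x-mode
   threshold, accepted greedily left to right with a 70 ms refractory
   period; a candidate exactly 70 ms after the last accepted spike survives.

5. **Grouping.** Spikes are chained while the inter-spike gap is at most
   `1/1.33 Hz = 0.752 s` — any gap consistent with the minimum train rate
   keeps the chain alive — and each *maximal* chain is classified by spike
   count, duration (last minus first spike) and mean rate. Mean rate
   defaults to `(n − 1)/duration` (the reciprocal mean inter-spike
   interval); the `n/duration` reading is exposed as
   `rate_definition = "count"` since the original definition does not say
   which is meant. Chains shorter than 1 s are single spikes, not trains.
   `group_events` is verified exactly against a brute-force enumerator of
   all contiguous spike subsequences on hundreds of random spike sets.

6. **Alternative definitions.** `definition_profile` switches the taxonomy:
   `"sle_klein"` (seizure-like events, >= 3 s), `"five_five"` (HPDs >= 5 s
   and >= 5 Hz) and `"twele"` (HPDs >= 20 s at 10–20 Hz). Because intra-train
   spike rates in this model peak at 3–4 Hz, the stricter 5 Hz/10–20 Hz
   profiles classify no HPDs on the same spike sequences — a property the
   acceptance suite asserts end to end.

7. **Generalized seizures.** The visual criterion is automated as: windowed
   RMS (1 s windows) above 4x the per-channel median RMS on *all* channels
   for at least 10 s, followed by 30 s of ipsilateral RMS below 0.5x
   baseline. These defaults were calibrated on the simulator only; they
   automate a criterion that was applied by eye in the source analyses, and
   nothing here validates them against human scoring of real recordings.

## Spectral analysis

Power spectral density uses a 10 s Hann window sliding in 5 s steps (50%
overlap), demeaned per window, one-sided, normalized by the taper power so
that the integrated PSD of a window equals its variance (Parseval within
5% is an asserted contract). Frequency resolution is 0.1 Hz. Band powers
are per-window mean PSD over bins with `low <= f < high` — half-open edges
make delta/theta/alpha/beta/gamma (1–4, 4–8, 8–13, 13–30, 30–80 Hz) a true
partition — averaged over the window set and log10-transformed afterwards
(band powers are approximately log-normal across sessions; log base is
configurable). The coastline (line length) is the exact total variation of
the trace per 10 s window, averaged over the interval at the same
granularity as the band powers. Pre/post spectra can be expressed as a
percentage of the pretreatment maximum of the window-mean spectrum, the
convention used for published power-spectrum figures in this field.

The 5 s step is a reading of "power per 5 s" combined with "10 s sliding
window": 50% overlap reconciles the two; the step is exposed in
`spectral_params()` for other readings.

## The synthetic-data generator: what it emulates and what it does not

The generator exists to give the pipeline inputs with known ground truth.

* **Background**: 1/f-shaped Gaussian noise (`noise_sd` 20 uV, exponent 1)
  plus a single 7 Hz, 10 uV sinusoid standing in for the theta rhythm.
  Total SD ~21 uV.
* **Events**: Poisson counts per kind; defaults match the pretreatment
  activity of a chronically epileptic high-HPD animal — 120 spike trains/h
  (target spans 1.5–5 s, so ~390 s/h), 12 HPDs/h (spans 10–21 s, ~185 s/h),
  60 isolated spikes/h, and one generalized seizure every ~20 h (the
  observed ceiling is ~2/day). Intra-event spike times are a renewal
  process with ±20% jittered intervals around a per-event rate drawn from
  3–4 Hz, reproducing the intra-train rate peak of this model. Overlaps are
  resolved by rejection resampling (longest events placed first, 1000
  retries, then a scheduling error) with a 2 s spacing margin so distinct
  events can never chain together.
* **Spikes** are biphasic difference-of-exponentials transients, < 50 ms
  wide, with the dominant lobe at the scheduled polarity and amplitude
  `spike_amp` (default 3) times the empirical mode of the per-second
  background extrema — i.e. 1.5x the detection threshold, and about 4.3x
  the background SD. `spike_amp` is expressed relative to the mode because
  every threshold in the detection chain is; values below 2.5 are rejected
  as undetectable by construction.
* **Generalized seizures** are 15–40 Hz high-amplitude bursts on all
  channels followed by a 30 s suppression epoch in which the background is
  scaled to 0.15x. The 30 s suppression length is a fixed choice; real
  post-ictal depression length varies and is not modeled.
* **Treatment effects** are piecewise-constant rate multipliers active from
  35 to 94 min after injection. A suppressant is multipliers 0 on trains
  and HPDs; a proconvulsant multiplies the generalized-seizure rate.

Not emulated: electrode artifacts, state-dependent (sleep/wake, estrous)
rate modulation, spike-waveform variability across animals, slow amplitude
drift, and any biophysics. A green recovery test therefore establishes that
the detection chain inverts *this* generative model at realistic SNR — it
does not establish detector performance on real recordings, where waveform
and background assumptions are broken in ways the simulator does not
represent.

## Treatment analysis

`evaluate_session` runs detection and spectral summaries per window and
applies the exclusion rule. Group assignment uses the strict `> 50 s/h`
HPD-duration cutoff at the reference session. Generalized-seizure
occurrence across treatments is tested with a Pearson chi-square on the
2 x k (treatment x seizure-presence) table without continuity correction —
on the published occurrence counts in this model (3/7 and 1/7 seizing after
the two lamotrigine doses, 0/7 elsewhere) this gives p = 0.0160 with
df = 7, reproduced to the printed precision by the acceptance suite. The
full repeated-measures mixed-effects machinery applied to the real cohort
is deliberately out of scope; `paired_prepost_summary` emits the tidy
per-treatment paired table (n, mean ± SD pre/post, mean difference, paired
t, Sidak-adjusted alpha `1 − 0.95^(1/m)`) ready for export into any
statistics package. Treatments with fewer than 2 usable sessions are
flagged non-estimable rather than erroring, mirroring the uneven group
sizes the exclusion rule produces.

## Tolerances and degenerate inputs

* Recording validation requires finite amplitudes, equal channel lengths
  and a sampling rate of at least 160 samples/s (twice the 80 Hz band
  edge).
* Windows are half-open `[start, end)` everywhere; sample `i` covers
  `[i/rate, (i+1)/rate)`, so adjacent slices partition a recording without
  duplicated samples.
* The mode needs at least 10 segments; shorter traces raise a range error.
* Parseval is asserted at 5% (Hann taper compensation); white-noise band
  flatness at ~10%; EDF round trips at one 16-bit quantization step.
* Empty spike lists, empty truths, all-zero schedules and zero-power
  spectra are all valid inputs with defined (empty or zero) outputs; a
  zero pretreatment maximum makes normalization a range error rather than
  an Inf.

## Known limitations

* The EDF writer targets the plain 16-bit EDF profile (no EDF+
  annotations); start time and exact duration ride in a header text field.
* Auto-polarity can still be arbitrary on recordings with genuinely no
  epileptiform activity; it is harmless there but the override flag is the
  right tool for real cohorts.
* The generalized-seizure detector is tuned to the simulator's seizure
  morphology; thresholds will need re-calibration against scored real data
  before any substantive use.
* Acceptance-scale simulations are scaled to desk hardware (e.g. 5
  end-to-end suppressant sessions rather than a 7-animal cohort); the
  asserted properties are per-session and unaffected by the count.
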