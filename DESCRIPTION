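Package: hpdlfp
Title: Detection and Treatment Analysis of Hippocampal Paroxysmal Discharges in LFP Recordings
Version: 0.1.0
Authors@R:
    person("LFP", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying epileptiform activity in intracranial
    local field potential (LFP) recordings from rodent epilepsy models.
    Implements mode-based epileptiform spike detection with a 2x-mode
    amplitude threshold, grouping of spikes into spike trains and
    hippocampal paroxysmal discharges (HPDs) with configurable literature
    definitions, automated flagging of generalized seizures, sliding-window
    Hanning spectral band-power and coastline analysis, and paired
    pre-/post-treatment comparison of drug effects including a chi-square
    test on generalized-seizure occurrence. A seeded multi-channel LFP
    simulator with ground-truth event annotations allows the whole pipeline
    to be validated without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
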