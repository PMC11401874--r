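Package: sergain
Title: Spiking Network Model and Electrophysiology Analysis of 5-HT2A Gain Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based leaky integrate-and-fire model of an excitatory/
    inhibitory cortical network under 5-HT2A (Gq) neuromodulation, together with
    the spike-train and LFP analysis stack used to characterise it: opto-index,
    divisive-gain regression, spontaneous and evoked normalization, band power,
    and cross-correlogram monosynaptic inference. Includes a synthetic-session
    generator with ground truth for parameter-recovery testing, and protocol
    drivers for activation-fraction sweeps and mean-driven superposition
    predictions.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    tibble
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
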