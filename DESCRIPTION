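Package: ffinet
Title: Feedforward Inhibition Circuits with Electrically Coupled Interneurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of canonical feedforward-inhibition
    microcircuits built from Izhikevich regular-spiking and fast-spiking
    neurons, with conductance-based AMPA/GABA synapses and gap-junction
    (electrical) coupling between interneurons. Provides the three canonical
    configurations (single circuit, coupled pair, and a 50-unit network), a
    fixed-step clock-driven simulation engine, synthetic stimulus generators
    (timed DC pulses and Gaussian-jittered input times), subthreshold PSP
    integration metrics, smoothed spike-time-density statistics, and
    spike-timing mutual information and transmission efficiency between the
    source and target populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
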