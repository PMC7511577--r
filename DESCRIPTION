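Package: ihcfc
Title: Theta-Gamma Cross-Frequency Coupling in Compartmental Pyramidal
    Neuron Models with Ih Conductance Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reduced multicompartment conductance-based models of a large
    pyramidal neuron with three spatial configurations of the
    hyperpolarization-activated mixed cation (Ih, HCN) conductance:
    an exponential somato-apical gradient, a uniform distribution, and no
    Ih.  Provides a cable-equation simulator for dual sinusoidal current
    injection protocols (4 Hz theta modulation plus 40 Hz low-gamma
    injection), a phase-amplitude cross-frequency coupling analysis
    pipeline (Tort modulation index, height ratio, amplitude ratio,
    theta phase of gamma-envelope extrema), synthetic coupled-signal
    generators with controlled ground-truth coupling, and experiment
    drivers that map coupling strength and phase along the soma-apical
    dendrite axis and tuft.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
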