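Package: thetagamma
Title: Theta-Gamma Cross-Frequency Directionality in Feedforward and Feedback Inhibitory Motifs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based spiking-network simulations of theta-modulated
    interneuron-network-gamma (ING) and pyramidal-interneuron-network-gamma
    (PING) motifs, together with the analysis stack used to characterise their
    theta-gamma interactions: mean-vector-length cross-frequency coupling (CFC)
    comodulograms with phase-split surrogates and cluster-based significance,
    cross-frequency directionality (CFD) via the phase slope index, kernel
    conversion of spike trains to rate series, and k-nearest-neighbour mutual
    information protocols for signal fidelity and consistency. Networks combine
    five-compartment pyramidal cells and point basket cells with double
    exponential AMPA/NMDA/GABA-A synapses, a theta-modulated spike-packet
    drive, Poisson background noise, and an optional parallel input pathway.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
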