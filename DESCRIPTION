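Package: bitsnn
Title: Event-Driven Spiking Networks with 1-Bit Stochastic STDP
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Event-driven simulation of spiking neural networks whose synapses
    are restricted to 1-bit precision and trained by stochastic order-based
    spike-timing-dependent plasticity (STDP). Provides linear-leak
    integrate-and-fire neurons with a bit-shift (piece-wise linear) leak
    approximation, the stabilization mechanisms that make binary stochastic
    STDP learn (weight normalization, homeostatic threshold adaptation,
    threshold saturation, dual learning/inference thresholds, winner-take-all
    lateral inhibition, pre-event list flushing), two spiking classifiers
    (a teacher-driven STDP classifier and a histogram/softmax classifier with
    conversion to spiking neurons), address-event representation (AER) stream
    utilities, synthetic stimulus and Poisson rate-coding generators, and a
    behavioral clock-cycle cost model of a hardware STDP unit including a
    16-bit LFSR pseudo-random generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, nnet, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'aer.R'
    'bitsnn-package.R'
    'neuron.R'
    'stdp-binary.R'
    'network.R'
    'classifiers.R'
    'stimuli.R'
    'experiments.R'
    'hw-model.R'
    'idx.R'
    'stdp-kernels.R'
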