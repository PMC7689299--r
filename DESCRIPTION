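Package: ataxiaChannels
Title: Cross-Model Ion Channel Dysregulation and Purkinje Neuron
    Physiology in Spinocerebellar Ataxia
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for regional Purkinje-neuron vulnerability
    studies in spinocerebellar ataxia mouse models. Computes cross-model
    ion-channel differential-expression overlaps with UpSet (exclusive
    intersection) semantics and a permutation null backed by an exact
    enumeration oracle; classifies channel genes by their dependence on
    the ATXN1-Cic repressor complex from three differential-expression
    contrasts; extracts electrophysiological features from voltage- and
    current-clamp recordings (two-compartment equivalent-circuit
    capacitance from double-exponential transient fits, area-method
    capacitance, interspike-interval coefficient of variation and firing
    classification, afterhyperpolarization measurement, recording quality
    control, liquid junction potential correction); and performs molecular
    quantification (comparative-Ct and standard-curve qPCR, ChIP-qPCR
    percent input, immunofluorescence line-profile intensity scoring).
    A seeded synthetic-data generator emulates every input class with
    known ground truth so the full pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    minpack.lm,
    signal,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ComplexHeatmap
Config/testthat/edition: 3
RoxygenNote: 7.3.3
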