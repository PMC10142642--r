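Package: sortgauge
Title: Quantitative Evaluation of Continuous-Flow Particle Sorters by Flow Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates, gates and quantifies flow-cytometry readouts of
    continuous-flow microfluidic particle sorters. Provides a labeled synthetic
    event generator (bead mixtures and bead-spiked diluted blood with a
    probabilistic two-outlet sorter), a minimal FCS 3.0 / TSV event reader and
    writer, hierarchical geometric gating with pulse-processing
    singlet/doublet discrimination, counting-bead (accudrop) volume
    normalization, and the Separation Efficiency and Purity metrics used to
    benchmark size-based sorting devices, together with replicate aggregation
    and collection-ratio quality control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
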