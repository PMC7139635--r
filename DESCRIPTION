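Package: recombsim
Title: Simulation of Recombination Patterns in Doubled-Haploid, RIL and
    MAGIC Breeding Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward simulation of meiosis and breeding schemes for maize-like
    genomes, parameterized by an empirical per-chromosome crossover-count
    distribution and a window-level recombination-rate landscape. Simulates
    doubled-haploid (DH) induction at any selfing generation, recombinant
    inbred lines by single-seed descent, and 8/16/32-parent MAGIC funnels
    completed by DH induction or continuous selfing; tracks founder-labelled
    chromosome mosaics (junctions/IBD segments) and reports recombination
    events per line, fragment lengths, recombination-bin maps, and Kosambi
    linkage maps built from window-resolved genotype matrices.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
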