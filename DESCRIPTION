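Package: chromochoreo
Title: Quantifying the Choreography of Multichromosome Bacterial Cell Cycles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the cell-cycle choreography of bacteria with
    multipartite genomes, modelled on two-chromosome alphaproteobacteria.
    Locates replication origin and terminus regions from cumulative GC skew,
    searches replicons for parS-candidate palindromes, degenerate consensus
    motifs and KOPS strand bias; segments rod-shaped cells in fluorescence
    images, detects diffraction-limited foci and septal rings, measures ring
    diameters from z-stacks, and builds demographs; converts population
    one-focus fractions into locus duplication ages and times under the
    exponential age distribution of steadily growing populations; and ships a
    seeded synthetic-data generator (skewed genomes, cell populations,
    rendered images) so the whole pipeline is testable without microscopy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    Biostrings,
    EBImage,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
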