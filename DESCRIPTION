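Package: adenoforge
Title: In Silico Planning and Simulation of Adenoviral Genome Reconstruction
    by Isothermal Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans and simulates the reconstruction of large linear viral
    genomes (adenovirus-scale, ~35 kb) as circular plasmid clones via tailed-PCR
    fragmentation and isothermal (Gibson) assembly. Provides a core dsDNA
    sequence model with linear/circular topology, a restriction-enzyme model
    with explicit end chemistry (blunt, 5' and 3' overhangs, type IIS offsets),
    a primer grammar for vector-anchored and junction-overlap primers, reaction
    simulators for PCR (including inverse PCR), sticky/blunt ligation and
    overlap-directed assembly, a full multi-step reconstruction workflow
    (backbone engineering, paired-fragment intermediates, E3 replacement by a
    reporter cassette, final reassembly, rescue linearization, verification),
    and a seeded synthetic-genome generator so the entire pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
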