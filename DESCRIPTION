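Package: nucleodyn
Title: Nucleosome Stability and Dynamics from Single-Molecule FRET,
    Titrations, Gels, Tiling Arrays and Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of nucleosome stability and dynamics
    assays: all-photons burst search and corrected FRET efficiency /
    stoichiometry / time-deviation features for diffusing single-molecule
    FRET data, probability distribution analysis (PDA) with shot-noise-exact
    efficiency histograms, salt-titration sigmoid fitting with stability
    midpoint (C0.5) extraction, densitometry quantification of competitive
    nucleosome assembly and ATP-driven remodelling time courses,
    tiling-array normalization with genomic region-class summaries and
    metagene TSS profiles, and histone-DNA contact geometry on nucleosome
    coordinate files. A synthetic-data module generates every input the
    pipeline consumes, so all analyses are exercisable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    bio3d
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
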