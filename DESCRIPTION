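Package: junctura
Title: Annotation and Modeling of Nuclease-Induced Translocation Breakpoint Junctions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing breakpoint junctions of chromosomal
    translocations induced by designer nucleases (e.g. zinc-finger
    nucleases) at two cut loci. Junction amplicons are decomposed into
    deletion, microhomology and insertion components against the
    perfect-join derivative chromosome expected after 5'-overhang fill-in;
    insertion origins (templated, possibly inverted) are traced to the
    parental loci. An analytic "expected by chance" microhomology null
    model, per-genotype summary statistics, exact nonparametric tests,
    plate-based translocation-frequency estimation (with Poisson
    correction), Surveyor-nuclease indel arithmetic, and a generative
    simulator of end-joining junctions are included, so the full pipeline
    is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
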