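Package: mgcgep
Title: Multigene Concatemer Gene Expression Profiling Toolkit
Version: 0.1.0
Authors@R:
    person("MgC-GEP", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Design, simulation and analysis toolkit for gene expression
    profiling via multigene concatemers (MgC-GEP), a SAGE-style tag
    counting protocol built on multiplex chimeric primers. The package
    designs multiplex panels of chimeric primers (gene-specific 3' part
    plus a universal adaptor carrying a BamHI or HindIII site) under
    melting-temperature and amplicon-length constraints, simulates the
    amplification, restriction digestion, sticky-end concatemer ligation,
    size selection and clone sequencing steps from a ground-truth
    expression profile, deconvolves clone reads back into ordered gene
    tags, counts tag occurrences per gene, and estimates internal-control
    normalised relative expression with count-based confidence intervals,
    including a comparative-CT (delta-delta-CT) path for qPCR data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
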