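Package: riboscore
Title: Quantitative Profiling of rRNA 2'-O-Methylation and Pseudouridylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scoring of ribose 2'-O-methylation (RiboMeth-seq MethScore) and
    pseudouridylation (HydraPsiSeq NormUcount / PsiScore) stoichiometry from
    per-position read-end count profiles, with validated modification-site
    catalogs, a Poisson cleavage-library simulator for both chemistries,
    paired differential-modification testing between conditions, and
    snoRNA-guide concordance classification. All stages are composable and
    file-backed (TSV/FASTA/BEDGraph), with an end-to-end demo pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
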