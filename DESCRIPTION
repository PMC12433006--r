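Package: nanomsp
Title: Methylation-Specific PCR Biomarker Discovery from Nanopore Methylation Calls
Version: 0.1.0
Authors@R:
    person("nanomsp", "developers", email = "nanomsp@example.org", role = c("aut", "cre"))
Description: End-to-end discovery and validation of methylation-specific PCR (MSP)
    biomarkers from per-CpG nanopore 5mC methylation calls. Reads bedmethyl pileup
    files, calls tumor-vs-control differentially methylated primer regions with a
    CpG-density-aware sliding-window algorithm, performs in-silico bisulfite
    conversion and constraint-based design of bisulfite-specific primer pairs and
    hydrolysis probes, and validates candidate markers from qPCR CT tables via
    delta-CT normalization, Welch tests with Bonferroni correction, Youden-optimal
    cutpoints and AUC. Ships a synthetic-data generator emulating every input
    (reference with CpG islands, tumor/control bedmethyl files with tumor-purity
    mixing, CT tables) and a scriptable pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
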