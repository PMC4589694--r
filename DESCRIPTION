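Package: amplimine
Title: In Silico PCR Mining of GMO Detection-Method Amplicons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens nucleotide sequence collections with panels of PCR-based
    GMO detection methods (event-, construct-, element- and taxon-specific
    primer/probe assays) by in silico PCR: primer binding sites are located
    under bounded mismatch and indel tolerance, paired within a product-size
    window, and the predicted amplicons are extracted, probe-verified by local
    alignment, annotated with species and dataset provenance, and exported as
    a tab-delimited table. Non-redundant amplicon sets are built by exact
    deduplication and greedy identity/coverage clustering, and screening
    consistency summaries (methods detecting per dataset, records detected,
    amplicon-to-record ratios) are computed, including a strict perfect-match
    mode. A synthetic fixture generator plants primer and probe sites with
    controlled edit budgets so the whole pipeline can be exercised without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    optparse,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
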