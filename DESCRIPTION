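Package: codonsel
Title: Codon-Model Selection Tests and Convergent Substitution Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative-genomic selection analysis for sets of one-to-one
    orthologs on a fixed species tree. Implements a Goldman-Yang (GY94) codon
    substitution likelihood engine with one-ratio, two-ratio branch, and
    branch-site Model A fits; likelihood-ratio tests and empirical-Bayes site
    posteriors; the decision rules that call positively selected and rapidly
    evolving genes on a designated foreground lineage set; a screen for
    convergent amino-acid substitutions at conservative sites with
    conserved-domain and biochemical property-change annotation; chi-square
    gene-set enrichment; protein-guided codon back-translation; and a codon
    alignment simulator with plantable convergent substitutions for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
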