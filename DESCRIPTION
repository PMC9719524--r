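Package: sexlinkr
Title: Sex-Linked Marker Discovery and Population Structure from
    DArTseq Genotype Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies sex-linked SNP and presence-absence (SilicoDArT)
    markers from reduced-representation genotyping matrices and infers the
    sex-determining system (male XX/XY vs. female ZZ/ZW heterogamety).
    Reads and writes the one-row coded DArTseq CSV dialects, filters loci
    by call rate, classifies loci by per-sex heterozygosity/presence
    concordance with a false-positive homozygosity test, and grades
    markers as perfectly or moderately sex-linked. Association of
    candidate markers with phenotypic sex is quantified by pairwise
    Hamming distance summaries and the Cochran-Armitage trend test
    (asymptotic and permutation p-values). Population structure tools
    cover strict autosomal filtering, principal component analysis,
    Weir-Cockerham F_ST, Nei (1972) standard genetic distance and
    allele-level hierarchical AMOVA with permutation significance. A
    seeded simulator produces DArTseq-like datasets with known cluster
    divergence (Balding-Nichols model) and known sex-linked loci so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
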