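Package: orthofam
Title: Comparative Characterization of Ortholog Coding-Sequence Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy toolkit for comparative characterization of equal-length
    ortholog coding-sequence (CDS) and protein families, as applied to
    single-copy genes such as the avian uncoupling protein (avUCP): codon
    usage and relative synonymous codon usage (RSCU), positional GC content,
    codon adaptation index (CAI) with a Markov-model expected-CAI baseline,
    alignment-site classification (conserved, parsimony-informative and
    singleton sites), per-column Shannon entropy profiles and sequence-logo
    matrices, physio-chemical protein indices (molecular weight, isoelectric
    point, instability and aliphatic indices, GRAVY, extinction coefficient),
    neighbor-joining phylogenies on Jukes-Cantor protein distances with
    bootstrap supports, Kyte-Doolittle hydropathy profiling with
    transmembrane-topology assembly, and a seeded synthetic ortholog-family
    simulator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    phangorn,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
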