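Package: wgdkit
Title: Detection, Dating and Characterization of Whole-Genome Duplications
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A comparative-genomics toolkit for detecting and dating ancient
    whole-genome duplications (WGD) from gene collinearity and synonymous
    divergence, and for characterizing the retained duplicate genes.
    Implements protein-guided codon alignment with gap-flank column cleaning,
    NG86 Ka/Ks estimation with Jukes-Cantor correction, collinear-block
    chaining between an outgroup and a focal genome, 1:1/1:2 orthology
    classification and tandem-duplicate calling, Ks-distribution peak
    detection, consensus-age meta-analysis of per-family MCMC node ages
    (burn-in, ESS screening, KDE mode, ranked-bootstrap confidence
    intervals), exact 2x2 enrichment tests with Bonferroni correction,
    GO term enrichment with the elim decorrelation algorithm, and
    population-genetic summaries (nucleotide diversity, Watterson's theta,
    Tajima's D). A seeded simulator generates genomes carrying a WGD with
    class-dependent duplicate retention, codon sequences diverged at chosen
    Ka/Ks, per-family age estimates, neutral coalescent haplotypes, and
    coverage/expression-label tables, with truth tables for
    parameter-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings,
    ape
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
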