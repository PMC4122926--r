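Package: ancprobe
Title: Ancestral Protein Reconstruction and Ancestor-Probe Homology Fishing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs ancestral protein sequences by marginal maximum
    likelihood under the WAG amino-acid substitution model and uses them as
    probes to detect deeply diverged homologs in protein sequence
    collections. Provides a sequence-evolution simulator over phylogenies
    with recorded true ancestors, gap-based alignment column trimming,
    p-distances and maximum-likelihood pairwise distances, neighbor-joining
    tree construction, group distance-comparison statistics (Mann-Whitney,
    ANOVA, Bonferroni, percentile profiles, classical multidimensional
    scaling), affine-gap local alignment with Karlin-Altschul E-values,
    best-hit taxonomic classification, six-frame ORF finding, and
    orchestration of the two end-to-end experiments (ancestor distance
    reduction; ancestor-probe fishing).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    methods,
    phangorn,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
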