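Package: discordpan
Title: Phylogenomic Discordance and Pan-Genome Analysis Under the
    Multispecies Coalescent
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale tools for quantifying phylogenomic discordance and
    pan-genome structure in closely related plant lineages. Simulates gene
    trees under the multispecies coalescent from a species tree in coalescent
    units, optionally with a pulse of introgression, and evolves nucleotide
    alignments along them under JC69. Computes polarized site-pattern counts,
    the ABBA-BABA D statistic with block-jackknife Z scores, f4 and f4-ratio
    admixture estimates, and a per-block incomplete-lineage-sorting fraction.
    Splits reference-anchored alignments into non-overlapping windows, filters
    them, infers neighbor-joining trees with bootstrap support, and classifies
    window topologies. Compares observed against simulated quartet-topology
    frequencies and estimates per-branch theta. Classifies pan-gene clusters
    into core, soft-core, shell and accession-specific categories, builds
    pan/core accumulation curves by random accession sampling, and estimates
    Ka/Ks by the Nei-Gojobori (NG86) method.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
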