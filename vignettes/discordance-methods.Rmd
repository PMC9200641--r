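---
title: "Models and methods behind discordpan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind discordpan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discordpan)
library(dplyr)
```

discordpan quantifies two intertwined phenomena in groups of closely related
plant lineages such as wild and cultivated potatoes: *phylogenomic
discordance* — the disagreement between local genealogies and the species
tree caused by incomplete lineage sorting (ILS) and introgression — and
*pan-genome structure* — the partition of gene clusters into core, soft-core,
shell and accession-specific compartments. Because the statistics involved
(D, f4-ratio, site-pattern ILS fractions, topology spectra) are usually run
on genome-scale data with external toolchains, this package pairs each
statistic with a synthetic-data generator whose ground truth is known, so
every estimator can be validated end to end at desk scale.

## The multispecies coalescent simulator

`simulate_gene_trees()` draws independent gene trees from a rooted,
ultrametric species tree whose branch lengths are in coalescent units
(1 unit = 2N generations, the convention of summary species-tree methods
such as ASTRAL). Within a species-tree branch carrying `k` gene lineages,
coalescences occur with exponential waiting times at rate `k(k-1)/2`;
lineages that fail to coalesce pass to the parent branch, and the process
finishes in the ancestral population above the root. For a quartet separated
by an internal branch of length `t`, the gene-tree topology matches the
species tree with probability `1 - (2/3) exp(-t)`, and each discordant
resolution has probability `(1/3) exp(-t)`. These closed forms are the
oracle for the simulator's acceptance checks at `t = 0.1, 0.5, 2.0`.

Introgression is modelled as a single pulse: an
`introgression_scenario(donor, recipient, t_m, gamma)` moves each gene
lineage sitting in the recipient branch at time `t_m` into the donor branch
with probability `gamma`, independently per locus. The pulse is the simplest
model under which the f4-ratio has expectation `gamma`, which is exactly the
property the recovery tests exercise. Continuous migration, recombination
within loci and demographic size changes are deliberately out of scope.

Reproducibility is per locus: the stream for locus `i` is seeded by a fixed
affine map of `(master seed, i)`, so extending `n_loci` never perturbs
earlier loci, and a `gamma = 0` scenario consumes no extra random numbers
and reproduces the scenario-free run exactly. The map is a pragmatic
splitting device, not a cryptographic stream split; it is adequate for the
Monte-Carlo tolerances used here.

`simulate_alignment()` evolves sequences along a gene tree under JC69: the
root is uniform over the four bases and a branch of length `b` (coalescent
units) changes each site with probability `(3/4)(1 - exp(-4 b s / 3))`,
where `s` is `mutation_scale`, the expected substitutions per site per
coalescent unit. The default `mutation_scale = 0.02` used throughout the
examples puts pairwise divergences in the 2–15% range typical of
intrageneric comparisons — deep enough for informative windows, far from
saturation. JC69 is intentionally minimal: the downstream statistics depend
on site-pattern counts and topology classes, not on rate heterogeneity or
base composition, and the closed-form JC expectations double as test
oracles.

## Site-pattern statistics

`count_site_patterns()` polarizes each biallelic site with the outgroup
consensus (sites with a polymorphic or missing outgroup are skipped) and
accumulates the six patterns BAAA, ABAA, AABA, BBAA, ABBA, BABA by products
of per-group derived-allele frequencies — the frequency-weighted
(Patterson-style) convention; `weighted = FALSE` restricts to sites where
every group is fixed, i.e. strict integer counting. With one haploid sample
per group the two conventions coincide. Gaps and `N` both count as missing.

From pooled counts, `d_statistic()` is `(ABBA - BABA)/(ABBA + BABA)`, and
`block_jackknife()` supplies the standard error by delete-one resampling
over contiguous blocks (20 equal-count blocks by default, or BED-defined
blocks), with `Z = D/SE`. `f4()` is the mean over usable sites of
`(pW - pX)(pY - pZ)`, and `f4_ratio()` estimates an admixture fraction as a
ratio of two f4 statistics with a jackknife SE for the ratio; the
denominator must be significantly non-zero (`|Z| > 3` by default). The
quartets are fully configurable. For the package's pulse model on the tree
`((((B,X),A),C),O)` with donor `C` and recipient `X`, the documented default
`f4(A,O;X,B)/f4(A,O;C,B)` has expectation `gamma`; the calibration tests
require the estimate to sit within 0.1 of the simulated `gamma = 0.3` and
the null (`gamma = 0`) to produce `|Z| < 3` in at least 90% of replicates.

`ils_fraction()` implements the site-pattern ILS level: the two discordant
pattern counts divided by one third of
`BAAA + ABAA + AABA + 2(BBAA + BABA + ABBA)`, the weighted total of
segregating-site patterns. How per-SNP values of this quantity are best
aggregated into a genome-wide "fraction of the genome affected by ILS" is
not standardized; `ils_profile()` therefore reports per-block values plus
the fraction of blocks exceeding a user-chosen cutoff, and that block rule
should be read as a pragmatic summary, not a canonical definition.

## Windowed discordance

`window_trees()` tiles a reference-anchored alignment into non-overlapping
windows (100 kb by default; trailing partials are kept but flagged and
excluded from spectra), computes per-window diagnostics, and applies three
strict retention filters: fully aligned length above 10 kb (columns with no
missing character in any taxon), missing-cell rate below 20% (all cells in
the denominator), and mean bootstrap support above 80. Values exactly at a
threshold fail, and the filters are monotone under relaxation.

Per-window trees are inferred by neighbor joining on Jukes–Cantor distances
with pairwise deletion, plus a site-resampling bootstrap. Distance NJ was
chosen over per-window maximum likelihood deliberately: it is exact on
additive distances (verified against an exhaustive least-squares search over
all 4- and 5-taxon topologies), deterministic under a fixed seed, and the
downstream discordance summary depends only on topology classes, for which
branch-length model fidelity is immaterial. Saturated pairs (`p >= 0.75`)
receive a large sentinel distance with a warning rather than an infinite
value so that NJ remains defined.

`classify_topology()` roots each retained tree on the outgroup and, when the
three focal groups are monophyletic, names the sister lineage of the focal
(Etuberosum-like) clade; all failures fall into `other`.
`topology_spectrum()` tallies canonical unrooted topology strings, so both
the number of retained windows and the number of distinct topologies are
reported — the two readings of a "distinct window trees" count.

## Observed versus simulated quartet frequencies

`quartet_frequencies()` reduces every tree to its induced unrooted quartet
topology for each 4-species subset via the four-point condition on the tree
metric; induced polytomies are tallied as unresolved and excluded from the
per-subset normalization. `compare_frequencies()` pairs two such tables and
reports the Pearson correlation, the statistic used to judge whether an
ILS-only coalescent simulation reproduces the observed topology mixture.
`estimate_theta()` divides matched internal-branch lengths of a
mutation-unit tree by a coalescent-unit tree, giving the per-branch
population-mutation-rate proxy; branches with zero coalescent length are
flagged undefined rather than propagated as infinities.

## Pan-genome classification, accumulation and Ka/Ks

`classify_clusters()` partitions clusters by occupancy `o` among `n`
accessions: core (`o = n`), soft-core (`soft_core_min` to `n - 1`), specific
(`o = 1`), shell (everything between). The default
`soft_core_min = ceiling(0.933 n)`, capped at `n - 1`, reproduces the 42–44
band at `n = 45` while remaining non-degenerate for small panels; below 5
accessions the bands collapse and the function refuses to classify.
`simulate_presence_absence()` inverts the classifier: categories are
apportioned to match requested proportions exactly (largest-remainder
rounding), occupancies are drawn uniformly within each band, and present
accessions uniformly at random — so classification must recover the
generated labels with zero error, which is tested.

`accumulation_curve()` implements totally random rarefaction: for each
genome count `k` it samples accession subsets uniformly (all distinct
subsets when `choose(n,k)` fits within the combination budget, the default
500 combinations with 30 replicate rounds), recording pan (union) and core
(intersection) cluster counts. Means are monotone by construction and both
variances vanish at `k = n`; on a 3-accession toy the means equal exhaustive
enumeration exactly.

`ng86_kaks()` implements the Nei–Gojobori (1986) estimator: synonymous site
fractions from each codon's nine single-nucleotide neighbours under the
standard genetic code (mutations to stop codons count as nonsynonymous
sites), sites averaged between the two sequences; differences per codon
averaged over all minimal mutational pathways with equal weight, skipping
pathways through stop codons and re-weighting (if every pathway is blocked,
all are used); and the Jukes–Cantor correction applied to `pN` and `pS`,
with `p >= 3/4` flagged saturated. Codons containing ambiguity are excluded
pairwise, a trailing stop is dropped, an internal stop is an error. Large
KaKs-Calculator-style pipelines average many estimators; this package
implements NG86 alone because it is fully specified, closed-form, and
sufficient to compare selective constraint across pan-genome compartments —
a deliberate scope decision. Under neutral JC69 simulation the estimator's
Ka/Ks is 1 within Monte-Carlo error, which the acceptance tests assert.

## Numerical choices and problem sizes

- Ties in the four-point condition (within `1e-12`) are treated as
  unresolved quartets rather than broken arbitrarily.
- Jackknife SE of exactly zero with a non-zero statistic yields an explicit
  `undefined_z` flag instead of an infinite Z.
- The calibration studies use 2,000 loci of 500 bp per replicate with 50
  replicates, 20,000 loci for closed-form frequency checks, and 300–400
  2-kb windows for the end-to-end pipeline — sizes chosen so the full
  validation suite runs on a single CPU in minutes while keeping Monte-Carlo
  standard errors a factor of three below every tolerance asserted.

## What the generators do not emulate

The synthetic data are idealized: no rate heterogeneity among sites or
branches, no base-composition bias, no alignment error, no missing-data
structure correlated with divergence, no linked selection, and one haploid
sample per species by default. Passing tests therefore demonstrate that the
estimators are correct under their stated models, not that real alignments
satisfy those models; on real data the filters (missing rate, bootstrap) and
the jackknife blocking carry the weight of robustness, and D/f4 statistics
retain their usual caveats about ancestral structure mimicking gene flow.
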