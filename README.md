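# discordpan

Phylogenomic discordance and pan-genome analysis under the multispecies
coalescent, at desk scale.

In groups of recently diverged lineages — wild and cultivated potatoes and
their tomato relatives are the motivating case — local genealogies disagree
with the species tree because of incomplete lineage sorting (ILS) and
interspecific gene flow, and the gene repertoire itself varies between
accessions. discordpan provides, in one tidyverse-style R package, the
statistics used to dissect both phenomena together with simulators that
generate every required input with known ground truth:

- **Multispecies coalescent (MSC) simulation** — gene trees from a species
  tree in coalescent units (`simulate_gene_trees()`), optionally with a
  pulse of introgression of fraction γ (`introgression_scenario()`), plus
  JC69 sequence evolution along those trees (`simulate_alignment()`). For an
  internal branch of length *t*, gene trees match the species tree with
  probability 1 − (2/3)e^(−t) — the closed form every simulation is checked
  against.
- **Site-pattern statistics** — polarized ABBA/BABA counting with frequency
  weighting (`count_site_patterns()`), the D statistic
  D = (ABBA − BABA)/(ABBA + BABA) with block-jackknife Z
  (`abba_baba()`, `block_jackknife()`), f4 and f4-ratio admixture estimates
  (`f4()`, `f4_ratio()`), and the site-pattern ILS level
  (ABBA + BABA) / [(BAAA + ABAA + AABA + 2(BBAA + BABA + ABBA)) / 3]
  (`ils_fraction()`).
- **Windowed discordance** — non-overlapping windows with strict retention
  filters (aligned length > 10 kb, missing rate < 20%, mean bootstrap > 80),
  neighbor-joining trees with site-resampling bootstrap, topology
  classification and spectra (`window_trees()`, `topology_spectrum()`).
- **Observed vs simulated quartet frequencies** — induced quartet topologies
  per 4-species subset, Pearson comparison against MSC expectations, and
  per-branch theta = mutation units / coalescent units
  (`quartet_frequencies()`, `compare_frequencies()`, `estimate_theta()`).
- **Pan-genome structure** — core / soft-core / shell / accession-specific
  classification (core = all *n* accessions; soft-core = 42–44 of 45;
  specific = 1), totally-random accumulation curves, and NG86 Ka/Ks with
  Jukes–Cantor correction (`classify_clusters()`, `accumulation_curve()`,
  `ng86_kaks()`).

Fitted objects ship with `tidy()`/`glance()` methods and `autoplot()`
figures; all tabular inputs and outputs are data frames/tibbles.

## Worked example

Simulate 5,000 coalescent gene trees on a quartet with an internal branch of
0.5 coalescent units, then detect and quantify a γ = 0.3 introgression pulse
from sequence data:

```r
library(discordpan)

sp <- ape::read.tree(text = "(((A:1,B:1):0.5,C:1.5):1,O:2.5);")
sim <- simulate_gene_trees(sp, n_loci = 5000, seed = 1)
quartet_frequencies(sim)
#> # A tibble: 3 × 5
#>   subset  topology count n_resolved  freq
#>   <chr>   <chr>    <dbl>      <dbl> <dbl>
#> 1 A,B,C,O A,B|C,O   3000       5000 0.6
#> 2 A,B,C,O A,C|B,O    977       5000 0.195
#> 3 A,B,C,O A,O|B,C   1023       5000 0.205
```

The concordant fraction 0.600 sits on the coalescent expectation
1 − (2/3)e^(−0.5) = 0.596, and the two discordant classes split the
remainder evenly, as ILS predicts. Now add gene flow on a five-taxon tree
`((((B,X),A),C),O)` — donor `C` into recipient `X`:

```r
sp5 <- ape::read.tree(text = "((((B:1,X:1):0.5,A:1.5):1,C:2.5):1.5,O:4);")
sc  <- introgression_scenario(donor = "C", recipient = "X",
                              t_m = 0.5, gamma = 0.3)
gt  <- simulate_gene_trees(sp5, n_loci = 2000, scenario = sc, seed = 1)
al  <- simulate_alignments(gt, locus_length = 500, mutation_scale = 0.02,
                           seed = 1)
pooled <- concat_alignments(al)

abba_baba(pooled, c(B = "P1", X = "P2", C = "P3", O = "O"), blocks = 20)
#> <D statistic, block jackknife>
#>   estimate = 0.63862, SE = 0.017739, Z = 36.001, blocks = 20

f4_ratio(pooled, c(A = "A", B = "B", X = "X", C = "C", O = "O"),
         c("A", "O", "X", "B"), c("A", "O", "C", "B"), blocks = 20)
#> <f4-ratio A,O,X,B / A,O,C,B>
#>   alpha = 0.31649, SE = 0.026633, blocks = 20
```

D is strongly positive (Z = 36): derived alleles are shared between the
recipient and the donor lineage far in excess of the ILS expectation. The
f4-ratio estimate α = 0.316 ± 0.027 recovers the simulated admixture
fraction γ = 0.3. Under γ = 0 the same pipeline gives |Z| < 3 (no false
signal); that calibration is part of the test suite.

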