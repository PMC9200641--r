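simple_groups <- c(P1 = "P1", P2 = "P2", P3 = "P3", O = "O")

test_that("haploid site patterns match per-site manual classification", {
  aln <- multi_alignment(c(P1 = "GAG", P2 = "AGA", P3 = "AGG", O = "AAA"))
  cts <- count_site_patterns(aln, simple_groups)
  expect_equal(cts$BAAA, 1)
  expect_equal(cts$ABBA, 1)
  expect_equal(cts$BABA, 1)
  expect_equal(cts$ABAA + cts$AABA + cts$BBAA, 0)
  expect_equal(cts$n_sites_used, 3L)
})

test_that("monomorphic data yields zero counts with a warning", {
  aln <- multi_alignment(c(P1 = "ACGT", P2 = "ACGT", P3 = "ACGT",
                           O = "ACGT"))
  expect_warning(cts <- count_site_patterns(aln, simple_groups),
                 "no usable sites")
  expect_equal(sum(cts[, c("BAAA", "ABAA", "AABA", "BBAA", "ABBA",
                           "BABA")]), 0)
})

test_that("frequency weighting multiplies group allele frequencies", {
  # p1 = p2 = 0.5, p3 = 1 at a single site: ABBA = BABA = 0.25
  aln <- multi_alignment(c(P1a = "G", P1b = "A", P2a = "G", P2b = "A",
                           P3a = "G", P3b = "G", O = "A"))
  groups <- c(P1a = "P1", P1b = "P1", P2a = "P2", P2b = "P2",
              P3a = "P3", P3b = "P3", O = "O")
  cts <- count_site_patterns(aln, groups)
  expect_equal(cts$ABBA, 0.25)
  expect_equal(cts$BABA, 0.25)
  expect_equal(cts$AABA, 0.25)
  # strict counting drops the polymorphic-group site entirely
  strict <- suppressWarnings(count_site_patterns(aln, groups,
                                                 weighted = FALSE))
  expect_equal(strict$n_sites_used, 0L)
})

test_that("polymorphic or missing outgroup sites are skipped", {
  aln <- multi_alignment(c(P1 = "GG", P2 = "AA", P3 = "AA",
                           O1 = "AG", O2 = "GG"))
  groups <- c(P1 = "P1", P2 = "P2", P3 = "P3", O1 = "O", O2 = "O")
  # site 1: outgroup polymorphic (A/G) -> skipped;
  # site 2: O1=G,O2=G monomorphic -> anc G, P1 ancestral, P2/P3 derived
  cts <- count_site_patterns(aln, groups)
  expect_equal(cts$n_sites_used, 1L)
  expect_equal(cts$AABA + cts$ABAA, 0)
  expect_equal(cts$BBAA, 0)
  # derived in P2 and P3, ancestral in P1 -> ABBA-type with B = derived
  expect_equal(cts$ABBA, 1)
})

test_that("alignment and SNP-table inputs agree on the same sites", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tp1\tp2\tp3\tog",
    "chr1\t1\t.\tA\tG\t.\t.\t.\tGT\t1/1\t0/0\t1/1\t0/0",
    "chr1\t2\t.\tC\tT\t.\t.\t.\tGT\t0/0\t1/1\t1/1\t0/0",
    "chr1\t3\t.\tG\tA\t.\t.\t.\tGT\t1/1\t1/1\t0/0\t0/0",
    "chr1\t4\t.\tT\tC\t.\t.\t.\tGT\t0/0\t0/0\t0/0\t1/1"
  ), path)
  snp <- read_snp_table(path)
  groups <- c(p1 = "P1", p2 = "P2", p3 = "P3", og = "O")
  cts_snp <- count_site_patterns(snp, groups)
  # equivalent haploid alignment (site 4: outgroup carries ALT, so REF is
  # derived in all of P1..P3 -> BBBA, contributing to no accumulator)
  aln <- multi_alignment(c(p1 = "GCAT", p2 = "ATAT", p3 = "GTGT",
                           og = "ACGC"))
  cts_aln <- count_site_patterns(aln, groups)
  for (col in c("BAAA", "ABAA", "AABA", "BBAA", "ABBA", "BABA")) {
    expect_equal(cts_snp[[col]], cts_aln[[col]], info = col)
  }
  expect_equal(cts_snp$BABA, 1)  # site 1
  expect_equal(cts_snp$ABBA, 1)  # site 2
  expect_equal(cts_snp$BBAA, 1)  # site 3
})

test_that("D statistic arithmetic and boundaries", {
  expect_equal(d_statistic(counts_row(ABBA = 10, BABA = 10)), 0)
  expect_equal(d_statistic(counts_row(ABBA = 10, BABA = 0)), 1)
  expect_equal(d_statistic(counts_row(ABBA = 30, BABA = 20)), 0.2)
  expect_error(d_statistic(counts_row(BAAA = 5)), "undefined")
})

test_that("block jackknife matches a brute-force delete-one transcription", {
  abba <- c(3, 2, 4, 1, 5)
  baba <- c(1, 2, 0, 3, 1)
  bc <- dplyr::bind_rows(lapply(1:5, function(i) {
    counts_row(ABBA = abba[i], BABA = baba[i], block = i)
  }))
  res <- block_jackknife(bc)
  expect_equal(res$estimate, 8 / 22)
  # independent literal transcription of the delete-one scheme
  loo <- vapply(1:5, function(i) {
    a <- sum(abba[-i]); b <- sum(baba[-i])
    (a - b) / (a + b)
  }, numeric(1))
  se <- sqrt((4 / 5) * sum((loo - mean(loo))^2))
  expect_equal(res$se, se)
  expect_equal(res$z, (8 / 22) / se)
  expect_equal(res$n_blocks, 5L)
})

test_that("jackknife degenerate cases are flagged", {
  sym <- dplyr::bind_rows(lapply(1:4, function(i) {
    counts_row(ABBA = 2, BABA = 2, block = i)
  }))
  res <- block_jackknife(sym)
  expect_equal(res$estimate, 0)
  expect_equal(res$z, 0)
  expect_false(res$undefined_z)

  skewed <- dplyr::bind_rows(lapply(1:3, function(i) {
    counts_row(ABBA = 4, BABA = 1, block = i)
  }))
  res2 <- block_jackknife(skewed)
  expect_true(res2$undefined_z)
  expect_true(is.na(res2$z))

  expect_error(block_jackknife(counts_row(ABBA = 1, BABA = 1)),
               "at least 2")
})

test_that("pooled statistics equal block-weighted recombination", {
  set.seed(31)
  bc <- dplyr::bind_rows(lapply(1:6, function(i) {
    counts_row(BAAA = rpois(1, 5), ABAA = rpois(1, 5), AABA = rpois(1, 5),
               BBAA = rpois(1, 8), ABBA = rpois(1, 4), BABA = rpois(1, 3),
               block = i)
  }))
  pooled <- counts_row(BAAA = sum(bc$BAAA), ABAA = sum(bc$ABAA),
                       AABA = sum(bc$AABA), BBAA = sum(bc$BBAA),
                       ABBA = sum(bc$ABBA), BABA = sum(bc$BABA))
  expect_equal(d_statistic(bc), d_statistic(pooled))
  expect_equal(ils_fraction(bc), ils_fraction(pooled))
})

test_that("ILS fraction follows the printed site-pattern formula", {
  expect_equal(ils_fraction(counts_row(BAAA = 2, ABAA = 3, BBAA = 4)), 0)
  cts <- counts_row(ABBA = 3, BABA = 3, BAAA = 2, ABAA = 2, AABA = 2,
                    BBAA = 4)
  expect_equal(ils_fraction(cts), 18 / 26)
  expect_equal(ils_fraction(counts_row(BBAA = 9)), 0)
  expect_error(ils_fraction(counts_row()), "undefined")
})

test_that("ILS profile summarizes blocks against a cutoff", {
  bc <- dplyr::bind_rows(
    counts_row(ABBA = 5, BABA = 5, BBAA = 2, block = 1L),   # high ILS
    counts_row(ABBA = 0.5, BABA = 0.5, BBAA = 20, block = 2L),
    counts_row(BBAA = 10, block = 3L)                       # zero ILS
  )
  pr <- ils_profile(bc, cutoff = 0.5)
  expect_equal(nrow(pr$per_block), 3L)
  expect_equal(pr$genome_fraction_ils, 1 / 3)
})

test_that("f4 sign conventions and arithmetic", {
  # haploid taxa, outgroup-free statistic: two usable sites
  aln <- multi_alignment(c(W1 = "GG", W2 = "GA", X = "AA", Y = "GA",
                           Z = "AG"))
  groups <- c(W1 = "W", W2 = "W", X = "X", Y = "Y", Z = "Z")
  # site 1 (tracked allele A): pW=0, pX=1, pY=0, pZ=1 -> (0-1)(0-1)=1
  # site 2: pW=0.5, pX=1, pY=1, pZ=0 -> (0.5-1)(1-0) = -0.5
  r <- f4(aln, groups, c("W", "X", "Y", "Z"))
  expect_equal(r$f4, (1 - 0.5) / 2)
  flip <- f4(aln, groups, c("X", "W", "Y", "Z"))
  expect_equal(flip$f4, -r$f4)
  same <- f4(aln, groups, c("W", "W", "Y", "Z"))
  expect_equal(same$f4, 0)
})

test_that("f4 ratio of identical quartets is one", {
  aln <- multi_alignment(c(A = "GGAAG", B = "GAAAG", C = "AGGGA",
                           O = "AAAAA", X = "GAGGA"))
  groups <- c(A = "A", B = "B", C = "C", O = "O", X = "X")
  r <- f4_ratio(aln, groups, c("A", "O", "C", "B"), c("A", "O", "C", "B"),
                blocks = NULL, z_threshold = 0)
  expect_equal(r$alpha, 1)
})

test_that("tidiers expose D and f4 results as tibbles", {
  bc <- dplyr::bind_rows(lapply(1:4, function(i) {
    counts_row(ABBA = 3 + i, BABA = 2, block = i)
  }))
  res <- block_jackknife(bc)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("statistic", "estimate", "std.error", "z", "n_blocks",
                     "undefined_z"))
  gl <- glance(res)
  expect_true(all(c("ABBA", "BABA", "n_sites_used") %in% names(gl)))
})
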