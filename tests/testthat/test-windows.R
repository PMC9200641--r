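toy_aln <- function(n_taxa = 3, width = 2500, start = 0, chrom = "chr1",
                    seed = 1) {
  set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), n_taxa * width, replace = TRUE),
              n_taxa, width)
  rownames(m) <- paste0("t", seq_len(n_taxa))
  multi_alignment(m, region = list(chrom = chrom, start = start,
                                   end = start + width))
}

test_that("windows tile the region with a flagged trailing partial", {
  cfg <- window_filter_config(window_size = 1000, min_aligned = 100)
  w <- split_windows(toy_aln(width = 2500), cfg)
  expect_equal(nrow(w), 3L)
  expect_equal(w$start, c(0L, 1000L, 2000L))
  expect_equal(w$end, c(1000L, 2000L, 2500L))
  expect_equal(w$partial, c(FALSE, FALSE, TRUE))
  # tiles cover the region exactly
  expect_equal(sum(w$end - w$start), 2500L)
  expect_equal(sum(vapply(w$alignment, n_sites, integer(1))), 2500L)

  one <- split_windows(toy_aln(width = 1000), cfg)
  expect_equal(nrow(one), 1L)
  expect_false(one$partial)

  short <- split_windows(toy_aln(width = 999), cfg)
  expect_equal(nrow(short), 1L)
  expect_true(short$partial)
})

test_that("windows respect absolute reference coordinates", {
  cfg <- window_filter_config(window_size = 1000, min_aligned = 100)
  w <- split_windows(toy_aln(width = 1500, start = 500), cfg)
  expect_equal(w$start, c(500L, 1000L))
  expect_equal(w$end, c(1000L, 2000L))
  expect_equal(w$partial, c(TRUE, FALSE))
})

test_that("window statistics count fully aligned columns and missing cells", {
  m <- rbind(t1 = c("A", "C", "G", "T", "N"),
             t2 = c("A", "-", "G", "T", "A"),
             t3 = c("A", "C", "G", "N", "A"))
  aln <- multi_alignment(m)
  st <- window_stats(aln)
  expect_equal(st$aligned_length, 2L)       # columns 1 and 3
  expect_equal(st$missing_rate, 3 / 15)     # cells convention
})

test_that("retention filters are strict inequalities", {
  cfg <- window_filter_config()
  recs <- tibble::tibble(
    aligned_length = c(9000, 50000, 50000, 10000),
    missing_rate = c(0.05, 0.10, 0.05, 0.05),
    mean_bootstrap = c(95, 95, 80, 95)
  )
  out <- filter_windows(recs, cfg)
  expect_equal(out$passed, c(FALSE, TRUE, FALSE, FALSE))
  expect_false(out$pass_aligned[1])
  expect_false(out$pass_bootstrap[3])       # exactly 80 fails
  expect_false(out$pass_aligned[4])         # exactly 10 kb fails
})

test_that("filters are monotone under threshold relaxation", {
  set.seed(77)
  recs <- tibble::tibble(
    aligned_length = runif(50, 0, 100000),
    missing_rate = runif(50),
    mean_bootstrap = runif(50, 0, 100)
  )
  strict <- filter_windows(recs, window_filter_config())
  relaxed <- filter_windows(recs, window_filter_config(
    min_aligned = 5000, max_missing = 0.5, min_mean_bootstrap = 50))
  expect_true(all(relaxed$passed[strict$passed]))
})

test_that("JC distances invert the substitution model", {
  aln <- multi_alignment(c(a = "AAAA", b = "AAAA", c = "AAAA"))
  expect_true(all(jc_distance_matrix(aln) == 0))

  # exactly 937 differences over 10,000 sites: p = 0.0937
  n_diff <- 937
  s1 <- rep("A", 10000)
  s2 <- s1
  s2[seq_len(n_diff)] <- "C"
  s3 <- rep("G", 10000)
  aln2 <- multi_alignment(rbind(a = s1, b = s2,
                                c = c(rep("A", 5000), rep("G", 5000))))
  d <- jc_distance_matrix(aln2)
  expect_equal(d["a", "b"], -0.75 * log(1 - 4 * 0.0937 / 3))
  expect_equal(round(d["a", "b"], 4), 0.1, tolerance = 1e-3)

  # agreement with the reference implementation on clean data
  db <- ape::dist.dna(ape::as.DNAbin(strsplit(apply(aln2$seq, 1, paste,
                                                    collapse = ""), "")),
                      model = "JC69", as.matrix = TRUE)
  expect_equal(unname(d), unname(db), tolerance = 1e-10)
})

test_that("saturated and incomparable pairs are handled", {
  sat <- multi_alignment(rbind(a = rep("A", 100), b = rep("C", 100),
                               c = c(rep("A", 50), rep("C", 50))))
  expect_warning(d <- jc_distance_matrix(sat), "saturated")
  expect_equal(d["a", "b"], 10)

  gap <- multi_alignment(rbind(a = c("A", "C", "N", "N"),
                               b = c("N", "N", "G", "T"),
                               c = c("A", "C", "G", "T")))
  expect_error(jc_distance_matrix(gap), "a, b")
})

test_that("neighbor joining recovers additive trees exactly", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:1,D:1):1);")
  d <- ape::cophenetic.phylo(tr)
  nt <- nj_tree(d)
  expect_equal(canonical_topology(nt), canonical_topology(tr))
  # internal branch length: rooted 1+1 collapses to a single edge of 2
  internal <- nt$edge.length[nt$edge[, 2L] > ape::Ntip(nt)]
  expect_equal(sort(internal), 2)

  expect_equal(ape::Ntip(nj_tree(d[1:3, 1:3])), 3L)
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("bootstrap supports are deterministic under a fixed seed", {
  tr <- ape::read.tree(
    text = "(((t1:0.05,t2:0.05):0.05,t3:0.1):0.1,(t4:0.1,t5:0.1):0.1);")
  aln <- simulate_alignment(tr, 400, mutation_scale = 1, seed = 12)
  d <- jc_distance_matrix(aln)
  t1 <- nj_tree(d, aln = aln, bootstrap = 50, seed = 3)
  t2 <- nj_tree(d, aln = aln, bootstrap = 50, seed = 3)
  expect_identical(t1$node.label, t2$node.label)
  expect_true(is.na(t1$node.label[1]))
  sup <- as.numeric(t1$node.label[-1])
  expect_true(all(sup >= 0 & sup <= 100))
  expect_error(nj_tree(d, bootstrap = 10), "alignment")
})

test_that("topology classification reads the sister of the focal clade", {
  groups <- c(E1 = "ETB", E2 = "ETB", P1 = "PET", P2 = "PET",
              L1 = "LYC", OUT = "OUT")
  t_pet <- ape::read.tree(
    text = "((((E1:1,E2:1):1,(P1:1,P2:1):1):1,L1:2):1,OUT:3);")
  expect_equal(classify_topology(t_pet, groups), "ETB_sister_to_PET")
  t_lyc <- ape::read.tree(
    text = "((((E1:1,E2:1):1,L1:2):1,(P1:1,P2:1):1):1,OUT:3);")
  expect_equal(classify_topology(t_lyc, groups), "ETB_sister_to_LYC")
  t_both <- ape::read.tree(
    text = "(((E1:1,E2:1):1,((P1:1,P2:1):1,L1:2):1):1,OUT:3);")
  expect_equal(classify_topology(t_both, groups), "ETB_sister_to_PET_LYC")
  # PET paraphyletic: one PET leaf inside the LYC+P2 clade
  t_para <- ape::read.tree(
    text = "((((E1:1,E2:1):1,P1:1):1,(P2:1,L1:1):1):1,OUT:3);")
  expect_equal(classify_topology(t_para, groups), "other")
  expect_error(classify_topology(t_pet, c(E1 = "ETB", P1 = "PET",
                                          L1 = "LYC")), "OUT")
})

test_that("topology spectrum counts canonical topologies and classes", {
  tr <- ape::read.tree(text = "(((E:1,P:1):1,L:1):1,OUT:1);")
  recs <- tibble::tibble(
    tree = rep(list(tr), 10),
    passed = rep(TRUE, 10),
    partial = rep(FALSE, 10),
    topology_class = rep("ETB_sister_to_PET", 10)
  )
  sp <- topology_spectrum(recs)
  expect_equal(nrow(sp$spectrum), 1L)
  expect_equal(sp$spectrum$count, 10L)
  expect_equal(sp$n_windows_passed, 10L)
  expect_equal(sum(sp$class_counts$fraction), 1)
  expect_equal(glance(sp)$n_distinct_topologies, 1L)
})

test_that("canonical topology is invariant to rotation and lengths", {
  a <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):1);")
  b <- ape::read.tree(text = "((D:9,C:9):9,(B:9,A:9):9);")
  c3 <- ape::read.tree(text = "(((A:1,C:1):1,B:1):1,D:1);")
  expect_equal(canonical_topology(a), canonical_topology(b))
  expect_false(canonical_topology(a) == canonical_topology(c3))
})
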