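test_that("occupancy bands at n = 45 match the category definitions", {
  th <- pan_thresholds(45)
  expect_equal(th$soft_core_min, 42L)
  m <- matrix(0L, 4, 45,
              dimnames = list(paste0("c", 1:4), paste0("a", 1:45)))
  m[1, ] <- 1L                 # 45 accessions -> core
  m[2, 1:43] <- 1L             # 43 -> soft-core
  m[3, 1:10] <- 1L             # 10 -> shell
  m[4, 1] <- 1L                # 1 -> specific
  cl <- classify_clusters(m, th)
  expect_equal(as.character(cl$clusters$category),
               c("core", "soft_core", "shell", "specific"))
  expect_equal(sum(cl$summary$n), 4L)
  # band edges: 42 and 44 are soft-core, 41 is shell
  edges <- matrix(0L, 3, 45)
  rownames(edges) <- paste0("e", 1:3)
  edges[1, 1:42] <- 1L
  edges[2, 1:44] <- 1L
  edges[3, 1:41] <- 1L
  cle <- classify_clusters(edges, th)
  expect_equal(as.character(cle$clusters$category),
               c("soft_core", "soft_core", "shell"))
})

test_that("classification is invariant to row and column order", {
  pa <- simulate_presence_absence(12, 200, c(0.3, 0.2, 0.4, 0.1), seed = 8)
  m <- pa$matrix
  cl <- classify_clusters(m)
  set.seed(9)
  shuffled <- m[sample(nrow(m)), sample(ncol(m))]
  cl2 <- classify_clusters(shuffled)
  ref <- cl$clusters[match(cl2$clusters$cluster, cl$clusters$cluster), ]
  expect_equal(as.character(cl2$clusters$category),
               as.character(ref$category))
})

test_that("classifier recovers generator labels exactly", {
  pa <- simulate_presence_absence(45, 3000,
                                  c(0.255, 0.112, 0.554, 0.079), seed = 17)
  cl <- classify_clusters(pa$matrix)
  expect_equal(as.character(cl$clusters$category),
               as.character(pa$truth$category))
})

test_that("all-zero clusters are dropped with a message", {
  m <- matrix(c(1L, 1L, 0L, 0L, 1L, 0L), 2, 3,
              dimnames = list(c("c1", "c2"), c("a", "b", "c")))
  m2 <- rbind(m, c0 = c(0L, 0L, 0L))
  expect_error(classify_clusters(m2), "5 accessions")
  m5 <- cbind(m2, d = c(1L, 0L, 0L), e = c(1L, 0L, 0L))
  expect_message(cl <- classify_clusters(m5), "dropped")
  expect_equal(nrow(cl$clusters), 2L)
})

test_that("accumulation curve matches exhaustive enumeration on a toy", {
  # 3 accessions x 6 clusters
  m <- matrix(c(1, 1, 1,
                1, 1, 0,
                1, 0, 0,
                0, 1, 0,
                0, 0, 1,
                0, 1, 1), 6, 3, byrow = TRUE,
              dimnames = list(paste0("c", 1:6), c("a", "b", "c")))
  cv <- accumulation_curve(m, n_combinations = 500, replications = 2,
                           seed = 4)
  # independent exhaustive oracle over all subsets of each size
  for (k in 1:3) {
    subs <- utils::combn(3, k, simplify = FALSE)
    pan <- vapply(subs, function(s) {
      sum(rowSums(m[, s, drop = FALSE]) > 0)
    }, numeric(1))
    core <- vapply(subs, function(s) {
      sum(rowSums(m[, s, drop = FALSE]) == k)
    }, numeric(1))
    expect_equal(cv$pan_mean[cv$k == k], mean(pan))
    expect_equal(cv$core_mean[cv$k == k], mean(core))
  }
  # k = n endpoints: no variance, pan = all clusters, core = universal ones
  expect_equal(cv$pan_min[cv$k == 3], cv$pan_max[cv$k == 3])
  expect_equal(cv$pan_mean[cv$k == 3], 6)
  expect_equal(cv$core_mean[cv$k == 3], 1)
  # k = 1: mean pan equals mean per-accession cluster count
  expect_equal(cv$pan_mean[cv$k == 1], mean(colSums(m)))
})

test_that("accumulation means are monotone for any seed", {
  pa <- simulate_presence_absence(10, 300, c(0.3, 0.1, 0.5, 0.1), seed = 2)
  for (s in 1:3) {
    cv <- accumulation_curve(pa$matrix, n_combinations = 30,
                             replications = 3, seed = s)
    expect_true(all(diff(cv$pan_mean) >= 0))
    expect_true(all(diff(cv$core_mean) <= 0))
  }
  cv <- accumulation_curve(pa$matrix, n_combinations = 30, replications = 3,
                           seed = 1)
  cv2 <- accumulation_curve(pa$matrix, n_combinations = 30,
                            replications = 3, seed = 1)
  expect_equal(as.data.frame(cv), as.data.frame(cv2))
  expect_s3_class(autoplot(cv), "ggplot")
})

test_that("NG86 handles identical and synonymous-only pairs", {
  same <- ng86_kaks("ATGGCT", "ATGGCT")
  expect_equal(same$ka, 0)
  expect_equal(same$ks, 0)
  expect_true(same$ratio_undefined)

  # Gly GGT -> GGC in a three-codon context: purely synonymous
  syn <- ng86_kaks("AAAAAAGGT", "AAAAAAGGC")
  expect_equal(syn$nd, 0)
  expect_equal(syn$sd, 1)
  expect_equal(syn$ka, 0)
  expect_gt(syn$ks, 0)
})

test_that("NG86 site and difference counts match hand enumeration", {
  r <- ng86_kaks("TTT", "TTA")
  expect_equal(r$n_sites, 2.5)
  expect_equal(r$s_sites, 0.5)
  expect_equal(r$nd, 1)
  expect_equal(r$sd, 0)
  expect_equal(r$ka, -0.75 * log(1 - 4 * 0.4 / 3))
  expect_equal(round(r$ka, 4), 0.5716)
  expect_equal(r$ks, 0)
  # invariants
  expect_equal(r$n_sites + r$s_sites, 3 * r$n_codons_used)
})

test_that("NG86 is symmetric and codon-order invariant", {
  a <- "ATGGCTCGATTTACC"
  b <- "ATGGGTCGCTTAACA"
  r1 <- tidy(ng86_kaks(a, b))
  r2 <- tidy(ng86_kaks(b, a))
  expect_equal(r1, r2)
  # permute codons jointly
  perm <- c(4, 1, 5, 2, 3)
  codons <- function(x) substring(x, 3 * (seq_len(5) - 1) + 1,
                                  3 * seq_len(5))
  a2 <- paste(codons(a)[perm], collapse = "")
  b2 <- paste(codons(b)[perm], collapse = "")
  expect_equal(tidy(ng86_kaks(a2, b2)), r1)
})

test_that("NG86 rejects malformed CDS input", {
  expect_error(ng86_kaks("ATGG", "ATGA"), "multiple of 3")
  expect_error(ng86_kaks("ATGTAAGCT", "ATGAAAGCT"), "stop codon at codon 2")
  # trailing stop codons are tolerated
  r <- ng86_kaks("ATGGCTTAA", "ATGGCATAA")
  expect_equal(r$n_codons_used, 2L)
})

test_that("multi-hit codons average over unblocked minimal pathways", {
  # TTT -> GTA: paths TTT->GTT->GTA (nonsyn Phe>Val, syn Val>Val)
  #            and TTT->TTA->GTA (nonsyn Phe>Leu, nonsyn Leu>Val)
  r <- ng86_kaks("TTT", "GTA")
  expect_equal(r$sd, 0.5)
  expect_equal(r$nd, 1.5)
})
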