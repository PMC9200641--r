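# shared fixtures: small species trees and group maps used across tests

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# 4-taxon ingroup quartet ((A,B),C) with outgroup O; internal branch 0.5
tree4 <- function(t = 0.5) {
  ape::read.tree(text = sprintf(
    "(((A:1,B:1):%s,C:%s):1,O:%s);", t, 1 + t, 2 + t))
}

# 5-taxon tree for pulse introgression: ((((B,X),A),C),O), donor C -> X
tree5_pulse <- function() {
  ape::read.tree(text = "((((B:1,X:1):0.5,A:1.5):1,C:2.5):1.5,O:4);")
}

groups_dstat <- c(B = "P1", X = "P2", C = "P3", O = "O")
groups_all5 <- c(A = "A", B = "B", X = "X", C = "C", O = "O")

# one D / f4-ratio replicate on simulated loci (2,000 x 500 bp by default)
sim_replicate <- function(seed, gamma = 0, n_loci = 2000, locus_length = 500,
                          with_f4 = FALSE) {
  sc <- if (gamma > 0) {
    introgression_scenario("C", "X", t_m = 0.5, gamma = gamma)
  } else {
    NULL
  }
  gt <- simulate_gene_trees(tree5_pulse(), n_loci, scenario = sc, seed = seed)
  al <- simulate_alignments(gt, locus_length, mutation_scale = 0.02,
                            seed = seed)
  big <- concat_alignments(al)
  jk <- abba_baba(big, groups_dstat, blocks = 20)
  out <- list(d = jk$estimate, z = jk$z)
  if (with_f4) {
    fr <- f4_ratio(big, groups_all5, c("A", "O", "X", "B"),
                   c("A", "O", "C", "B"), blocks = 20)
    out$alpha <- fr$alpha
  }
  out
}

# site-pattern counts tibble built directly (one block per row)
counts_row <- function(BAAA = 0, ABAA = 0, AABA = 0, BBAA = 0, ABBA = 0,
                       BABA = 0, block = 1L, n_sites_used = NULL) {
  if (is.null(n_sites_used)) {
    n_sites_used <- as.integer(ceiling(BAAA + ABAA + AABA + BBAA + ABBA +
                                         BABA))
  }
  tibble::tibble(block = block, BAAA = BAAA, ABAA = ABAA, AABA = AABA,
                 BBAA = BBAA, ABBA = ABBA, BABA = BABA,
                 n_sites_used = n_sites_used)
}

# every unrooted topology on 4 taxa (3) or 5 taxa (15), built from newick
all_unrooted_shapes <- function(taxa) {
  pairings <- function(four) {
    list(list(four[c(1, 2)], four[c(3, 4)]),
         list(four[c(1, 3)], four[c(2, 4)]),
         list(four[c(1, 4)], four[c(2, 3)]))
  }
  texts <- if (length(taxa) == 4L) {
    vapply(pairings(taxa), function(p) {
      sprintf("((%s,%s),(%s,%s));", p[[1]][1], p[[1]][2], p[[2]][1],
              p[[2]][2])
    }, character(1))
  } else if (length(taxa) == 5L) {
    unlist(lapply(taxa, function(s) {
      rest <- setdiff(taxa, s)
      vapply(pairings(rest), function(p) {
        sprintf("((%s,%s),%s,(%s,%s));", p[[1]][1], p[[1]][2], s,
                p[[2]][1], p[[2]][2])
      }, character(1))
    }))
  } else {
    stop("only 4- or 5-taxon shapes are enumerated")
  }
  lapply(texts, function(tx) ape::read.tree(text = tx))
}

# exhaustive least-squares topology search over all unrooted shapes:
# independent oracle for neighbor joining
ls_best_topology <- function(d) {
  taxa <- rownames(d)
  shapes <- all_unrooted_shapes(taxa)
  pair_idx <- utils::combn(length(taxa), 2L)
  rss <- vapply(shapes, function(tr) {
    tr$edge.length <- rep(1, nrow(tr$edge))
    # path-edge incidence matrix: which edges lie on the path between i and j
    A <- matrix(0, ncol(pair_idx), nrow(tr$edge))
    for (p in seq_len(ncol(pair_idx))) {
      i <- match(taxa[pair_idx[1L, p]], tr$tip.label)
      j <- match(taxa[pair_idx[2L, p]], tr$tip.label)
      path_nodes <- ape::nodepath(tr, i, j)
      edges <- map_edge_indices(tr, path_nodes)
      A[p, edges] <- 1
    }
    y <- d[cbind(taxa[pair_idx[1L, ]], taxa[pair_idx[2L, ]])]
    fit <- stats::lm.fit(A, y)
    sum(fit$residuals^2)
  }, numeric(1L))
  canonical_topology(shapes[[which.min(rss)]])
}

map_edge_indices <- function(tr, path_nodes) {
  vapply(seq_len(length(path_nodes) - 1L), function(k) {
    a <- path_nodes[k]
    b <- path_nodes[k + 1L]
    which((tr$edge[, 1L] == a & tr$edge[, 2L] == b) |
            (tr$edge[, 1L] == b & tr$edge[, 2L] == a))
  }, integer(1L))
}
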