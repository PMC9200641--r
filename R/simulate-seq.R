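#' Evolve a nucleotide alignment along a gene tree under JC69
#'
#' The root sequence is drawn uniformly over `{A, C, G, T}`; along each branch
#' the JC69 substitution process runs for `branch length * mutation_scale`
#' expected substitutions per site, i.e. a site changes state with probability
#' `(3/4)(1 - exp(-4 d / 3))` and, given a change, picks one of the other
#' three bases uniformly.
#'
#' @param tree A rooted `phylo` gene tree with non-negative branch lengths
#'   (coalescent units) and unique tip labels.
#' @param locus_length Alignment length in bp.
#' @param mutation_scale Expected substitutions per site per coalescent unit
#'   of branch length (a theta-like scale factor).
#' @param seed Integer seed; a fixed seed gives identical output.
#' @return A [multi_alignment] with one row per tip.
#' @examples
#' t <- ape::read.tree(text = "((A:0.5,B:0.5):0.5,C:1);")
#' simulate_alignment(t, locus_length = 50, mutation_scale = 0.1, seed = 1)
#' @export
simulate_alignment <- function(tree, locus_length, mutation_scale, seed = 1L) {
  stopifnot(locus_length >= 1, mutation_scale >= 0)
  if (anyDuplicated(tree$tip.label)) {
    stop("gene tree tip labels must be unique", call. = FALSE)
  }
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    stop("gene tree must have non-negative branch lengths", call. = FALSE)
  }
  set.seed(seed)
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  tr <- ape::reorder.phylo(tree, "cladewise")   # edges in preorder
  seqs <- matrix(0L, nnode, locus_length)
  root <- ntip + 1L
  seqs[root, ] <- sample.int(4L, locus_length, replace = TRUE)
  p_change <- 0.75 * (1 - exp(-4 * tr$edge.length * mutation_scale / 3))
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1L]
    child <- tr$edge[e, 2L]
    s <- seqs[par, ]
    if (p_change[e] > 0) {
      hit <- runif(locus_length) < p_change[e]
      nh <- sum(hit)
      if (nh > 0L) {
        # uniform over the three other bases
        s[hit] <- ((s[hit] - 1L + sample.int(3L, nh, replace = TRUE)) %% 4L) + 1L
      }
    }
    seqs[child, ] <- s
  }
  m <- matrix(c("A", "C", "G", "T")[seqs[seq_len(ntip), , drop = FALSE]],
              ntip, locus_length)
  rownames(m) <- tr$tip.label
  new_multi_alignment(m)
}

#' Evolve alignments for a set of simulated gene trees
#'
#' Convenience wrapper mapping [simulate_alignment()] over the `tree`
#' list-column produced by [simulate_gene_trees()], with per-locus seeds split
#' from the master seed.
#'
#' @param gene_trees A tibble with columns `locus` and `tree`, as returned by
#'   [simulate_gene_trees()].
#' @inheritParams simulate_alignment
#' @return The input tibble with an added `alignment` list-column.
#' @export
simulate_alignments <- function(gene_trees, locus_length, mutation_scale,
                                seed = 1L) {
  stopifnot(all(c("locus", "tree") %in% names(gene_trees)))
  gene_trees %>%
    mutate(alignment = map2(.data$tree, .data$locus, function(tr, loc) {
      simulate_alignment(tr, locus_length, mutation_scale,
                         seed = locus_seed(seed + 7L, loc))
    }))
}

#' Simulate a pan-gene presence/absence matrix with known categories
#'
#' Each cluster is assigned a true category so that the realized composition
#' matches `proportions` as closely as integer counts allow (largest-remainder
#' apportionment), then an occupancy is drawn uniformly from the category's
#' band (core: all `n` accessions; soft-core: `soft_core_min` to `n - 1`;
#' shell: 2 to `soft_core_min - 1`; specific: exactly 1) and the present
#' accessions are chosen uniformly at random.
#'
#' @param n_accessions Number of accessions (columns); must be at least 5 so
#'   the occupancy bands are non-degenerate.
#' @param n_clusters Number of pan-gene clusters (rows).
#' @param proportions Numeric length-4 vector `(core, soft_core, shell,
#'   specific)` summing to 1.
#' @param seed Integer seed.
#' @param soft_core_min Lower edge of the soft-core occupancy band; defaults
#'   to `ceiling(0.933 * n_accessions)`, capped at `n_accessions - 1` so the
#'   band is never empty (42 of 45).
#' @return A list with `matrix` (clusters x accessions 0/1 integer matrix) and
#'   `truth` (tibble of `cluster`, `category`, `occupancy`).
#' @export
simulate_presence_absence <- function(n_accessions, n_clusters,
                                      proportions, seed = 1L,
                                      soft_core_min =
                                        min(ceiling(0.933 * n_accessions),
                                            n_accessions - 1)) {
  if (n_accessions < 5L) {
    stop("need at least 5 accessions: occupancy bands are degenerate below ",
         "that", call. = FALSE)
  }
  stopifnot(length(proportions) == 4L, all(proportions >= 0))
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("proportions must sum to 1", call. = FALSE)
  }
  n <- n_accessions
  if (soft_core_min > n - 1L && proportions[2L] > 0) {
    stop("soft-core band is empty for n = ", n, call. = FALSE)
  }
  set.seed(seed)
  cats <- c("core", "soft_core", "shell", "specific")
  base <- floor(proportions * n_clusters)
  rem <- proportions * n_clusters - base
  short <- n_clusters - sum(base)
  if (short > 0L) base[order(rem, decreasing = TRUE)[seq_len(short)]] <-
      base[order(rem, decreasing = TRUE)[seq_len(short)]] + 1L
  category <- sample(rep(cats, times = base))

  occ_of <- function(cat) {
    switch(cat,
           core = n,
           soft_core = if (soft_core_min == n - 1L) n - 1L else
             sample(soft_core_min:(n - 1L), 1L),
           shell = if (soft_core_min - 1L == 2L) 2L else
             sample(2:(soft_core_min - 1L), 1L),
           specific = 1L)
  }
  occupancy <- map_int(category, function(cat) as.integer(occ_of(cat)))
  m <- matrix(0L, n_clusters, n,
              dimnames = list(sprintf("cluster_%05d", seq_len(n_clusters)),
                              sprintf("acc_%03d", seq_len(n))))
  for (i in seq_len(n_clusters)) {
    m[i, sample.int(n, occupancy[i])] <- 1L
  }
  list(matrix = m,
       truth = tibble(cluster = rownames(m),
                      category = factor(category, levels = cats),
                      occupancy = occupancy))
}
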