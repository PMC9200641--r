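# pairing key for four species given a tree-metric distance matrix.
# Returns "a,b|c,d" (sorted within and between pairs) or NA for ties
# (an unresolved induced quartet).
quartet_split <- function(d, four) {
  s1 <- d[four[1L], four[2L]] + d[four[3L], four[4L]]  # 12|34
  s2 <- d[four[1L], four[3L]] + d[four[2L], four[4L]]  # 13|24
  s3 <- d[four[1L], four[4L]] + d[four[2L], four[3L]]  # 14|23
  sums <- c(s1, s2, s3)
  lo <- which(sums < min(sums) + 1e-12)
  if (length(lo) != 1L) return(NA_character_)
  pairs <- switch(lo,
                  list(four[c(1L, 2L)], four[c(3L, 4L)]),
                  list(four[c(1L, 3L)], four[c(2L, 4L)]),
                  list(four[c(1L, 4L)], four[c(2L, 3L)]))
  pairs <- lapply(pairs, sort)
  pairs <- pairs[order(vapply(pairs, `[`, character(1L), 1L))]
  paste(vapply(pairs, paste, character(1L), collapse = ","),
        collapse = "|")
}

# all three topology keys for a sorted 4-species subset
quartet_topologies <- function(four) {
  four <- sort(four)
  key <- function(p1, p2) {
    pairs <- list(sort(p1), sort(p2))
    pairs <- pairs[order(vapply(pairs, `[`, character(1L), 1L))]
    paste(vapply(pairs, paste, character(1L), collapse = ","),
          collapse = "|")
  }
  c(key(four[c(1L, 2L)], four[c(3L, 4L)]),
    key(four[c(1L, 3L)], four[c(2L, 4L)]),
    key(four[c(1L, 4L)], four[c(2L, 3L)]))
}

#' Quartet-topology frequencies across a set of gene trees
#'
#' For every 4-species subset of `species`, tallies each tree's induced
#' unrooted quartet topology (via the four-point condition on the tree
#' metric). Trees missing a species are skipped for subsets involving it;
#' induced hard polytomies are tallied as unresolved and excluded from the
#' per-subset normalization.
#'
#' @param trees A list of `phylo`, a `multiPhylo`, or a tibble with a `tree`
#'   list-column (as from [simulate_gene_trees()]).
#' @param species Species to analyse; defaults to the tip labels of the
#'   first tree.
#' @return A tibble with columns `subset` (comma-joined sorted species),
#'   `topology` (`"a,b|c,d"`), `count`, `n_resolved` and `freq`; three rows
#'   per subset.
#' @export
quartet_frequencies <- function(trees, species = NULL) {
  if (is.data.frame(trees)) trees <- trees$tree
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  stopifnot(length(trees) >= 1L)
  if (is.null(species)) species <- trees[[1L]]$tip.label
  if (length(species) < 4L) stop("need at least 4 species", call. = FALSE)
  subsets <- combn(sort(species), 4L, simplify = FALSE)
  keys <- lapply(subsets, quartet_topologies)
  tally <- lapply(seq_along(subsets), function(i) {
    setNames(numeric(3L), keys[[i]])
  })
  n_skipped <- 0L
  for (tr in trees) {
    if (is.null(tr$edge.length)) tr$edge.length <- rep(1, nrow(tr$edge))
    d <- ape::cophenetic.phylo(tr)
    for (i in seq_along(subsets)) {
      four <- subsets[[i]]
      if (!all(four %in% rownames(d))) {
        n_skipped <- n_skipped + 1L
        next
      }
      key <- quartet_split(d, four)
      if (!is.na(key)) tally[[i]][key] <- tally[[i]][key] + 1
    }
  }
  if (n_skipped > 0L) {
    message(n_skipped, " tree/subset combination(s) skipped for missing ",
            "species")
  }
  map_dfr(seq_along(subsets), function(i) {
    counts <- tally[[i]]
    tibble(subset = paste(subsets[[i]], collapse = ","),
           topology = names(counts),
           count = as.numeric(counts),
           n_resolved = sum(counts),
           freq = if (sum(counts) > 0) counts / sum(counts) else
             rep(NA_real_, 3L))
  })
}

#' Compare observed and simulated quartet frequencies
#'
#' Pairs two [quartet_frequencies()] tables by subset and topology and
#' computes the Pearson correlation of their frequencies.
#'
#' @param obs,sim Quartet-frequency tibbles with matching subset/topology
#'   keys.
#' @return An object of class `quartet_comparison`: list with `r` and the
#'   `paired` tibble (`subset`, `topology`, `freq_obs`, `freq_sim`).
#' @export
compare_frequencies <- function(obs, sim) {
  paired <- inner_join(
    obs %>% select("subset", "topology", freq_obs = "freq"),
    sim %>% select("subset", "topology", freq_sim = "freq"),
    by = c("subset", "topology")
  ) %>%
    filter(!is.na(.data$freq_obs), !is.na(.data$freq_sim))
  if (nrow(paired) < 3L) {
    stop("need at least 3 paired frequencies", call. = FALSE)
  }
  structure(list(r = cor(paired$freq_obs, paired$freq_sim), paired = paired),
            class = "quartet_comparison")
}

#' @export
print.quartet_comparison <- function(x, ...) {
  cat("<quartet_comparison> ", nrow(x$paired), " paired frequencies, ",
      "Pearson r = ", signif(x$r, 5), "\n", sep = "")
  invisible(x)
}

# internal-branch table keyed by the (sorted) tip set of the child clade
internal_branch_table <- function(tree) {
  ntip <- ape::Ntip(tree)
  internal_children <- tree$edge[, 2L] > ntip
  idx <- which(internal_children)
  tibble(
    clade = vapply(tree$edge[idx, 2L], function(v) {
      paste(sort(node_tips(tree, v)), collapse = ",")
    }, character(1L)),
    length = tree$edge.length[idx]
  )
}

#' Per-branch theta from matched mutation- and coalescent-unit trees
#'
#' Given the same rooted topology measured twice (branch lengths in expected
#' substitutions per site, e.g. from a concatenated ML tree, and in
#' coalescent units, e.g. from a summary species-tree method), theta for each
#' internal branch is mutation-unit length divided by coalescent-unit length.
#'
#' @param tree_mutation_units,tree_coalescent_units Two rooted `phylo`
#'   objects with identical topologies.
#' @return A tibble with `clade` (sorted tip set below the branch),
#'   `mutation_units`, `coalescent_units` and `theta` (`NA` with a flag
#'   column `undefined` when the coalescent length is zero).
#' @export
estimate_theta <- function(tree_mutation_units, tree_coalescent_units) {
  if (canonical_topology(tree_mutation_units) !=
      canonical_topology(tree_coalescent_units)) {
    stop("trees have different topologies", call. = FALSE)
  }
  mt <- internal_branch_table(tree_mutation_units) %>%
    rename(mutation_units = "length")
  ct <- internal_branch_table(tree_coalescent_units) %>%
    rename(coalescent_units = "length")
  inner_join(mt, ct, by = "clade") %>%
    mutate(undefined = .data$coalescent_units == 0,
           theta = ifelse(.data$undefined, NA_real_,
                          .data$mutation_units / .data$coalescent_units))
}
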