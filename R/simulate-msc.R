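#' Describe a single pulse of introgression
#'
#' An introgression scenario moves gene lineages found in the recipient
#' species-tree branch at time `t_m` (coalescent units before present) into
#' the donor branch, independently per lineage with probability `gamma`.
#' Under this pulse model the f4-ratio has expectation `gamma`.
#'
#' @param donor,recipient Species-tree branch labels (tip labels, or node
#'   labels for internal branches). A branch is named by the node below it.
#' @param t_m Pulse time in coalescent units before present. Must fall
#'   strictly inside both the donor and the recipient branch intervals.
#' @param gamma Admixture fraction in `[0, 1]`.
#' @return A list of class `introgression_scenario`.
#' @export
introgression_scenario <- function(donor, recipient, t_m, gamma) {
  stopifnot(is.character(donor), is.character(recipient),
            length(donor) == 1L, length(recipient) == 1L)
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]", call. = FALSE)
  if (t_m < 0) stop("t_m must be non-negative", call. = FALSE)
  if (donor == recipient) stop("donor and recipient must differ", call. = FALSE)
  structure(list(donor = donor, recipient = recipient, t_m = t_m,
                 gamma = gamma),
            class = "introgression_scenario")
}

# --- species-tree bookkeeping -----------------------------------------------

# node ages (time before present) for an ultrametric rooted tree;
# tips are at age 0
sp_tree_ages <- function(tree) {
  if (is.null(tree$edge.length)) {
    stop("species tree must carry branch lengths (coalescent units)",
         call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("species tree has negative branch lengths", call. = FALSE)
  }
  depth <- ape::node.depth.edgelength(tree)  # distance from the root
  h <- max(depth)
  tip_depth <- depth[seq_len(ape::Ntip(tree))]
  if (max(tip_depth) - min(tip_depth) > 1e-6 * max(h, 1)) {
    stop("species tree must be ultrametric (equal root-to-tip path lengths)",
         call. = FALSE)
  }
  h - depth
}

# resolve a branch label (tip label or internal node label) to a node id
sp_node_id <- function(tree, label) {
  id <- match(label, tree$tip.label)
  if (!is.na(id)) return(id)
  if (!is.null(tree$node.label)) {
    id <- match(label, tree$node.label)
    if (!is.na(id)) return(id + ape::Ntip(tree))
  }
  stop("branch label '", label, "' not found in the species tree",
       call. = FALSE)
}

# deterministic per-locus seed derived from the master seed, so earlier loci
# are unchanged when n_loci grows
locus_seed <- function(seed, locus) {
  as.integer((as.numeric(seed) * 97 + as.numeric(locus) * 100003) %% 2147483629)
}

# --- multispecies coalescent ------------------------------------------------

#' Simulate gene trees under the multispecies coalescent
#'
#' Draws independent gene trees from a rooted, ultrametric species tree whose
#' branch lengths are in coalescent units (2N generations). Within each
#' species-tree branch, the `k` lineages present coalesce with exponential
#' waiting times at rate `k(k-1)/2`; lineages that fail to coalesce are handed
#' to the parent branch, and the process completes in the ancestral population
#' above the root. An optional [introgression_scenario()] relocates recipient
#' lineages to the donor branch at the pulse time with probability `gamma`,
#' independently per locus and per lineage.
#'
#' Under this model a species-tree internal branch of length `t` yields the
#' concordant quartet topology with probability `1 - (2/3) exp(-t)` and each
#' discordant topology with probability `(1/3) exp(-t)`.
#'
#' @param species_tree A rooted ultrametric `phylo` with coalescent-unit
#'   branch lengths.
#' @param n_loci Number of gene trees to draw.
#' @param samples_per_species Haploid samples per species (default 1). With
#'   more than one sample, tips are labelled `<species>_<k>`.
#' @param scenario Optional [introgression_scenario()].
#' @param seed Master integer seed. Per-locus streams are split from it, so
#'   increasing `n_loci` does not perturb earlier loci.
#' @return A tibble with columns `locus`, `introgressed` (did any lineage
#'   relocate at this locus), and `tree` (list-column of ultrametric `phylo`
#'   gene trees with coalescent-unit branch lengths).
#' @examples
#' sp <- ape::read.tree(text = "((A:1,B:1):0.5,C:1.5);")
#' sim <- simulate_gene_trees(sp, n_loci = 10, seed = 1)
#' sim$tree[[1]]
#' @export
simulate_gene_trees <- function(species_tree, n_loci,
                                samples_per_species = 1L,
                                scenario = NULL, seed = 1L) {
  stopifnot(n_loci >= 1, samples_per_species >= 1)
  tree <- species_tree
  ntip <- ape::Ntip(tree)
  ages <- sp_tree_ages(tree)
  root <- ntip + 1L
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  parent[root] <- 0L

  pulse <- NULL
  if (!is.null(scenario)) {
    don <- sp_node_id(tree, scenario$donor)
    rec <- sp_node_id(tree, scenario$recipient)
    t_m <- scenario$t_m
    span_ok <- function(v) {
      top <- if (v == root) Inf else ages[parent[v]]
      t_m > ages[v] && t_m < top
    }
    if (!span_ok(don) || !span_ok(rec)) {
      stop("t_m = ", t_m, " does not fall inside both the donor and the ",
           "recipient branch intervals", call. = FALSE)
    }
    pulse <- list(donor = don, recipient = rec, t_m = t_m,
                  gamma = scenario$gamma)
  }

  # event schedule: speciation times (internal node ages) and the pulse,
  # in increasing age order
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  ev_time <- ages[internal]
  ev_node <- internal
  # ties in age (zero-length internal branches): children merge before
  # their parent, so order equal-age events by decreasing root distance
  depth_steps <- vapply(internal, function(v) {
    d <- 0L
    while (v != root) {
      v <- parent[v]
      d <- d + 1L
    }
    d
  }, integer(1L))
  o <- order(ev_time, -depth_steps)
  ev_time <- ev_time[o]
  ev_node <- ev_node[o]
  if (!is.null(pulse) && pulse$gamma > 0) {
    ins <- sum(ev_time <= pulse$t_m)
    ev_time <- append(ev_time, pulse$t_m, after = ins)
    ev_node <- append(ev_node, NA_integer_, after = ins)  # NA marks the pulse
  }
  children <- split(tree$edge[, 2L], tree$edge[, 1L])

  tip_names <- if (samples_per_species == 1L) tree$tip.label else
    as.vector(t(outer(tree$tip.label, seq_len(samples_per_species),
                      function(a, b) paste0(a, "_", b))))
  n_lin0 <- ntip * samples_per_species
  branch0 <- rep(seq_len(ntip), each = samples_per_species)

  newicks <- character(n_loci)
  introgressed <- logical(n_loci)

  for (locus in seq_len(n_loci)) {
    set.seed(locus_seed(seed, locus))
    lin_branch <- branch0
    lin_str <- tip_names
    lin_time <- numeric(n_lin0)
    moved <- FALSE
    t_cur <- 0

    coalesce_in <- function(b, t0, t1) {
      repeat {
        idx <- which(lin_branch == b)
        k <- length(idx)
        if (k < 2L) break
        t0 <- t0 + rexp(1L, k * (k - 1) / 2)
        if (t0 >= t1) break
        pair <- idx[sample.int(k, 2L)]
        i <- pair[1L]; j <- pair[2L]
        new_str <- paste0("(", lin_str[i], ":",
                          format(t0 - lin_time[i], digits = 10), ",",
                          lin_str[j], ":",
                          format(t0 - lin_time[j], digits = 10), ")")
        keep <- -pair
        lin_branch <<- c(lin_branch[keep], b)
        lin_str <<- c(lin_str[keep], new_str)
        lin_time <<- c(lin_time[keep], t0)
      }
      invisible(NULL)
    }

    for (e in seq_along(ev_time)) {
      t_ev <- ev_time[e]
      for (b in unique(lin_branch)) coalesce_in(b, t_cur, t_ev)
      if (is.na(ev_node[e])) {               # introgression pulse
        at_rec <- which(lin_branch == pulse$recipient)
        if (length(at_rec) > 0L) {
          go <- runif(length(at_rec)) < pulse$gamma
          if (any(go)) {
            lin_branch[at_rec[go]] <- pulse$donor
            moved <- TRUE
          }
        }
      } else {                               # speciation: merge child branches
        kids <- children[[as.character(ev_node[e])]]
        lin_branch[lin_branch %in% kids] <- ev_node[e]
      }
      t_cur <- t_ev
    }
    coalesce_in(root, t_cur, Inf)            # ancestral population

    newicks[locus] <- paste0(lin_str[1L], ";")
    introgressed[locus] <- moved
  }

  trees <- ape::read.tree(text = newicks)
  trees <- if (inherits(trees, "phylo")) list(trees) else unname(unclass(trees))
  tibble(locus = seq_len(n_loci), introgressed = introgressed,
         tree = trees)
}
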