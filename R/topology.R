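# tip labels descending from `node` (which may itself be a tip)
node_tips <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  unlist(lapply(kids, node_tips, tree = tree))
}

#' Canonical unrooted topology string
#'
#' Produces a branch-length-free newick string that is identical for all
#' trees sharing an unrooted topology: the tree is re-rooted on its
#' lexicographically smallest tip and child clades are sorted recursively.
#'
#' @param tree A `phylo`.
#' @return A single newick string.
#' @export
canonical_topology <- function(tree) {
  tr <- ape::unroot(tree)
  tr$edge.length <- NULL
  tr$node.label <- NULL
  anchor <- sort(tr$tip.label)[1L]
  tr <- ape::root(tr, outgroup = anchor, resolve.root = TRUE)
  ntip <- ape::Ntip(tr)
  canon <- function(node) {
    if (node <= ntip) return(tr$tip.label[node])
    kids <- tr$edge[tr$edge[, 1L] == node, 2L]
    paste0("(", paste(sort(vapply(kids, canon, character(1L)),
                           method = "radix"), collapse = ","), ")")
  }
  paste0(canon(ntip + 1L), ";")
}

#' Classify a window tree by the position of the focal clade
#'
#' Roots the tree on the `OUT` group and, when `PET`, `LYC` and `ETB` are
#' each monophyletic, names the sister of the `ETB` clade. Any monophyly or
#' rooting failure yields `"other"`.
#'
#' @param tree A `phylo`.
#' @param groups A `(taxon, group)` data frame or named vector with groups
#'   `PET`, `LYC`, `ETB`, `OUT`.
#' @return One of `"ETB_sister_to_PET"`, `"ETB_sister_to_LYC"`,
#'   `"ETB_sister_to_PET_LYC"`, `"other"`.
#' @export
classify_topology <- function(tree, groups) {
  gmap <- as_group_map(groups)
  sets <- lapply(c(PET = "PET", LYC = "LYC", ETB = "ETB", OUT = "OUT"),
                 function(g) intersect(names(gmap)[gmap == g],
                                       tree$tip.label))
  if (length(sets$OUT) == 0L) {
    stop("no OUT taxa present in the tree", call. = FALSE)
  }
  for (g in c("PET", "LYC", "ETB")) {
    if (length(sets[[g]]) == 0L) {
      stop("group '", g, "' has no taxa in the tree", call. = FALSE)
    }
  }
  rooted <- tryCatch(
    ape::root(ape::unroot(tree), outgroup = sets$OUT, resolve.root = TRUE),
    error = function(e) NULL)
  if (is.null(rooted)) return("other")
  mono <- vapply(c("PET", "LYC", "ETB"), function(g) {
    length(sets[[g]]) == 1L || ape::is.monophyletic(rooted, sets[[g]])
  }, logical(1L))
  if (!all(mono)) return("other")
  etb_node <- if (length(sets$ETB) == 1L) {
    match(sets$ETB, rooted$tip.label)
  } else {
    ape::getMRCA(rooted, sets$ETB)
  }
  parent <- rooted$edge[rooted$edge[, 2L] == etb_node, 1L]
  if (length(parent) != 1L) return("other")
  sister <- setdiff(node_tips(rooted, parent), sets$ETB)
  if (setequal(sister, sets$PET)) return("ETB_sister_to_PET")
  if (setequal(sister, sets$LYC)) return("ETB_sister_to_LYC")
  if (setequal(sister, union(sets$PET, sets$LYC))) {
    return("ETB_sister_to_PET_LYC")
  }
  "other"
}

#' Topology spectrum of retained windows
#'
#' Tallies canonical unrooted topologies over the retained (passed,
#' non-partial) windows and, when present, the `topology_class` assignments.
#'
#' @param records A window-record tibble (see [window_trees()]) with a `tree`
#'   list-column; logical columns `passed` and `partial` are honoured when
#'   present, otherwise every window with a tree is counted.
#' @return An object of class `topology_spectrum`: a list with `spectrum`
#'   (tibble of `topology`, `count`, `fraction`), `class_counts` (or `NULL`),
#'   `n_windows_total`, `n_windows_passed` and `n_distinct_topologies`.
#' @export
topology_spectrum <- function(records) {
  keep <- rep(TRUE, nrow(records))
  if ("passed" %in% names(records)) keep <- keep & records$passed
  if ("partial" %in% names(records)) keep <- keep & !records$partial
  keep <- keep & !map_lgl(records$tree, is.null)
  topo <- map_chr(records$tree[keep], canonical_topology)
  spectrum <- tibble(topology = topo) %>%
    count(.data$topology, name = "count") %>%
    arrange(dplyr::desc(.data$count)) %>%
    mutate(fraction = .data$count / sum(.data$count))
  class_counts <- NULL
  if ("topology_class" %in% names(records)) {
    class_counts <- tibble(topology_class = records$topology_class[keep]) %>%
      count(.data$topology_class, name = "n") %>%
      mutate(fraction = .data$n / sum(.data$n))
  }
  structure(list(spectrum = spectrum, class_counts = class_counts,
                 n_windows_total = nrow(records),
                 n_windows_passed = sum(keep),
                 n_distinct_topologies = nrow(spectrum)),
            class = "topology_spectrum")
}

#' @export
print.topology_spectrum <- function(x, ...) {
  cat("<topology_spectrum> ", x$n_windows_passed, " retained of ",
      x$n_windows_total, " windows; ", x$n_distinct_topologies,
      " distinct topologies\n", sep = "")
  if (!is.null(x$class_counts)) print(x$class_counts)
  invisible(x)
}
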