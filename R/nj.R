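# integer-coded copy of an alignment (A=1 .. T=4, NA where missing) for fast
# pairwise comparison; honours a precomputed cache in the `int` field
aln_as_int <- function(aln) {
  if (!is.null(aln$int)) return(aln$int)
  m <- matrix(match(aln$seq, c("A", "C", "G", "T")),
              nrow(aln$seq), ncol(aln$seq))
  rownames(m) <- rownames(aln$seq)
  m
}

#' Jukes-Cantor pairwise distance matrix
#'
#' Pairwise p-distances over sites where both taxa are called (pairwise
#' deletion of `N` and `-`), corrected as `d = -(3/4) log(1 - (4/3) p)`.
#' Saturated pairs (`p >= 0.75`) receive a large-distance sentinel with a
#' warning; a pair with no comparable sites is an error.
#'
#' @param aln A [multi_alignment] with at least 3 taxa.
#' @param saturated_sentinel Distance assigned to saturated pairs.
#' @return A symmetric numeric matrix with taxon dimnames.
#' @export
jc_distance_matrix <- function(aln, saturated_sentinel = 10) {
  if (n_taxa(aln) < 3L) stop("need at least 3 taxa", call. = FALSE)
  m <- aln_as_int(aln)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  saturated <- character()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(m[i, ]) & !is.na(m[j, ])
      nc <- sum(ok)
      if (nc == 0L) {
        stop("no comparable sites for pair (", rownames(m)[i], ", ",
             rownames(m)[j], ")", call. = FALSE)
      }
      p <- sum(m[i, ok] != m[j, ok]) / nc
      if (p >= 0.75) {
        d[i, j] <- d[j, i] <- saturated_sentinel
        saturated <- c(saturated,
                       paste0(rownames(m)[i], "-", rownames(m)[j]))
      } else {
        d[i, j] <- d[j, i] <- -0.75 * log(1 - 4 * p / 3)
      }
    }
  }
  if (length(saturated) > 0L) {
    warning("saturated pair(s) set to sentinel distance ",
            saturated_sentinel, ": ", paste(saturated, collapse = ", "))
  }
  d
}

#' Neighbor-joining tree with site-resampling bootstrap
#'
#' Canonical Saitou-Nei neighbor joining (via \pkg{ape}) on a distance
#' matrix, exact on additive distances. When `bootstrap > 0`, alignment
#' columns are resampled with replacement, distances and the NJ tree are
#' recomputed, and each internal branch's support is the percentage of
#' replicates containing that bipartition, stored in `node.label` (the root
#' entry is `NA`).
#'
#' @param dist Symmetric distance matrix with taxon dimnames.
#' @param aln The [multi_alignment] the distances came from; required when
#'   `bootstrap > 0`.
#' @param bootstrap Number of bootstrap replicates (0 = none).
#' @param seed Integer seed for resampling; fixed seed gives identical
#'   supports.
#' @return An unrooted `phylo`, with bootstrap percentages in `node.label`
#'   when requested.
#' @export
nj_tree <- function(dist, aln = NULL, bootstrap = 0L, seed = 1L) {
  if (nrow(dist) < 3L) stop("need at least 3 taxa", call. = FALSE)
  tree <- ape::nj(dist)
  if (bootstrap > 0L) {
    if (is.null(aln)) {
      stop("bootstrap requires the alignment for site resampling",
           call. = FALSE)
    }
    set.seed(seed)
    L <- n_sites(aln)
    reps <- vector("list", bootstrap)
    for (b in seq_len(bootstrap)) {
      cols <- sample.int(L, L, replace = TRUE)
      db <- suppressWarnings(jc_distance_matrix(aln_slice(aln, cols)))
      reps[[b]] <- ape::nj(db)
    }
    counts <- ape::prop.clades(tree, reps, rooted = FALSE)
    supports <- 100 * counts / bootstrap
    supports[1L] <- NA_real_  # root pseudo-clade of the unrooted tree
    tree$node.label <- supports
  }
  tree
}

#' Mean bootstrap support of a tree
#'
#' @param tree A `phylo` whose `node.label` holds bootstrap supports
#'   (non-numeric or missing labels are ignored).
#' @return Mean support, or `NA` when no numeric supports are present.
#' @export
mean_bootstrap <- function(tree) {
  if (is.null(tree$node.label)) return(NA_real_)
  v <- suppressWarnings(as.numeric(tree$node.label))
  if (all(is.na(v))) return(NA_real_)
  mean(v, na.rm = TRUE)
}
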