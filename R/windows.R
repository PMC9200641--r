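#' Window filtering configuration
#'
#' Holds the window size and the three retention filters applied to
#' per-window trees: fully aligned length above `min_aligned` bp, missing
#' rate below `max_missing`, and mean bootstrap support above
#' `min_mean_bootstrap`. All three are strict inequalities.
#'
#' @param window_size Window width in bp (default 100 kb).
#' @param min_aligned Minimum fully aligned length in bp (default 10 kb).
#'   A column counts as fully aligned when no retained taxon is missing.
#' @param max_missing Maximum missing-cell fraction (default 0.20). Gaps and
#'   `N` both count as missing; the denominator is all cells.
#' @param min_mean_bootstrap Minimum mean bootstrap support (default 80).
#' @return A list of class `window_filter_config`.
#' @export
window_filter_config <- function(window_size = 100000L, min_aligned = 10000L,
                                 max_missing = 0.20,
                                 min_mean_bootstrap = 80) {
  stopifnot(min_aligned > 0, min_aligned <= window_size,
            max_missing >= 0, max_missing <= 1)
  structure(list(window_size = as.integer(window_size),
                 min_aligned = as.integer(min_aligned),
                 max_missing = max_missing,
                 min_mean_bootstrap = min_mean_bootstrap),
            class = "window_filter_config")
}

#' Split a reference-anchored alignment into non-overlapping windows
#'
#' Windows tile the reference in consecutive `[k*w, (k+1)*w)` intervals.
#' A trailing (or leading) window shorter than `w` is retained and flagged
#' `partial`. Alignment columns are assumed to map one-to-one to reference
#' positions (reference-projected alignment).
#'
#' @param aln A [multi_alignment] with a `region`.
#' @param cfg A [window_filter_config()] (only `window_size` is used here).
#' @return A tibble with columns `chrom`, `start`, `end`, `partial` and an
#'   `alignment` list-column of per-window [multi_alignment] objects.
#' @export
split_windows <- function(aln, cfg = window_filter_config()) {
  if (is.null(aln$region)) {
    stop("alignment must carry a region to be windowed", call. = FALSE)
  }
  w <- cfg$window_size
  r <- aln$region
  if (r$end - r$start != n_sites(aln)) {
    stop("region width (", r$end - r$start, ") does not match the number of ",
         "alignment columns (", n_sites(aln), ")", call. = FALSE)
  }
  ks <- seq.int(r$start %/% w, (r$end - 1L) %/% w)
  out <- map_dfr(ks, function(k) {
    s <- max(k * w, r$start)
    e <- min((k + 1L) * w, r$end)
    cols <- seq.int(s - r$start + 1L, e - r$start)
    sub <- aln_slice(aln, cols, region = list(chrom = r$chrom, start = s,
                                              end = e))
    tibble(chrom = r$chrom, start = s, end = e, partial = (e - s) < w,
           alignment = list(sub))
  })
  out
}

#' Alignment-quality statistics for a window
#'
#' @param aln A [multi_alignment].
#' @return A one-row tibble with `aligned_length` (number of columns with no
#'   missing character in any taxon) and `missing_rate` (missing cells over
#'   all cells).
#' @export
window_stats <- function(aln) {
  miss <- aln_missing(aln)
  tibble(aligned_length = sum(colSums(miss) == 0L),
         missing_rate = mean(miss))
}

#' Apply the three window retention filters
#'
#' A window passes iff `aligned_length > min_aligned` AND
#' `missing_rate < max_missing` AND `mean_bootstrap > min_mean_bootstrap`,
#' each strictly. Windows at exactly a threshold fail.
#'
#' @param records A tibble with columns `aligned_length`, `missing_rate` and
#'   `mean_bootstrap` (NA mean bootstrap fails the bootstrap criterion).
#' @param cfg A [window_filter_config()].
#' @return `records` with added logical columns `pass_aligned`,
#'   `pass_missing`, `pass_bootstrap` and `passed`.
#' @export
filter_windows <- function(records, cfg = window_filter_config()) {
  records %>%
    mutate(
      pass_aligned = .data$aligned_length > cfg$min_aligned,
      pass_missing = .data$missing_rate < cfg$max_missing,
      pass_bootstrap = !is.na(.data$mean_bootstrap) &
        .data$mean_bootstrap > cfg$min_mean_bootstrap,
      passed = .data$pass_aligned & .data$pass_missing & .data$pass_bootstrap
    )
}

#' Windowed tree inference and discordance classification
#'
#' End-to-end per-window pipeline: split a reference-anchored alignment into
#' windows, compute alignment statistics, infer a neighbor-joining tree with
#' bootstrap support for every window that passes the alignment filters,
#' apply all three retention filters, and (optionally) classify each retained
#' window's topology with [classify_topology()].
#'
#' @param aln A [multi_alignment] with a `region`, or a tibble of windows as
#'   returned by [split_windows()].
#' @param cfg A [window_filter_config()].
#' @param groups Optional taxon grouping (`PET`, `LYC`, `ETB`, `OUT`) for
#'   topology classification.
#' @param bootstrap Bootstrap replicates for [nj_tree()].
#' @param seed Integer seed for the bootstrap resampling.
#' @return A window-record tibble: coordinates, `partial`, `aligned_length`,
#'   `missing_rate`, `tree` (list-column; `NULL` where not inferred),
#'   `mean_bootstrap`, per-filter diagnostics, `passed` and (when `groups` is
#'   given) `topology_class`.
#' @export
window_trees <- function(aln, cfg = window_filter_config(), groups = NULL,
                         bootstrap = 100L, seed = 1L) {
  wins <- if (inherits(aln, "multi_alignment")) split_windows(aln, cfg) else
    aln
  stats <- map_dfr(wins$alignment, window_stats)
  recs <- dplyr::bind_cols(wins, stats)
  infer <- recs$aligned_length > cfg$min_aligned &
    recs$missing_rate < cfg$max_missing & !recs$partial
  trees <- vector("list", nrow(recs))
  mean_bs <- rep(NA_real_, nrow(recs))
  for (i in which(infer)) {
    d <- jc_distance_matrix(recs$alignment[[i]])
    tr <- nj_tree(d, aln = recs$alignment[[i]], bootstrap = bootstrap,
                  seed = locus_seed(seed, i))
    trees[[i]] <- tr
    mean_bs[i] <- mean_bootstrap(tr)
  }
  recs$tree <- trees
  recs$mean_bootstrap <- mean_bs
  recs <- filter_windows(recs, cfg)
  if (!is.null(groups)) {
    recs$topology_class <- NA_character_
    for (i in which(recs$passed)) {
      recs$topology_class[i] <- classify_topology(recs$tree[[i]], groups)
    }
  }
  recs
}
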