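# per-site allele frequencies for an arbitrary set of groups, unpolarized.
# The tracked allele is arbitrary per site; every f4 product is invariant to
# the choice because swapping alleles flips the sign of both factors.
freq_unpolarized <- function(data, group_list) {
  if (inherits(data, "multi_alignment")) {
    mi <- aln_as_int(data)
    rows_of <- lapply(group_list, function(tx) match(tx, rownames(mi)))
    used_rows <- unique(unlist(rows_of))
    mask <- allele_mask(mi, used_rows)
    usable <- bitcount4[mask + 1L] == 2L
    # track the lowest-coded allele present; f4 is invariant to the choice
    track_code <- match(bitwAnd(mask, -mask), c(1L, 2L, 4L, 8L))
    freqs <- matrix(NA_real_, length(group_list), ncol(mi),
                    dimnames = list(names(group_list), NULL))
    for (g in names(group_list)) {
      rows <- rows_of[[g]]
      if (length(rows) == 1L) {
        v <- mi[rows, ]
        freqs[g, ] <- as.numeric(v == track_code)   # NA propagates
        usable <- usable & !is.na(v)
      } else {
        sub <- mi[rows, , drop = FALSE]
        called <- colSums(!is.na(sub))
        hits <- colSums(sub == rep(track_code, each = length(rows)),
                        na.rm = TRUE)
        freqs[g, ] <- hits / called                 # NaN where uncalled
        usable <- usable & called > 0L
      }
    }
    coords <- NULL
    if (!is.null(data$region)) {
      coords <- tibble(chrom = data$region$chrom,
                       start = data$region$start + seq_len(ncol(mi)) - 1L)
    }
    list(freqs = freqs, usable = usable, coords = coords, n_all = ncol(mi))
  } else {
    taxa <- unique(unlist(group_list))
    fm <- t(as.matrix(data[, taxa, drop = FALSE]))
    usable <- rep(TRUE, ncol(fm))
    freqs <- matrix(NA_real_, length(group_list), ncol(fm),
                    dimnames = list(names(group_list), NULL))
    for (g in names(group_list)) {
      rows <- group_list[[g]]
      sub <- fm[rows, , drop = FALSE]
      called <- colSums(!is.na(sub))
      freqs[g, ] <- ifelse(called > 0L, colMeans(sub, na.rm = TRUE), NA_real_)
      usable <- usable & called > 0L
    }
    list(freqs = freqs, usable = usable,
         coords = data[, c("chrom", "start")], n_all = nrow(data))
  }
}

# per-block sums of (pW - pX)(pY - pZ) for one ordered quartet
f4_block_sums <- function(data, gmap, quartet, blocks) {
  stopifnot(length(quartet) == 4L)
  avail <- if (inherits(data, "multi_alignment")) taxa_labels(data) else
    names(data)
  group_list <- lapply(setNames(quartet, quartet), function(lab) {
    group_taxa(gmap, lab, avail)
  })
  fr <- freq_unpolarized(data, group_list)
  term <- (fr$freqs[quartet[1L], ] - fr$freqs[quartet[2L], ]) *
    (fr$freqs[quartet[3L], ] - fr$freqs[quartet[4L], ])
  use <- fr$usable & !is.na(term)
  blk <- site_blocks(fr$n_all, blocks, fr$coords)
  use <- use & !is.na(blk)
  if (!any(use)) {
    stop("f4 is undefined: no usable sites for quartet (",
         paste(quartet, collapse = ", "), ")", call. = FALSE)
  }
  agg <- rowsum(term[use], group = blk[use])
  tibble(block = as.integer(rownames(agg)), sum_term = agg[, 1L],
         n_sites = as.integer(table(blk[use])))
}

jackknife_ratio <- function(num_sum, num_n, den_sum = NULL, den_n = NULL) {
  # delete-one over aligned blocks; plain f4 when den_* is NULL
  nb <- length(num_sum)
  est_of <- function(keep) {
    f4n <- sum(num_sum[keep]) / sum(num_n[keep])
    if (is.null(den_sum)) return(f4n)
    f4n / (sum(den_sum[keep]) / sum(den_n[keep]))
  }
  total <- est_of(seq_len(nb))
  if (nb < 2L) {
    return(list(estimate = total, se = NA_real_, z = NA_real_, n_blocks = nb))
  }
  loo <- vapply(seq_len(nb), function(i) est_of(setdiff(seq_len(nb), i)),
                numeric(1L))
  se <- sqrt((nb - 1) / nb * sum((loo - mean(loo))^2))
  z <- if (se > 0) total / se else if (total == 0) 0 else NA_real_
  list(estimate = total, se = se, z = z, n_blocks = nb)
}

#' Four-population f4 statistic
#'
#' `f4(W, X; Y, Z)` is the mean over usable sites of
#' `(pW - pX)(pY - pZ)`, where `p` are per-group allele frequencies of a
#' consistently tracked allele. A block jackknife supplies the standard error
#' when at least two blocks are available.
#'
#' @inheritParams count_site_patterns
#' @param quartet Ordered character vector of four group labels `(W, X, Y, Z)`.
#' @return An object of class `f4_result` with elements `f4`, `se`, `z`,
#'   `n_blocks`, `quartet` and the `per_block` sums tibble.
#' @export
f4 <- function(data, groups, quartet, blocks = NULL) {
  gmap <- as_group_map(groups)
  if (inherits(data, "multi_alignment")) data$int <- aln_as_int(data)
  pb <- f4_block_sums(data, gmap, quartet, blocks)
  jk <- jackknife_ratio(pb$sum_term, pb$n_sites)
  structure(list(f4 = jk$estimate, se = jk$se, z = jk$z,
                 n_blocks = jk$n_blocks, quartet = quartet, per_block = pb,
                 alpha = NULL),
            class = "f4_result")
}

#' f4-ratio estimate of an admixture fraction
#'
#' `alpha = f4(numerator) / f4(denominator)`, with a delete-one block
#' jackknife for the standard error of the ratio. The denominator must be
#' significantly non-zero (`|Z| > z_threshold` by its own jackknife).
#'
#' Under the package's pulse-introgression model on a species tree
#' `((((B,X),A),C),O)` with donor `C` and recipient `X`, the configuration
#' `numerator = c("A","O","X","B")`, `denominator = c("A","O","C","B")` has
#' expectation `gamma`, the donor ancestry fraction of `X`.
#'
#' @inheritParams f4
#' @param numerator_quartet,denominator_quartet Ordered quartets of group
#'   labels for the two f4 statistics.
#' @param z_threshold Required `|Z|` of the denominator f4 (default 3).
#' @return An `f4_result` whose `alpha`, `se`, `z` describe the ratio;
#'   `f4_num` and `f4_den` hold the two component statistics.
#' @export
f4_ratio <- function(data, groups, numerator_quartet, denominator_quartet,
                     blocks = NULL, z_threshold = 3) {
  gmap <- as_group_map(groups)
  if (inherits(data, "multi_alignment")) data$int <- aln_as_int(data)
  pbn <- f4_block_sums(data, gmap, numerator_quartet, blocks)
  pbd <- f4_block_sums(data, gmap, denominator_quartet, blocks)
  common <- intersect(pbn$block, pbd$block)
  pbn <- pbn[match(common, pbn$block), ]
  pbd <- pbd[match(common, pbd$block), ]
  den <- jackknife_ratio(pbd$sum_term, pbd$n_sites)
  if (den$estimate == 0) {
    stop("f4-ratio is undefined: denominator f4 is zero", call. = FALSE)
  }
  if (!is.na(den$z) && abs(den$z) < z_threshold) {
    stop("f4-ratio is undefined: denominator f4 not significantly non-zero ",
         "(|Z| = ", signif(abs(den$z), 4), " < ", z_threshold, ")",
         call. = FALSE)
  }
  jk <- jackknife_ratio(pbn$sum_term, pbn$n_sites, pbd$sum_term, pbd$n_sites)
  structure(list(alpha = jk$estimate, se = jk$se, z = jk$z,
                 n_blocks = jk$n_blocks,
                 numerator_quartet = numerator_quartet,
                 denominator_quartet = denominator_quartet,
                 f4_num = sum(pbn$sum_term) / sum(pbn$n_sites),
                 f4_den = den$estimate, f4 = NULL),
            class = "f4_result")
}

#' @export
print.f4_result <- function(x, ...) {
  if (is.null(x$alpha)) {
    cat("<f4(", paste(x$quartet, collapse = ","), ")>\n", sep = "")
    cat("  f4 = ", signif(x$f4, 5), ", SE = ", signif(x$se, 5), ", Z = ",
        signif(x$z, 5), ", blocks = ", x$n_blocks, "\n", sep = "")
  } else {
    cat("<f4-ratio ", paste(x$numerator_quartet, collapse = ","), " / ",
        paste(x$denominator_quartet, collapse = ","), ">\n", sep = "")
    cat("  alpha = ", signif(x$alpha, 5), ", SE = ", signif(x$se, 5),
        ", blocks = ", x$n_blocks, "\n", sep = "")
  }
  invisible(x)
}
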