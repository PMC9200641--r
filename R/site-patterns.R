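pattern_cols <- c("BAAA", "ABAA", "AABA", "BBAA", "ABBA", "BABA")

# normalize a taxon->group mapping into a named character vector taxon->group
as_group_map <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("taxon", "group") %in% names(groups)))
    setNames(as.character(groups$group), groups$taxon)
  } else if (!is.null(names(groups))) {
    setNames(as.character(groups), names(groups))
  } else {
    stop("groups must be a (taxon, group) data frame or named vector",
         call. = FALSE)
  }
}

# taxa (names) belonging to `label`, with a config error when empty
group_taxa <- function(gmap, label, available) {
  taxa <- names(gmap)[gmap == label]
  if (length(taxa) == 0L) {
    stop("group '", label, "' has no taxa", call. = FALSE)
  }
  absent <- setdiff(taxa, available)
  if (length(absent) > 0L) {
    stop("taxa not present in the data: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  taxa
}

# per-site allele-presence bitmask (A=1, C=2, G=4, T=8) over a set of rows
# of an integer-coded alignment; 0 where every row is missing
allele_mask <- function(mi, rows) {
  mask <- integer(ncol(mi))
  pow <- c(1L, 2L, 4L, 8L)
  for (r in rows) {
    v <- mi[r, ]
    ok <- !is.na(v)
    mask[ok] <- bitwOr(mask[ok], pow[v[ok]])
  }
  mask
}

bitcount4 <- c(0L, 1L, 1L, 2L, 1L, 2L, 2L, 3L, 1L, 2L, 2L, 3L, 2L, 3L, 3L, 4L)

# per-site derived-allele frequency matrix (groups x sites) plus usability.
# Sites are usable when the outgroup is monomorphic and non-missing, the
# site is biallelic across all used taxa, and every group has at least one
# called allele.
freq_by_group_aln <- function(aln, group_list, out_label = "O") {
  mi <- aln_as_int(aln)
  rows_of <- lapply(group_list, function(tx) match(tx, rownames(mi)))
  used_rows <- unique(unlist(rows_of))
  n_alleles <- bitcount4[allele_mask(mi, used_rows) + 1L]
  mask_o <- allele_mask(mi, rows_of[[out_label]])
  out_mono <- mask_o %in% c(1L, 2L, 4L, 8L)
  anc_code <- match(mask_o, c(1L, 2L, 4L, 8L))     # NA unless monomorphic

  usable <- out_mono & n_alleles == 2L
  freqs <- matrix(NA_real_, length(group_list), ncol(mi),
                  dimnames = list(names(group_list), NULL))
  for (g in names(group_list)) {
    rows <- rows_of[[g]]
    if (length(rows) == 1L) {
      v <- mi[rows, ]
      freqs[g, ] <- as.numeric(v != anc_code)     # NA propagates
      usable <- usable & !is.na(v)
    } else {
      sub <- mi[rows, , drop = FALSE]
      called <- colSums(!is.na(sub))
      derived <- colSums(sub != rep(anc_code, each = length(rows)),
                         na.rm = TRUE)
      freqs[g, ] <- derived / called              # NaN where uncalled
      usable <- usable & called > 0L
    }
  }
  list(freqs = freqs, usable = usable)
}

# derived-allele frequencies from a SNP-table tibble (read_snp_table output)
freq_by_group_snp <- function(snp, group_list, out_label = "O") {
  taxa <- unique(unlist(group_list))
  fm <- t(as.matrix(snp[, taxa, drop = FALSE]))  # taxa x sites, ALT freq
  og <- group_list[[out_label]]
  fo <- fm[og, , drop = FALSE]
  all0 <- colSums(fo == 0, na.rm = TRUE) == colSums(!is.na(fo)) &
    colSums(!is.na(fo)) > 0
  all1 <- colSums(fo == 1, na.rm = TRUE) == colSums(!is.na(fo)) &
    colSums(!is.na(fo)) > 0
  usable <- all0 | all1
  # derived allele is ALT when the outgroup is fixed REF, and vice versa
  dm <- fm
  dm[, all1] <- 1 - fm[, all1]
  freqs <- matrix(NA_real_, length(group_list), ncol(fm),
                  dimnames = list(names(group_list), NULL))
  for (g in names(group_list)) {
    rows <- group_list[[g]]
    sub <- dm[rows, , drop = FALSE]
    called <- colSums(!is.na(sub))
    freqs[g, ] <- ifelse(called > 0L, colMeans(sub, na.rm = TRUE), NA_real_)
    usable <- usable & called > 0L
  }
  list(freqs = freqs, usable = usable)
}

# assign every site to a jackknife block: either a BED tibble (needs site
# reference coordinates) or an integer giving equal-count contiguous blocks
site_blocks <- function(n_sites, blocks, coords = NULL) {
  if (is.null(blocks)) return(rep(1L, n_sites))
  if (is.data.frame(blocks)) {
    if (is.null(coords)) {
      stop("BED blocks need reference coordinates (alignment region or SNP ",
           "positions)", call. = FALSE)
    }
    id <- rep(NA_integer_, n_sites)
    for (b in seq_len(nrow(blocks))) {
      hit <- coords$chrom == blocks$chrom[b] &
        coords$start >= blocks$start[b] & coords$start < blocks$end[b]
      id[hit] <- b
    }
    id
  } else {
    as.integer(cut(seq_len(n_sites), breaks = blocks, labels = FALSE))
  }
}

#' Count polarized biallelic site patterns
#'
#' Counts the six polarized site patterns (BAAA, ABAA, AABA, BBAA, ABBA,
#' BABA) for a four-group arrangement `(P1, P2, P3, O)`. The outgroup
#' consensus allele is taken as ancestral ("A"); sites where the outgroup is
#' polymorphic or entirely missing, sites that are not biallelic, and sites
#' where any group lacks data are skipped. Per-group derived-allele
#' frequencies `p1, p2, p3` increment the accumulators by frequency products
#' (e.g. `ABBA += (1 - p1) p2 p3`); with one haploid sample per group this
#' reduces to integer pattern counting.
#'
#' @param data A [multi_alignment], or a SNP-table tibble from
#'   [read_snp_table()].
#' @param groups A `(taxon, group)` data frame or named `taxon -> group`
#'   vector using the labels `P1`, `P2`, `P3`, `O`.
#' @param blocks Optional jackknife blocking: a 3-column BED tibble (requires
#'   reference coordinates) or an integer number of equal-count contiguous
#'   blocks. `NULL` pools everything into one block.
#' @param weighted If `FALSE`, only sites where every group is fixed
#'   (frequency 0 or 1) are counted, i.e. strict integer pattern counting.
#' @return A tibble with one row per block: `block`, the six pattern columns,
#'   and `n_sites_used`.
#' @examples
#' aln <- multi_alignment(c(P1 = "GAG", P2 = "AGA", P3 = "AGG", O = "AAA"))
#' count_site_patterns(aln, c(P1 = "P1", P2 = "P2", P3 = "P3", O = "O"))
#' @export
count_site_patterns <- function(data, groups, blocks = NULL, weighted = TRUE) {
  gmap <- as_group_map(groups)
  labels <- c("P1", "P2", "P3", "O")
  missing_lab <- setdiff(labels, unique(gmap))
  if (length(missing_lab) > 0L) {
    stop("groups must cover all of P1, P2, P3, O; missing: ",
         paste(missing_lab, collapse = ", "), call. = FALSE)
  }
  if (inherits(data, "multi_alignment")) {
    group_list <- lapply(setNames(labels, labels), function(lab) {
      group_taxa(gmap, lab, taxa_labels(data))
    })
    fr <- freq_by_group_aln(data, group_list)
    coords <- NULL
    if (!is.null(data$region)) {
      coords <- tibble(chrom = data$region$chrom,
                       start = data$region$start + seq_len(n_sites(data)) - 1L)
    }
    n_all <- n_sites(data)
  } else {
    group_list <- lapply(setNames(labels, labels), function(lab) {
      group_taxa(gmap, lab, names(data))
    })
    fr <- freq_by_group_snp(data, group_list)
    coords <- data[, c("chrom", "start")]
    n_all <- nrow(data)
  }
  p1 <- fr$freqs["P1", ]; p2 <- fr$freqs["P2", ]; p3 <- fr$freqs["P3", ]
  use <- fr$usable & !is.na(p1) & !is.na(p2) & !is.na(p3)
  # sites with no derived allele in P1..P3 are not segregating for the test
  use <- use & (p1 + p2 + p3) > 0
  if (!weighted) {
    fixed <- p1 %in% c(0, 1) & p2 %in% c(0, 1) & p3 %in% c(0, 1)
    use <- use & fixed
  }
  if (!any(use)) {
    warning("no usable sites; returning zero counts")
  }
  blk <- site_blocks(n_all, blocks, coords)
  use <- use & !is.na(blk)
  acc <- cbind(
    BAAA = (p1 * (1 - p2) * (1 - p3))[use],
    ABAA = ((1 - p1) * p2 * (1 - p3))[use],
    AABA = ((1 - p1) * (1 - p2) * p3)[use],
    BBAA = (p1 * p2 * (1 - p3))[use],
    ABBA = ((1 - p1) * p2 * p3)[use],
    BABA = (p1 * (1 - p2) * p3)[use]
  )
  blocks_present <- sort(unique(blk[!is.na(blk)]))
  if (length(blocks_present) == 0L) blocks_present <- 1L
  # zero rows for empty blocks keep the jackknife blocking stable
  sums <- matrix(0, length(blocks_present), 6L,
                 dimnames = list(NULL, pattern_cols))
  n_used <- integer(length(blocks_present))
  if (nrow(acc) > 0L) {
    agg <- rowsum(acc, group = blk[use])
    idx <- match(as.integer(rownames(agg)), blocks_present)
    sums[idx, ] <- agg
    n_used[idx] <- as.integer(table(factor(blk[use],
                                           levels = blocks_present)))
  }
  dplyr::bind_cols(tibble(block = blocks_present), as_tibble(sums),
                   tibble(n_sites_used = n_used))
}

pool_counts <- function(counts) {
  c(colSums(counts[, pattern_cols, drop = FALSE]),
    n_sites_used = sum(counts$n_sites_used))
}

#' ABBA-BABA D statistic from pooled site-pattern counts
#'
#' `D = (ABBA - BABA) / (ABBA + BABA)`; positive values indicate an excess of
#' derived-allele sharing between P2 and P3.
#'
#' @param counts A site-pattern tibble from [count_site_patterns()] (rows are
#'   pooled before computing D).
#' @return A single numeric value in `[-1, 1]`.
#' @export
d_statistic <- function(counts) {
  p <- pool_counts(counts)
  denom <- p[["ABBA"]] + p[["BABA"]]
  if (denom <= 0) {
    stop("D is undefined: ABBA + BABA = 0", call. = FALSE)
  }
  (p[["ABBA"]] - p[["BABA"]]) / denom
}

#' ABBA-BABA test in one call
#'
#' Counts site patterns with [count_site_patterns()] and returns the
#' D statistic with its block-jackknife standard error and Z score.
#'
#' @inheritParams count_site_patterns
#' @param blocks Jackknife blocking (default 20 equal-count contiguous
#'   blocks).
#' @return A `dstat_result`; see [block_jackknife()].
#' @export
abba_baba <- function(data, groups, blocks = 20L, weighted = TRUE) {
  counts <- count_site_patterns(data, groups, blocks = blocks,
                                weighted = weighted)
  block_jackknife(counts)
}

#' Per-block incomplete-lineage-sorting fraction
#'
#' For pooled polarized site-pattern counts, the ILS level is the count of the
#' two discordant patterns divided by a third of the weighted total of
#' segregating-site patterns:
#' `(ABBA + BABA) / ((BAAA + ABAA + AABA + 2 (BBAA + BABA + ABBA)) / 3)`.
#'
#' @inheritParams d_statistic
#' @return A single non-negative numeric value.
#' @export
ils_fraction <- function(counts) {
  p <- pool_counts(counts)
  denom <- (p[["BAAA"]] + p[["ABAA"]] + p[["AABA"]] +
              2 * (p[["BBAA"]] + p[["BABA"]] + p[["ABBA"]])) / 3
  if (denom <= 0) {
    stop("ILS fraction is undefined: no segregating-site patterns",
         call. = FALSE)
  }
  (p[["ABBA"]] + p[["BABA"]]) / denom
}

#' Per-block ILS profile and genome-wide ILS fraction
#'
#' Applies [ils_fraction()] to each block and reports the fraction of blocks
#' whose ILS value exceeds `cutoff`. The block-threshold rule is a pragmatic
#' summary, not a published convention; choose `cutoff` for the question at
#' hand.
#'
#' @param block_counts Site-pattern tibble with one row per block.
#' @param cutoff ILS value above which a block counts as ILS-affected.
#' @return A list with `per_block` (tibble of `block`, `ils`) and
#'   `genome_fraction_ils`.
#' @export
ils_profile <- function(block_counts, cutoff = 0.5) {
  per_block <- block_counts %>%
    group_by(.data$block) %>%
    dplyr::group_modify(function(d, key) {
      tibble(ils = tryCatch(ils_fraction(d), error = function(e) NA_real_))
    }) %>%
    ungroup()
  ok <- !is.na(per_block$ils)
  list(per_block = per_block,
       genome_fraction_ils = if (any(ok)) mean(per_block$ils[ok] > cutoff)
       else NA_real_)
}

#' Block-jackknife standard error and Z score for a counts statistic
#'
#' Delete-one jackknife over blocks: the statistic is recomputed on the pooled
#' counts of the remaining blocks for each deleted block, and
#' `SE^2 = ((n-1)/n) * sum((D_(-i) - mean(D_(-i)))^2)`, `Z = D_total / SE`.
#'
#' @param block_counts Site-pattern tibble with at least two non-empty blocks.
#' @param statistic Function mapping a counts tibble to a scalar (default
#'   [d_statistic()]).
#' @return An object of class `dstat_result` with elements `estimate`, `se`,
#'   `z`, `n_blocks`, `counts` (pooled one-row tibble) and `undefined_z`.
#' @export
block_jackknife <- function(block_counts, statistic = d_statistic) {
  nonempty <- block_counts$n_sites_used > 0
  bc <- block_counts[nonempty, , drop = FALSE]
  nb <- nrow(bc)
  if (nb < 2L) {
    stop("block jackknife needs at least 2 non-empty blocks", call. = FALSE)
  }
  total <- statistic(bc)
  loo <- vapply(seq_len(nb), function(i) statistic(bc[-i, , drop = FALSE]),
                numeric(1L))
  se <- sqrt((nb - 1) / nb * sum((loo - mean(loo))^2))
  undefined <- se == 0 && total != 0
  z <- if (se > 0) total / se else if (total == 0) 0 else NA_real_
  pooled <- bc %>%
    summarise(block = NA_integer_,
              dplyr::across(dplyr::all_of(pattern_cols), sum),
              n_sites_used = sum(.data$n_sites_used))
  structure(list(estimate = total, se = se, z = z, n_blocks = nb,
                 counts = pooled, undefined_z = undefined,
                 statistic_label = "D"),
            class = "dstat_result")
}

#' @export
print.dstat_result <- function(x, ...) {
  cat("<", x$statistic_label, " statistic, block jackknife>\n", sep = "")
  cat("  estimate = ", signif(x$estimate, 5), ", SE = ", signif(x$se, 5),
      ", Z = ", if (x$undefined_z) "undefined (SE = 0)" else signif(x$z, 5),
      ", blocks = ", x$n_blocks, "\n", sep = "")
  invisible(x)
}
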