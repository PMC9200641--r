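#' Multiple sequence alignment container
#'
#' A `multi_alignment` holds one aligned DNA sequence per taxon as a character
#' matrix (taxa in rows, alignment columns in columns) over the alphabet
#' `A, C, G, T, N, -`. Lowercase input is upper-cased and any other character
#' is mapped to `N`. An alignment may be anchored to reference coordinates via
#' `ref_taxon` and `region`; all coordinates in this package are 0-based,
#' half-open (BED convention).
#'
#' @param seqs Named character vector of equal-length DNA strings, or a
#'   character matrix with taxa as rownames (one character per cell).
#' @param ref_taxon Optional taxon label anchoring reference coordinates.
#' @param region Optional `list(chrom =, start =, end =)` giving the 0-based
#'   half-open reference interval the alignment covers.
#' @return An object of class `multi_alignment`.
#' @examples
#' aln <- multi_alignment(c(A = "ACGT", B = "ACGA"))
#' n_sites(aln)
#' @export
multi_alignment <- function(seqs, ref_taxon = NULL, region = NULL) {
  if (is.matrix(seqs)) {
    m <- seqs
    if (is.null(rownames(m))) {
      stop("alignment matrix must carry taxon labels as rownames",
           call. = FALSE)
    }
  } else {
    if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
      stop("sequences must be named by taxon", call. = FALSE)
    }
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      stop("alignment rows have unequal lengths: ",
           paste(unique(lens), collapse = ", "), call. = FALSE)
    }
    m <- do.call(rbind, strsplit(unname(as.character(seqs)), "", fixed = TRUE))
    if (is.null(m)) m <- matrix(character(), 0L, 0L)
    rownames(m) <- names(seqs)
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicate taxon labels: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "),
         call. = FALSE)
  }
  m[] <- toupper(m)
  m[!(m %in% c("A", "C", "G", "T", "N", "-"))] <- "N"
  if (!is.null(ref_taxon) && !(ref_taxon %in% rownames(m))) {
    stop("ref_taxon '", ref_taxon, "' is not an alignment row", call. = FALSE)
  }
  if (!is.null(region)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(region)))
    if (region$end - region$start < 1) {
      stop("region must span at least one base", call. = FALSE)
    }
  }
  structure(list(seq = m, ref_taxon = ref_taxon, region = region),
            class = "multi_alignment")
}

#' @export
print.multi_alignment <- function(x, ...) {
  cat("<multi_alignment> ", nrow(x$seq), " taxa x ", ncol(x$seq), " sites\n",
      sep = "")
  if (!is.null(x$region)) {
    cat("  region: ", x$region$chrom, ":", x$region$start, "-", x$region$end,
        " (0-based half-open)\n", sep = "")
  }
  cat("  taxa: ", paste(head(rownames(x$seq), 8L), collapse = ", "),
      if (nrow(x$seq) > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @rdname multi_alignment
#' @param x A `multi_alignment`.
#' @export
n_taxa <- function(x) nrow(x$seq)

#' @rdname multi_alignment
#' @export
n_sites <- function(x) ncol(x$seq)

#' @rdname multi_alignment
#' @export
taxa_labels <- function(x) rownames(x$seq)

# fast internal constructor: `m` must already be a clean upper-case
# character matrix over {A,C,G,T,N,-} with unique rownames
new_multi_alignment <- function(m, ref_taxon = NULL, region = NULL) {
  structure(list(seq = m, ref_taxon = ref_taxon, region = region),
            class = "multi_alignment")
}

#' Concatenate alignments column-wise
#'
#' Joins alignments over the same taxon set (rows are matched by label to the
#' first alignment's order). Useful for pooling many simulated loci before
#' site-pattern counting.
#'
#' @param alignments A list of [multi_alignment] objects, or a tibble with an
#'   `alignment` list-column.
#' @return A single [multi_alignment] without region anchoring.
#' @export
concat_alignments <- function(alignments) {
  if (is.data.frame(alignments)) alignments <- alignments$alignment
  stopifnot(length(alignments) >= 1L)
  taxa <- taxa_labels(alignments[[1L]])
  mats <- lapply(alignments, function(a) {
    if (!setequal(taxa_labels(a), taxa)) {
      stop("alignments have different taxon sets", call. = FALSE)
    }
    a$seq[taxa, , drop = FALSE]
  })
  new_multi_alignment(do.call(cbind, mats))
}

# logical matrix: TRUE where the cell is missing for statistics (N or gap)
aln_missing <- function(x) {
  m <- if (inherits(x, "multi_alignment")) x$seq else x
  m == "N" | m == "-"
}

# column subset preserving class; region trimmed to the matching ref interval
aln_slice <- function(x, cols, region = x$region) {
  new_multi_alignment(x$seq[, cols, drop = FALSE], ref_taxon = x$ref_taxon,
                      region = region)
}
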