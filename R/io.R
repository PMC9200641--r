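#' Read a multi-FASTA alignment
#'
#' Reads an aligned multi-FASTA file into a [multi_alignment]. Rows are
#' upper-cased and characters outside `A, C, G, T, -` become `N`. All records
#' must have equal length and unique labels.
#'
#' @param path Path to a FASTA file.
#' @param ref_taxon,region Passed to [multi_alignment()].
#' @return A [multi_alignment].
#' @export
read_alignment <- function(path, ref_taxon = NULL, region = NULL) {
  set <- Biostrings::readBStringSet(path)
  seqs <- setNames(as.character(set), names(set))
  # FASTA headers may carry descriptions after the first whitespace
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  multi_alignment(seqs, ref_taxon = ref_taxon, region = region)
}

#' Write a multi-FASTA alignment
#'
#' @param aln A [multi_alignment].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(aln$seq, 1L, paste, collapse = "")
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  invisible(path)
}

#' Read and write newick trees
#'
#' Thin wrappers around \pkg{ape} that fix the round-trip conventions used
#' throughout the package: `read_tree(write_tree(t))` reproduces topology,
#' branch lengths to 10 significant digits, and node (bootstrap) labels.
#'
#' @param path File path. Files may contain one tree or one tree per line.
#' @return `read_tree()` returns a single `phylo` for a one-tree file,
#'   otherwise a `multiPhylo` list; `write_tree()` returns `path` invisibly.
#' @export
read_tree <- function(path) {
  trees <- ape::read.tree(path)
  if (is.null(trees)) stop("no tree could be parsed from ", path, call. = FALSE)
  trees
}

#' @rdname read_tree
#' @param tree A `phylo` or `multiPhylo`.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' Read biallelic SNPs from a VCF
#'
#' Reads a VCF with GT fields into a tidy SNP table. Multiallelic records are
#' skipped (the number skipped is attached as attribute `n_skipped` and
#' reported via `message()`). Diploid genotypes are converted to per-taxon
#' derived(ALT)-allele frequencies 0, 0.5 or 1; missing genotypes become `NA`.
#' Positions are converted from the VCF's 1-based convention to the package's
#' 0-based half-open `start` on read.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF file.
#' @return A tibble with columns `chrom`, `start` (0-based), `ref`, `alt`,
#'   and one numeric frequency column per sample.
#' @export
read_snp_table <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  biallelic <- !is.na(fix$ALT) & !grepl(",", fix$ALT, fixed = TRUE) &
    !is.na(fix$REF) & nchar(fix$ALT) >= 1L
  n_skip <- sum(!biallelic)
  if (n_skip > 0L) {
    message(n_skip, " multiallelic or ALT-less record(s) skipped")
  }
  gt <- vcfR::extract.gt(v, element = "GT")[biallelic, , drop = FALSE]
  freq_of <- function(g) {
    g <- sub("|", "/", g, fixed = TRUE)
    out <- rep(NA_real_, length(g))
    out[g %in% c("0/0", "0")] <- 0
    out[g %in% c("0/1", "1/0")] <- 0.5
    out[g %in% c("1/1", "1")] <- 1
    out
  }
  freqs <- apply(gt, 2L, freq_of)
  if (is.null(dim(freqs))) freqs <- matrix(freqs, nrow = sum(biallelic),
                                           dimnames = list(NULL, colnames(gt)))
  out <- tibble(
    chrom = fix$CHROM[biallelic],
    start = as.integer(fix$POS[biallelic]) - 1L,
    ref = fix$REF[biallelic],
    alt = fix$ALT[biallelic]
  )
  out <- dplyr::bind_cols(out, as_tibble(freqs))
  bad <- out %>%
    group_by(.data$chrom) %>%
    summarise(ok = !is.unsorted(.data$start, strictly = TRUE)) %>%
    filter(!.data$ok)
  if (nrow(bad) > 0L) {
    stop("positions not strictly increasing on: ",
         paste(bad$chrom, collapse = ", "), call. = FALSE)
  }
  attr(out, "n_skipped") <- n_skip
  out
}

#' Read a presence/absence matrix
#'
#' Reads a TSV with a header row of accession names and a first column of
#' cluster identifiers. Cells must be numeric; counts greater than zero
#' collapse to presence (1).
#'
#' @param path Path to a TSV file.
#' @return An integer 0/1 matrix, clusters x accessions.
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("matrix file needs a header and rows",
                               call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  header <- parts[[1L]]
  widths <- lengths(parts[-1L])
  if (any(widths != length(header))) {
    stop("ragged row(s) at line(s): ",
         paste(which(widths != length(header)) + 1L, collapse = ", "),
         call. = FALSE)
  }
  body <- parts[-1L]
  ids <- map_chr(body, 1L)
  cells <- suppressWarnings(
    vapply(body, function(p) as.numeric(p[-1L]), numeric(length(header) - 1L))
  )
  if (anyNA(cells)) stop("non-numeric cell in matrix body", call. = FALSE)
  m <- t(matrix(cells, nrow = length(header) - 1L))
  m <- (m > 0) * 1L
  dimnames(m) <- list(ids, header[-1L])
  m
}

#' Write a presence/absence matrix
#'
#' @param m A clusters x accessions 0/1 matrix.
#' @param path Output TSV path.
#' @export
write_matrix <- function(m, path) {
  df <- data.frame(cluster = rownames(m), m, check.names = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read and write 3-column BED files
#'
#' BED intervals are 0-based half-open, matching the package's internal
#' coordinate convention, so values pass through unchanged.
#'
#' @param path File path.
#' @return A tibble with columns `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                  col_types = "cii", comment = "#")
}

#' @rdname read_bed
#' @param bed A tibble with columns `chrom`, `start`, `end`.
#' @export
write_bed <- function(bed, path) {
  readr::write_tsv(bed[, c("chrom", "start", "end")], path, col_names = FALSE)
  invisible(path)
}
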