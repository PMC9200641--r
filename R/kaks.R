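# --- NG86 Ka/Ks -------------------------------------------------------------

bases4 <- c("A", "C", "G", "T")

# codon -> amino acid (stop = "*"), standard genetic code
codon_aa <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

# per-codon synonymous site count: for each position the fraction of the
# three single-nucleotide neighbours coding the same amino acid; mutations
# to stop codons count as nonsynonymous sites
syn_sites_env <- new.env(parent = emptyenv())
syn_sites <- function(codon) {
  if (!is.null(syn_sites_env[[codon]])) return(syn_sites_env[[codon]])
  aa <- codon_aa(codon)
  s <- 0
  cc <- strsplit(codon, "")[[1L]]
  for (pos in 1:3) {
    for (b in setdiff(bases4, cc[pos])) {
      alt <- cc
      alt[pos] <- b
      alt_aa <- codon_aa(paste(alt, collapse = ""))
      if (alt_aa != "*" && alt_aa == aa) s <- s + 1 / 3
    }
  }
  syn_sites_env[[codon]] <- s
  s
}

# tiny permutation generator (1..3 elements)
perms_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms_of(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

# synonymous/nonsynonymous differences between two codons, averaging over
# all orderings of the differing positions; pathways through stop codons are
# skipped and the remainder re-weighted (all pathways used if every one is
# blocked)
codon_diffs <- function(c1, c2) {
  a <- strsplit(c1, "")[[1L]]
  b <- strsplit(c2, "")[[1L]]
  diff_pos <- which(a != b)
  if (length(diff_pos) == 0L) return(c(sd = 0, nd = 0))
  paths <- perms_of(diff_pos)
  tallies <- lapply(paths, function(ord) {
    cur <- a
    sd <- nd <- 0
    for (pos in ord) {
      nxt <- cur
      nxt[pos] <- b[pos]
      aa1 <- codon_aa(paste(cur, collapse = ""))
      aa2 <- codon_aa(paste(nxt, collapse = ""))
      if (aa1 == "*" || aa2 == "*") return(NULL)  # blocked pathway
      if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  })
  ok <- !vapply(tallies, is.null, logical(1L))
  if (!any(ok)) {
    # every minimal pathway passes through a stop; fall back to counting
    # steps through stops as nonsynonymous
    tallies <- lapply(paths, function(ord) {
      cur <- a
      sd <- nd <- 0
      for (pos in ord) {
        nxt <- cur
        nxt[pos] <- b[pos]
        if (codon_aa(paste(cur, collapse = "")) ==
            codon_aa(paste(nxt, collapse = ""))) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd = sd, nd = nd)
    })
    ok <- rep(TRUE, length(tallies))
  }
  mat <- do.call(rbind, tallies[ok])
  c(sd = mean(mat[, "sd"]), nd = mean(mat[, "nd"]))
}

split_codons <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L) {
    stop("CDS length ", nchar(cds), " is not a multiple of 3", call. = FALSE)
  }
  substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
}

#' Nei-Gojobori (NG86) Ka/Ks for a codon-aligned CDS pair
#'
#' Counts synonymous and nonsynonymous sites per codon from the nine
#' single-nucleotide neighbours under the standard genetic code (averaged
#' between the two sequences), counts differences per codon averaging over
#' all minimal mutational pathways with equal weight (pathways through stop
#' codons are skipped and the rest re-weighted), and applies the
#' Jukes-Cantor correction `K = -(3/4) log(1 - (4/3) p)` to `pN = Nd/N` and
#' `pS = Sd/S`.
#'
#' Codons containing `N`, `-` or other ambiguity in either sequence are
#' excluded pairwise. A trailing stop codon in either sequence is dropped;
#' a stop anywhere else is an error.
#'
#' @param cds1,cds2 Equal-length, in-frame, codon-aligned DNA strings.
#' @return An object of class `kaks_result`: list with `ka`, `ks`, `ratio`
#'   (`NA` with `ratio_undefined = TRUE` when `Ks = 0`), `n_sites`,
#'   `s_sites`, `nd`, `sd`, `n_codons_used` and `saturated`.
#' @examples
#' ng86_kaks("TTT", "TTA")
#' @export
ng86_kaks <- function(cds1, cds2) {
  if (nchar(cds1) != nchar(cds2)) {
    stop("sequences must be aligned to equal length", call. = FALSE)
  }
  co1 <- split_codons(cds1)
  co2 <- split_codons(cds2)
  clean <- function(codons, which_seq) {
    ok <- grepl("^[ACGT]{3}$", codons)
    aa <- rep(NA_character_, length(codons))
    aa[ok] <- codon_aa(codons[ok])
    stops <- which(aa == "*")
    internal <- stops[stops < length(codons)]
    if (length(internal) > 0L) {
      stop("internal stop codon at codon ", internal[1L], " in sequence ",
           which_seq, call. = FALSE)
    }
    list(ok = ok, last_stop = length(stops) > 0L)
  }
  c1 <- clean(co1, 1L)
  c2 <- clean(co2, 2L)
  keep <- c1$ok & c2$ok
  if (c1$last_stop || c2$last_stop) keep[length(keep)] <- FALSE
  co1 <- co1[keep]
  co2 <- co2[keep]
  if (length(co1) == 0L) stop("no usable codons", call. = FALSE)

  s1 <- vapply(co1, syn_sites, numeric(1L))
  s2 <- vapply(co2, syn_sites, numeric(1L))
  s_sites <- (sum(s1) + sum(s2)) / 2
  n_sites <- 3 * length(co1) - s_sites
  diffs <- map2(co1, co2, codon_diffs)
  sd_tot <- sum(map_dbl(diffs, "sd"))
  nd_tot <- sum(map_dbl(diffs, "nd"))
  p_n <- if (n_sites > 0) nd_tot / n_sites else 0
  p_s <- if (s_sites > 0) sd_tot / s_sites else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  ka <- jc(p_n)
  ks <- jc(p_s)
  saturated <- p_n >= 0.75 || p_s >= 0.75
  ratio_undefined <- is.na(ks) || ks == 0
  structure(list(ka = ka, ks = ks,
                 ratio = if (ratio_undefined) NA_real_ else ka / ks,
                 ratio_undefined = ratio_undefined,
                 n_sites = n_sites, s_sites = s_sites,
                 nd = nd_tot, sd = sd_tot,
                 n_codons_used = length(co1), saturated = saturated),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat("<kaks_result (NG86)> ", x$n_codons_used, " codons\n", sep = "")
  cat("  Ka = ", signif(x$ka, 5), " (N = ", signif(x$n_sites, 6), ", Nd = ",
      signif(x$nd, 6), ")\n", sep = "")
  cat("  Ks = ", signif(x$ks, 5), " (S = ", signif(x$s_sites, 6), ", Sd = ",
      signif(x$sd, 6), ")\n", sep = "")
  cat("  Ka/Ks = ",
      if (x$ratio_undefined) "undefined (Ks = 0)" else signif(x$ratio, 5),
      if (x$saturated) "  [saturated]" else "", "\n", sep = "")
  invisible(x)
}
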