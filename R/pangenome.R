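#' Pan-gene occupancy category thresholds
#'
#' Bands partition the occupancy range `1..n`: specific `{1}`, shell
#' `[2, soft_core_min - 1]`, soft-core `[soft_core_min, n - 1]`, core `{n}`.
#' The default `soft_core_min = ceiling(0.933 n)` (capped at `n - 1`)
#' reproduces the 42-44 soft-core band at `n = 45`.
#'
#' @param n Number of accessions (at least 5).
#' @param soft_core_min Lower edge of the soft-core band.
#' @return A list of class `pan_thresholds`.
#' @export
pan_thresholds <- function(n, soft_core_min = min(ceiling(0.933 * n),
                                                  n - 1)) {
  if (n < 5L) {
    stop("occupancy bands are degenerate for fewer than 5 accessions",
         call. = FALSE)
  }
  if (soft_core_min < 3L || soft_core_min > n) {
    stop("soft_core_min must lie in [3, n]", call. = FALSE)
  }
  structure(list(n = as.integer(n),
                 soft_core_min = as.integer(soft_core_min)),
            class = "pan_thresholds")
}

#' Classify pan-gene clusters by occupancy
#'
#' A cluster present in all `n` accessions is core; in `soft_core_min` to
#' `n - 1`, soft-core; in exactly 1, accession-specific; otherwise shell.
#' All-zero clusters are dropped with a message.
#'
#' @param matrix A clusters x accessions 0/1 matrix (counts collapse to
#'   presence).
#' @param thresholds A [pan_thresholds()]; defaults to the matrix's column
#'   count.
#' @return An object of class `pan_classification`: list with `clusters`
#'   (tibble of `cluster`, `occupancy`, `category`) and `summary` (tibble of
#'   `category`, `n`, `fraction`).
#' @export
classify_clusters <- function(matrix, thresholds = pan_thresholds(ncol(matrix))) {
  m <- (matrix > 0) * 1L
  if (ncol(m) != thresholds$n) {
    stop("thresholds were built for n = ", thresholds$n, " but the matrix ",
         "has ", ncol(m), " accessions", call. = FALSE)
  }
  occ <- rowSums(m)
  if (any(occ == 0L)) {
    message(sum(occ == 0L), " all-zero cluster(s) dropped")
    keep <- occ > 0L
    m <- m[keep, , drop = FALSE]
    occ <- occ[keep]
  }
  n <- thresholds$n
  sc <- thresholds$soft_core_min
  cats <- c("core", "soft_core", "shell", "specific")
  category <- ifelse(occ == n, "core",
                     ifelse(occ >= sc, "soft_core",
                            ifelse(occ == 1L, "specific", "shell")))
  clusters <- tibble(cluster = rownames(m) %||% as.character(seq_along(occ)),
                     occupancy = as.integer(occ),
                     category = factor(category, levels = cats))
  summary <- clusters %>%
    count(.data$category, name = "n", .drop = FALSE) %>%
    mutate(fraction = .data$n / sum(.data$n))
  structure(list(clusters = clusters, summary = summary,
                 thresholds = thresholds),
            class = "pan_classification")
}

#' @export
print.pan_classification <- function(x, ...) {
  cat("<pan_classification> ", nrow(x$clusters), " clusters, n = ",
      x$thresholds$n, " accessions (soft-core ", x$thresholds$soft_core_min,
      "-", x$thresholds$n - 1L, ")\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Pan/core accumulation curves by random accession sampling
#'
#' For each genome count `k` in `1..n`, samples accession subsets uniformly
#' (all distinct subsets when `choose(n, k)` does not exceed
#' `n_combinations`, otherwise `n_combinations` random subsets), computes the
#' pan size (clusters present in at least one sampled accession) and core
#' size (clusters present in all sampled), and repeats over `replications`
#' replicate rounds.
#'
#' @param matrix A clusters x accessions 0/1 matrix.
#' @param n_combinations Subsets sampled per genome count (default 500).
#' @param replications Replicate sampling rounds (default 30).
#' @param seed Integer seed; fixed seed gives identical curves.
#' @return An object of class `pan_curve`: a tibble with one row per `k`
#'   (`k`, `pan_mean`, `pan_min`, `pan_max`, `core_mean`, `core_min`,
#'   `core_max`, `n_subsets`).
#' @export
accumulation_curve <- function(matrix, n_combinations = 500L,
                               replications = 30L, seed = 1L) {
  m <- (matrix > 0) * 1L
  n <- ncol(m)
  stopifnot(n >= 2L)
  set.seed(seed)
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    n_total <- choose(n, k)
    pans <- cores <- numeric(0L)
    for (rep in seq_len(replications)) {
      if (n_total <= n_combinations) {
        sub <- combn(n, k)
      } else {
        sub <- replicate(n_combinations, sample.int(n, k))
        if (is.null(dim(sub))) sub <- matrix(sub, nrow = 1L)
      }
      ind <- matrix(0L, n, ncol(sub))
      ind[cbind(as.vector(sub),
                rep(seq_len(ncol(sub)), each = k))] <- 1L
      occ <- m %*% ind
      pans <- c(pans, colSums(occ > 0L))
      cores <- c(cores, colSums(occ == k))
    }
    rows[[k]] <- tibble(k = k,
                        pan_mean = mean(pans), pan_min = min(pans),
                        pan_max = max(pans),
                        core_mean = mean(cores), core_min = min(cores),
                        core_max = max(cores),
                        n_subsets = length(pans))
  }
  out <- bind_rows(rows)
  class(out) <- c("pan_curve", class(out))
  out
}
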