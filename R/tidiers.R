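#' Tidiers and plots for discordpan result objects
#'
#' `tidy()` returns one row per component estimate, `glance()` a one-row
#' model summary, and `autoplot()` a ggplot, following the conventions of
#' broom-style packages.
#'
#' @param x A result object.
#' @param ... Unused.
#' @name discordpan-tidiers
NULL

#' @rdname discordpan-tidiers
#' @export
tidy.dstat_result <- function(x, ...) {
  tibble(statistic = x$statistic_label, estimate = x$estimate,
         std.error = x$se, z = x$z, n_blocks = x$n_blocks,
         undefined_z = x$undefined_z)
}

#' @rdname discordpan-tidiers
#' @export
glance.dstat_result <- function(x, ...) {
  dplyr::bind_cols(tidy(x), x$counts %>% select(-"block"))
}

#' @rdname discordpan-tidiers
#' @export
tidy.f4_result <- function(x, ...) {
  if (is.null(x$alpha)) {
    tibble(statistic = "f4",
           quartet = paste(x$quartet, collapse = ","),
           estimate = x$f4, std.error = x$se, z = x$z, n_blocks = x$n_blocks)
  } else {
    tibble(statistic = "f4_ratio",
           quartet = paste0(paste(x$numerator_quartet, collapse = ","), " / ",
                            paste(x$denominator_quartet, collapse = ",")),
           estimate = x$alpha, std.error = x$se, z = x$z,
           n_blocks = x$n_blocks)
  }
}

#' @rdname discordpan-tidiers
#' @export
tidy.kaks_result <- function(x, ...) {
  tibble(ka = x$ka, ks = x$ks, ratio = x$ratio,
         n_sites = x$n_sites, s_sites = x$s_sites, nd = x$nd, sd = x$sd,
         n_codons_used = x$n_codons_used, saturated = x$saturated,
         ratio_undefined = x$ratio_undefined)
}

#' @rdname discordpan-tidiers
#' @export
tidy.pan_classification <- function(x, ...) x$clusters

#' @rdname discordpan-tidiers
#' @export
glance.pan_classification <- function(x, ...) {
  x$summary %>%
    tidyr::pivot_wider(names_from = "category",
                       values_from = c("n", "fraction")) %>%
    mutate(n_clusters = nrow(x$clusters))
}

#' @rdname discordpan-tidiers
#' @export
tidy.topology_spectrum <- function(x, ...) x$spectrum

#' @rdname discordpan-tidiers
#' @export
glance.topology_spectrum <- function(x, ...) {
  tibble(n_windows_total = x$n_windows_total,
         n_windows_passed = x$n_windows_passed,
         n_distinct_topologies = x$n_distinct_topologies)
}

#' @rdname discordpan-tidiers
#' @export
tidy.quartet_comparison <- function(x, ...) x$paired

#' @rdname discordpan-tidiers
#' @export
glance.quartet_comparison <- function(x, ...) {
  tibble(r = x$r, n_paired = nrow(x$paired))
}

#' @rdname discordpan-tidiers
#' @param object A result object (ggplot2 `autoplot` convention).
#' @export
autoplot.pan_curve <- function(object, ...) {
  long <- object %>%
    select("k", pan = "pan_mean", core = "core_mean") %>%
    tidyr::pivot_longer(c("pan", "core"), names_to = "curve",
                        values_to = "clusters")
  ribbon <- object %>%
    select("k", "pan_min", "pan_max", "core_min", "core_max")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$clusters,
                                     colour = .data$curve)) +
    ggplot2::geom_ribbon(data = ribbon,
                         ggplot2::aes(x = .data$k, ymin = .data$pan_min,
                                      ymax = .data$pan_max),
                         inherit.aes = FALSE, alpha = 0.15) +
    ggplot2::geom_ribbon(data = ribbon,
                         ggplot2::aes(x = .data$k, ymin = .data$core_min,
                                      ymax = .data$core_max),
                         inherit.aes = FALSE, alpha = 0.15) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "genomes sampled", y = "pan-gene clusters",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname discordpan-tidiers
#' @export
autoplot.topology_spectrum <- function(object, ...) {
  d <- if (!is.null(object$class_counts)) {
    object$class_counts %>% rename(label = "topology_class", count = "n")
  } else {
    object$spectrum %>%
      head(15L) %>%
      rename(label = "topology")
  }
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$label,
                                                     .data$count),
                                  y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "windows") +
    ggplot2::theme_minimal()
}

#' @rdname discordpan-tidiers
#' @export
autoplot.quartet_comparison <- function(object, ...) {
  ggplot2::ggplot(object$paired,
                  ggplot2::aes(x = .data$freq_sim, y = .data$freq_obs)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "simulated frequency", y = "observed frequency",
                  subtitle = paste0("Pearson r = ", signif(object$r, 4))) +
    ggplot2::theme_minimal()
}
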