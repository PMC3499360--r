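#' Plot an 8-feature average gene profile
#'
#' Draws the metagene curve (IG, P, E1-E5, IN on the x-axis, mean log2
#' enrichment on the y-axis), one colored line per region, faceted by
#' genotype and antibody when those columns are present.
#'
#' @param object A `metagene_profile` (from [region_metagene()] or
#'   [accessibility_metagene()]), or a row-bound tibble of several.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metagene_profile <- function(object, ...) {
  df <- as_tibble(object)
  grp <- intersect(c("genotype", "antibody"), names(df))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$feature, y = .data$mean,
                                        colour = .data$region,
                                        group = .data$region)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::labs(x = "gene feature", y = "mean enrichment",
                  colour = "region") +
    ggplot2::theme_minimal()
  if (length(grp)) {
    p <- p + ggplot2::facet_grid(
      rows = if ("antibody" %in% grp) ggplot2::vars(.data$antibody),
      cols = if ("genotype" %in% grp) ggplot2::vars(.data$genotype))
  }
  p
}

#' @rdname autoplot.metagene_profile
#' @export
plot_metagene <- function(object, ...) autoplot.metagene_profile(object, ...)

#' Plot a peak-centered average profile
#'
#' @param object A `peak_profile` from [peak_centered_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.peak_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$offset_mid, y = .data$mean)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "offset from peak center (bp)",
                  y = "mean enrichment") +
    ggplot2::theme_minimal()
}

#' Plot a binary occupancy heat map
#'
#' Promoters (ordered by chromosome and coordinate) on the x-axis, passing
#' factors on the y-axis, bound promoters drawn as filled tiles.
#'
#' @param object An `occupancy_matrix` from [occupancy_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.occupancy_matrix <- function(object, ...) {
  m <- object$matrix
  long <- tidyr::pivot_longer(m, cols = dplyr::all_of(object$passing),
                              names_to = "factor", values_to = "bound")
  long$gene_id <- factor(long$gene_id, levels = m$gene_id)
  long$factor <- factor(long$factor, levels = rev(object$passing))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$gene_id, y = .data$factor,
                                     fill = factor(.data$bound))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`0` = "white", `1` = "grey30"),
                               name = "bound") +
    ggplot2::labs(x = "promoter", y = "factor") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @rdname region_metagene
#' @param x A `metagene_profile`.
#' @param ... Unused.
#' @export
tidy.metagene_profile <- function(x, ...) as_tibble(x)

#' @rdname region_metagene
#' @export
glance.metagene_profile <- function(x, ...) {
  tibble(n_regions = length(unique(x$region)),
         n_features = length(unique(x$feature)),
         max_n_genes = max(x$n_genes),
         grand_mean = mean(x$mean, na.rm = TRUE))
}
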