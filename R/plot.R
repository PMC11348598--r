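#' Heatmap of an RBH-coverage distance matrix
#'
#' @param object A `polswap_dist` matrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.polswap_dist <- function(object, ...) {
  ids <- rownames(object)
  df <- tidyr::expand_grid(genome_a = ids, genome_b = ids)
  df$distance <- as.vector(t(unclass(object)))
  ggplot2::ggplot(df, ggplot2::aes(.data$genome_b, .data$genome_a,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), direction = -1) +
    ggplot2::labs(x = NULL, y = NULL, fill = "distance",
                  title = "RBH coverage distance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' DNAP family composition of the fixed-depth clades
#'
#' One bar per multi-genome clade, stacked by DNAP family counts; hotspot
#' clades (type-i heterogeneity) are marked.
#'
#' @param object A `swap_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.swap_report <- function(object, ...) {
  prof <- object$clade_profiles[!object$clade_profiles$is_singleton, ]
  calls <- object$calls
  df <- calls %>%
    dplyr::inner_join(object$membership[, c("clade_id", "genome_id")],
                      by = "genome_id") %>%
    dplyr::filter(.data$clade_id %in% prof$clade_id) %>%
    dplyr::count(.data$clade_id, .data$family)
  hot <- prof$clade_id[prof$het_type_i]
  df$hotspot <- df$clade_id %in% hot
  ggplot2::ggplot(df, ggplot2::aes(.data$clade_id, .data$n,
                                   fill = .data$family)) +
    ggplot2::geom_col() +
    ggplot2::geom_point(data = df[df$hotspot, , drop = FALSE],
                        ggplot2::aes(y = 0), shape = 17, size = 2,
                        show.legend = FALSE) +
    ggplot2::labs(x = "clade", y = "DNAP calls", fill = "family",
                  title = "DNAP families per clade (triangles: swap hotspots)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

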