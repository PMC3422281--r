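#' Plot a word-enrichment landscape
#'
#' One line per word across leading-bin cutoffs, with the Bonferroni
#' threshold as horizontal dotted lines. Positive scores indicate
#' enrichment of a word among the sequences before the cutoff.
#'
#' @param object `mirdep_landscape` from [enrichment_landscape()].
#' @param highlight words to colour (others are grey).
#' @param alpha significance level for the threshold lines (default 0.01).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mirdep_landscape <- function(object, highlight = character(0),
                                      alpha = 0.01, ...) {
  thr <- landscape_significance(object, alpha = alpha)$threshold
  df <- as_tibble(object) |>
    mutate(highlighted = ifelse(.data$word %in% highlight, .data$word, NA))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cutoff, y = .data$score,
                                   group = .data$word)) +
    ggplot2::geom_line(data = df |> filter(is.na(.data$highlighted)),
                       colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_line(data = df |> filter(!is.na(.data$highlighted)),
                       ggplot2::aes(colour = .data$highlighted),
                       linewidth = 0.7) +
    ggplot2::geom_hline(yintercept = c(-thr, thr), linetype = "dotted") +
    ggplot2::labs(x = "ranked sequences (leading bin size)",
                  y = "signed log10 hypergeometric p",
                  colour = "word") +
    ggplot2::theme_minimal()
}

#' Plot a GSEA running enrichment score
#'
#' The running score along the ranked list with member positions marked on
#' the axis.
#'
#' @param object `mirdep_gsea` from [gsea_preranked()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mirdep_gsea <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                   y = .data$running_score)) +
    ggplot2::geom_line(colour = "darkgreen") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_rug(data = df |> filter(.data$hit), sides = "b",
                      length = ggplot2::unit(0.03, "npc")) +
    ggplot2::labs(x = "rank in ordered list", y = "running enrichment score",
                  title = sprintf("%s: ES = %.3f, p = %.3g", object$set_id,
                                  object$es, object$p_perm)) +
    ggplot2::theme_minimal()
}

#' Heatmap of per-list per-cluster influence support
#'
#' Clusters as rows, target lists as columns; cell colour is the support
#' score and the printed number is the count of genes shared between the
#' cluster and the list.
#'
#' @param object `mirdep_support` from [influence_support()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mirdep_support <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(cluster = factor(.data$cluster,
                            levels = rev(sort(unique(.data$cluster)))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$list_id, y = .data$cluster,
                                   fill = .data$support)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$shared_count),
                       colour = "green3", size = 3) +
    ggplot2::scale_fill_viridis_c(option = "C") +
    ggplot2::labs(x = "target list", y = "cluster", fill = "support") +
    ggplot2::theme_minimal()
}

#' Bar plot of normalized class depths per library
#'
#' @param class_depths tibble from [normalize_class_depths()] (the
#'   `normalized` element) or raw class depths.
#' @return a ggplot object.
#' @export
plot_class_depths <- function(class_depths) {
  df <- class_depths |> filter(.data$class != "unmapped")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$depth,
                                   fill = .data$library_id)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "ncRNA class", y = "mapped depth",
                  fill = "library") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
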