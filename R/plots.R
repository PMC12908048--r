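# ggplot2 views of the result objects.

#' Boxplots of alpha diversity indices by group
#'
#' @param alpha Output of [alpha_diversity()].
#' @param metadata Metadata tibble with `sample_id` and the grouping column.
#' @param group Grouping column name (default `"infection"`).
#' @return A ggplot object, one facet per index.
#' @export
plot_alpha_diversity <- function(alpha, metadata, group = "infection") {
  df <- inner_join(alpha, as_tibble(metadata)[c("sample_id", group)],
                   by = "sample_id") |>
    pivot_longer(cols = -c("sample_id", !!group),
                 names_to = "index", values_to = "value") |>
    mutate(group = factor(.data[[group]]))
  ggplot(df, aes(x = .data$group, y = .data$value, fill = .data$group)) +
    geom_boxplot(outlier.size = 0.8, alpha = 0.8) +
    facet_wrap(~index, scales = "free_y") +
    labs(x = group, y = NULL, title = "Alpha diversity by group") +
    theme_minimal() +
    theme(legend.position = "none")
}

#' @describeIn pcoa Scatter plot of the first two principal coordinates,
#'   axis labels annotated with the proportion of (positive-eigenvalue)
#'   variation explained. `colour` may be a vector of group labels aligned
#'   with the samples.
#' @param object A `pcoa_ordination`.
#' @param colour Optional per-sample grouping vector for colouring.
#' @param ... Unused.
#' @export
autoplot.pcoa_ordination <- function(object, colour = NULL, ...) {
  df <- object$coordinates
  if (!is.null(colour)) df$group <- factor(colour)
  p <- ggplot(df, aes(x = .data$Axis1, y = .data$Axis2)) +
    labs(
      x = sprintf("PCo1 (%.1f%%)", 100 * object$proportion_explained[1]),
      y = sprintf("PCo2 (%.1f%%)", 100 * object$proportion_explained[2]),
      title = "Principal-coordinates ordination"
    ) +
    theme_minimal()
  if (is.null(colour)) {
    p + geom_point()
  } else {
    p + geom_point(aes(colour = .data$group)) +
      stat_ellipse(aes(colour = .data$group), level = 0.9)
  }
}

#' @describeIn bootstrap_optimism ROC curve of the apparent model, annotated
#'   with the apparent and optimism-corrected AUC.
#' @param object A `prognosis_result`.
#' @param ... Unused.
#' @export
autoplot.prognosis_result <- function(object, ...) {
  ggplot(object$roc, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    geom_step() +
    coord_equal() +
    labs(
      x = "False positive rate", y = "True positive rate",
      title = "ROC of the prognostic model",
      subtitle = sprintf("apparent AUC %.3f; corrected AUC %.3f (95%% CI %.3f-%.3f)",
                         object$apparent_auc, object$corrected_auc,
                         object$ci_low, object$ci_high)
    ) +
    theme_minimal()
}

#' @describeIn build_network Force-directed view of the co-occurrence
#'   network; edge colour encodes the correlation sign.
#' @param object A `co_network`.
#' @param ... Unused.
#' @export
autoplot.co_network <- function(object, ...) {
  if (nrow(object$edges) == 0) {
    return(ggplot() +
             annotate("text", x = 0, y = 0, label = "empty network") +
             theme_void())
  }
  g <- as_igraph(object)
  set.seed(1) # layout only; analysis results unaffected
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble(name = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
  edges <- object$edges |>
    inner_join(nodes, by = c(taxon_a = "name")) |>
    rename(x0 = "x", y0 = "y") |>
    inner_join(nodes, by = c(taxon_b = "name")) |>
    rename(x1 = "x", y1 = "y")
  ggplot() +
    geom_segment(data = edges,
                 aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                     yend = .data$y1, colour = .data$r > 0),
                 alpha = 0.5) +
    geom_point(data = nodes, aes(x = .data$x, y = .data$y), size = 2) +
    scale_colour_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "#b2182b"),
                        labels = c(`TRUE` = "positive", `FALSE` = "negative"),
                        name = "correlation") +
    theme_void() +
    labs(title = sprintf("Co-occurrence network (%d nodes, %d edges)",
                         length(object$nodes), nrow(object$edges)))
}
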