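# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @exportS3Method generics::tidy
tidy.pec_map <- function(x, ...) {
  nodes <- attr(x, "nodes")
  out <- as_tibble(x)
  if (!is.null(nodes)) out <- dplyr::left_join(out, nodes, by = "node_id")
  out
}

#' @exportS3Method generics::glance
glance.pec_map <- function(x, ...) {
  ok <- !x$degenerate
  tibble(subset = attr(x, "subset"), method = attr(x, "method"),
         n_outcomes = attr(x, "n_outcomes"),
         n_nodes = nrow(x), n_degenerate = sum(!ok),
         pec_mean = mean(x$pec[ok]),
         pec_max = max(x$pec[ok]),
         robust_max = robust_max(x)$value)
}

#' @exportS3Method generics::tidy
tidy.pec_pvalues <- function(x, ...) as_tibble(x)

#' @exportS3Method generics::glance
glance.pec_pvalues <- function(x, ...) {
  ok <- !x$degenerate
  tibble(sidedness = attr(x, "sidedness"), n_perm = attr(x, "n_perm"),
         alpha = attr(x, "alpha"), n_nodes = nrow(x),
         n_significant = sum(x$significant & ok),
         rejection_rate = mean(x$p[ok] < attr(x, "alpha")),
         p_min = min(x$p))
}

#' @exportS3Method generics::tidy
tidy.parcel_table <- function(x, ...) as_tibble(x)

#' @exportS3Method generics::glance
glance.parcel_table <- function(x, ...) {
  tibble(alpha = attr(x, "alpha"), n_parcels = nrow(x),
         n_significant = sum(x$significant), n_empty = sum(x$empty))
}

#' @exportS3Method generics::tidy
tidy.pec_run <- function(x, ...) tidy(x$parcels)

#' @exportS3Method generics::glance
glance.pec_run <- function(x, ...) {
  s <- x$summary
  tibble(subset = s$subset, n_outcomes = s$n_outcomes, g_bar = s$g_bar,
         robust_max_pec = s$robust_max$value,
         n_significant_nodes = s$n_significant_nodes,
         n_significant_parcels = s$n_significant_parcels,
         n_perm = s$plan$n_perm, sidedness = s$plan$sidedness,
         alpha = s$plan$alpha, seed = s$plan$seed)
}

#' Plot a PEC map over node coordinates
#'
#' Scatter of nodes colored by PEC on the x/y plane (grid meshes) with a
#' diverging palette centered at zero; degenerate nodes are dropped.
#'
#' @param object A `pec_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pec_map <- function(object, ...) {
  df <- tidy(object)
  df <- df[!df$degenerate, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$pec)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_colour_gradient2(low = "#2166AC", mid = "grey90",
                                    high = "#B2182B", midpoint = 0) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("PEC map (%s)", attr(object, "subset")),
                  x = "x (mm)", y = "y (mm)", colour = "PEC") +
    ggplot2::theme_minimal()
}

#' Plot node-wise permutation significance
#'
#' Histogram of node p-values with the alpha threshold marked; a calibrated
#' null map is flat, a planted effect piles mass at small p.
#'
#' @param object A `pec_pvalues`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pec_pvalues <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[!df$degenerate, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, by = 0.05),
                            fill = "grey35", colour = "white") +
    ggplot2::geom_vline(xintercept = attr(object, "alpha"),
                        linetype = "dashed", colour = "#B2182B") +
    ggplot2::labs(title = sprintf("Permutation p-values (%s, n_perm = %d)",
                                  attr(object, "sidedness"), attr(object, "n_perm")),
                  x = "p", y = "nodes") +
    ggplot2::theme_minimal()
}

#' Plot the parcel significance table
#'
#' Per-parcel 75th-percentile p-value on a reversed scale with the alpha
#' rule line; significant parcels are highlighted.
#'
#' @param object A `parcel_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.parcel_table <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[!df$empty, ]
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$parcel, .data$p75),
                                   y = .data$p75, fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = attr(object, "alpha"),
                        linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "#B2182B")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "75th-percentile node p-value",
                  fill = sprintf("p75 < %.2f", attr(object, "alpha"))) +
    ggplot2::theme_minimal()
}
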