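#' Volcano plot of a DE table
#'
#' Log2 fold change against -log10 p-value, colored by direction call
#' (up-regulated red, down-regulated green, unchanged blue), with the
#' fold-change and p cutoffs drawn as dashed guides.
#'
#' @param de A `de_table` from [call_de()].
#' @return A ggplot object.
#' @export
plot_volcano <- function(de) {
  cut <- attr(de, "cutoffs") %||% c(fc = 2, p = 0.05)
  ggplot2::ggplot(de, ggplot2::aes(.data$log2fc, -log10(.data$p_value),
                                   color = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::geom_vline(xintercept = c(-log2(cut[["fc"]]), log2(cut[["fc"]])),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(cut[["p"]]),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_color_manual(values = c(up = "#d73027", down = "#1a9850",
                                           unchanged = "#4575b4")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p-value",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.de_table <- function(object, ...) plot_volcano(object)

#' Degree survival-function plot of a network
#'
#' The empirical `P(Degree >= d)` on log-log axes with the fitted
#' least-squares line whose slope summarizes the scale-free character.
#'
#' @param stats A `degree_stats` object.
#' @return A ggplot object.
#' @export
plot_degree_ccdf <- function(stats) {
  deg <- stats$degrees$degree
  d <- sort(unique(deg[deg >= 1]))
  df <- tibble::tibble(
    degree = d,
    survival = vapply(d, function(x) mean(deg >= x), numeric(1))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$degree, .data$survival)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, color = "#d73027") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree d", y = "P(Degree >= d)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.degree_stats <- function(object, ...) plot_degree_ccdf(object)

#' Scatter plot of RNA-seq vs qPCR log2 fold changes
#'
#' @param x A `concordance_result` from [concordance()].
#' @return A ggplot object annotated with r and p.
#' @export
plot_concordance <- function(x) {
  ggplot2::ggplot(x$data, ggplot2::aes(.data$log2fc_rnaseq,
                                       .data$log2fc_qpcr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         linewidth = 0.3) +
    ggplot2::geom_point(color = "#4575b4") +
    ggplot2::labs(
      x = "RNA-seq log2 fold change", y = "qPCR log2 fold change",
      subtitle = sprintf("r = %.3f, p = %.3g (n = %d)", x$r, x$p_value, x$n)
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.concordance_result <- function(object, ...) plot_concordance(object)

#' Connectivity-score overview of a drug ranking
#'
#' Drugs ordered by permutation p-value with their connectivity scores;
#' reversers (negative scores) extend downwards.
#'
#' @param x A `connectivity_table` from [rank_drugs()].
#' @param top Number of top drugs to show (default 20).
#' @return A ggplot object.
#' @export
plot_connectivity <- function(x, top = 20L) {
  df <- utils::head(x, top)
  df$drug_id <- factor(df$drug_id, levels = rev(df$drug_id))
  ggplot2::ggplot(df, ggplot2::aes(.data$score, .data$drug_id,
                                   fill = .data$perm_p)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_gradient(low = "#d73027", high = "#bdbdbd") +
    ggplot2::labs(x = "connectivity score", y = NULL, fill = "perm p") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.connectivity_table <- function(object, ...) plot_connectivity(object)

# ---- broom-style methods ----------------------------------------------------

#' @exportS3Method generics::tidy
tidy.de_table <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @exportS3Method generics::glance
glance.de_table <- function(x, ...) {
  tab <- table(factor(x$direction, levels = c("up", "down", "unchanged")))
  tibble::tibble(
    n_genes = nrow(x),
    n_up = as.integer(tab[["up"]]),
    n_down = as.integer(tab[["down"]]),
    n_unchanged = as.integer(tab[["unchanged"]]),
    n_de = as.integer(tab[["up"]] + tab[["down"]])
  )
}

#' @exportS3Method generics::tidy
tidy.concordance_result <- function(x, ...) x$data

#' @exportS3Method generics::glance
glance.concordance_result <- function(x, ...) {
  tibble::tibble(n = x$n, r = x$r, p_value = x$p_value)
}

#' @exportS3Method generics::tidy
tidy.degree_stats <- function(x, ...) {
  dplyr::mutate(x$degrees, hub = .data$node %in% x$hubs)
}

#' @exportS3Method generics::glance
glance.degree_stats <- function(x, ...) {
  tibble::tibble(
    n_nodes = x$n_nodes, n_edges = x$n_edges,
    mean_degree = x$mean, sd_degree = x$sd, threshold = x$threshold,
    n_hubs = length(x$hubs), powerlaw_slope = x$powerlaw_slope
  )
}

#' @exportS3Method generics::tidy
tidy.concordance_classification <- function(x, ...) x$pairs

#' @exportS3Method generics::glance
glance.concordance_classification <- function(x, ...) {
  tibble::tibble(
    n_shared = nrow(x$pairs),
    consistent_down = x$counts[["consistent_down"]],
    consistent_up = x$counts[["consistent_up"]],
    mouse_down_human_up = x$counts[["mouse_down_human_up"]],
    mouse_up_human_down = x$counts[["mouse_up_human_down"]],
    n_consistent = x$n_consistent, n_inconsistent = x$n_inconsistent
  )
}
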