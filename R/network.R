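#' Filter an interaction network by combined score
#'
#' Keeps edges with `combined_score >= min_score` (the 0.4 default read
#' inclusively) and drops nodes left without any edge; the node set of the
#' result is exactly the set of surviving-edge endpoints.
#'
#' @param edges An `interaction_edges` tibble (`node_a`, `node_b`,
#'   `combined_score` in \[0,1\]).
#' @param min_score Minimum combined score (default 0.4, inclusive).
#' @return A filtered `interaction_edges` tibble.
#' @export
filter_edges <- function(edges, min_score = 0.4) {
  edges <- new_interaction_edges(edges)
  out <- dplyr::filter(edges, .data$combined_score >= min_score)
  structure(out, class = unique(c("interaction_edges", class(out))))
}

#' Degree statistics, hub calls and scale-free slope of a network
#'
#' Computes unweighted node degrees (each undirected edge contributes 1 to
#' both endpoints), their mean and sample standard deviation (n-1
#' denominator), the hub threshold `mean + 2 * sd`, and calls hubs as nodes
#' with degree strictly above the threshold. The scale-free character is
#' summarized descriptively by the least-squares slope of
#' `log10 P(Degree >= d)` against `log10 d` over the observed degrees
#' `d >= 1` (a survival-function fit, which avoids histogram-binning
#' artifacts on small networks); it never gates the hub calls.
#'
#' @param edges An `interaction_edges` tibble with >= 3 nodes.
#' @return Object of class `degree_stats`: list with `degrees` (tibble
#'   `node`, `degree`), `mean`, `sd`, `threshold`, `hubs` (character),
#'   `powerlaw_slope`, `n_nodes`, `n_edges`.
#' @examples
#' star <- tibble::tibble(node_a = "hub", node_b = paste0("v", 1:5),
#'                        combined_score = 0.9)
#' degree_stats(star)$threshold   # 4.9327
#' @export
degree_stats <- function(edges) {
  edges <- new_interaction_edges(edges)
  g <- igraph::graph_from_data_frame(
    edges[c("node_a", "node_b")], directed = FALSE
  )
  if (igraph::vcount(g) < 3L) abort("need >= 3 nodes")
  deg <- igraph::degree(g)
  mu <- mean(deg); s <- sd(deg)
  threshold <- mu + 2 * s
  hubs <- names(deg)[deg > threshold]
  structure(
    list(
      degrees = tibble::tibble(node = names(deg), degree = unname(deg)),
      mean = mu, sd = s, threshold = threshold,
      hubs = sort(hubs),
      powerlaw_slope = ccdf_slope(deg),
      n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g)
    ),
    class = "degree_stats"
  )
}

# least-squares slope of log10 P(D >= d) vs log10 d over observed d >= 1
ccdf_slope <- function(deg) {
  d <- sort(unique(deg[deg >= 1]))
  if (length(d) < 3L) return(NA_real_)
  surv <- vapply(d, function(x) mean(deg >= x), numeric(1))
  unname(stats::coef(stats::lm(log10(surv) ~ log10(d)))[2L])
}

#' @exportS3Method base::print
print.degree_stats <- function(x, ...) {
  cat(sprintf(
    "<degree_stats> %d nodes, %d edges | mean degree %.3f, sd %.3f, hub threshold %.3f\n",
    x$n_nodes, x$n_edges, x$mean, x$sd, x$threshold
  ))
  cat(sprintf("hubs (%d): %s\n", length(x$hubs),
              paste(head(x$hubs, 10L), collapse = ", ")))
  cat(sprintf("log-log CCDF slope: %.3f\n", x$powerlaw_slope))
  invisible(x)
}
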