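#' Upper-tail hypergeometric p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' at least `k` marked genes when `n` genes are drawn without replacement
#' from a universe of `N` containing `K` marked ones. Computed in log space
#' via the stable distribution-function routine; `k = 0` gives exactly 1.
#'
#' @param N Background universe size.
#' @param K Background genes with the property (`K <= N`).
#' @param n Query set size (`n <= N`).
#' @param k Query genes with the property (`0 <= k <= min(n, K)`).
#'   All arguments are vectorized.
#' @return Upper-tail p-value(s) in (0, 1].
#' @examples
#' hypergeom_upper(10, 5, 4, 4)   # 5 / choose(10, 4)
#' @export
hypergeom_upper <- function(N, K, n, k) {
  if (any(K > N) || any(n > N) || any(k > pmin(n, K)) || any(k < 0) ||
      any(N < 0)) {
    abort("need 0 <= k <= min(n, K), K <= N, n <= N")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: over ascending-sorted p-values,
#' `q_(i) = min_(j >= i) p_(j) * m / j`, mapped back to input order and
#' capped at 1.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order, each in \[p, 1\].
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = FALSE) || anyNA(p_values)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Hypergeometric over-representation analysis of gene sets
#'
#' Tests each annotation term for over-representation of the query set
#' within a declared background universe, with Benjamini-Hochberg FDR across
#' the tested terms. Term memberships are intersected with the background
#' first; terms are tested only when they overlap the query and their
#' background-intersected size lies within `size_range` (keeping the number
#' of tests meaningful, as is standard ORA practice). One-sided
#' over-representation only.
#'
#' @param query Character vector of query gene ids (subset of `background`).
#' @param background Character vector: the gene universe.
#' @param annotation Tibble with `term_id`, `term_name` and list-column
#'   `members` (see [read_gmt()]).
#' @param fdr_cutoff Significance cutoff on the q-value (default 0.05).
#' @param size_range Background-intersected term sizes eligible for testing
#'   (default `c(3, 2000)`).
#' @return Tibble of class `enrichment_table`, sorted by p-value: `term_id`,
#'   `term_name`, `N`, `K`, `n`, `k`, `p_value`, `fdr`, `significant`.
#' @export
enrich_sets <- function(query, background, annotation, fdr_cutoff = 0.05,
                        size_range = c(3, 2000)) {
  query <- unique(query); background <- unique(background)
  if (length(query) == 0L || length(background) == 0L) {
    abort("query and background must be non-empty")
  }
  if (!all(query %in% background)) abort("query must be a subset of background")
  members_bg <- purrr::map(annotation$members, intersect, background)
  K <- lengths(members_bg)
  k <- vapply(members_bg, function(m) length(intersect(m, query)), integer(1))
  keep <- k >= 1L & K >= size_range[1L] & K <= size_range[2L]
  out <- tibble::tibble(
    term_id = annotation$term_id[keep],
    term_name = annotation$term_name[keep],
    N = length(background), K = K[keep], n = length(query), k = k[keep]
  )
  out$p_value <- hypergeom_upper(out$N, out$K, out$n, out$k)
  out$fdr <- bh_fdr(out$p_value)
  out$significant <- out$fdr < fdr_cutoff
  out <- dplyr::arrange(out, .data$p_value, .data$term_id)
  class(out) <- unique(c("enrichment_table", class(out)))
  out
}
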