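#' Relative quantification by the 2^-ddCt method
#'
#' Normalizes each target gene's Ct to the reference gene within each sample
#' (delta-Ct), averages technical replicates on the Ct scale first, then
#' takes the difference of condition means (delta-delta-Ct, second condition
#' minus first) and reports `fold_change = 2^(-ddCt)`.
#'
#' @param ct Ct table: tibble with `sample_id`, `condition`, `gene_id`, `ct`
#'   (cycles, in (0, 45)). The [gen_ct_values()] output qualifies.
#' @param genes Target gene ids; default all non-reference genes present.
#' @param ref_gene Reference gene id; defaults to the table's `ref_gene`
#'   attribute, else `"Rpl7"`.
#' @param conditions Two condition labels, baseline first; default
#'   first-occurrence order in the table.
#' @return Tibble: `gene_id`, `ddct`, `fold_change`, `log2fc`.
#' @examples
#' ct <- gen_ct_values(c(gA = 4), noise_sd = 0, seed = 1)
#' ddct_fold_change(ct)   # recovers fold change 4
#' @export
ddct_fold_change <- function(ct, genes = NULL, ref_gene = NULL,
                             conditions = NULL) {
  if (is.null(ref_gene)) ref_gene <- attr(ct, "ref_gene") %||% "Rpl7"
  if (!any(ct$ct > 0 & ct$ct < 45) || any(!is.finite(ct$ct))) {
    abort("Ct values must be finite and in (0, 45)")
  }
  if (is.null(conditions)) conditions <- unique(ct$condition)
  if (length(conditions) != 2L) abort("exactly two conditions required")
  # technical replicates averaged on the Ct scale
  mean_ct <- ct |>
    dplyr::group_by(.data$sample_id, .data$condition, .data$gene_id) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop")
  ref <- dplyr::filter(mean_ct, .data$gene_id == ref_gene)
  all_samples <- unique(mean_ct$sample_id)
  missing_ref <- setdiff(all_samples, ref$sample_id)
  if (length(missing_ref) > 0L) {
    abort(paste0("reference gene '", ref_gene, "' not measured in sample(s): ",
                 paste(missing_ref, collapse = ", ")))
  }
  if (is.null(genes)) genes <- setdiff(unique(mean_ct$gene_id), ref_gene)
  dct <- mean_ct |>
    dplyr::filter(.data$gene_id %in% genes) |>
    dplyr::left_join(dplyr::select(ref, "sample_id", ref_ct = "ct"),
                     by = "sample_id") |>
    dplyr::mutate(dct = .data$ct - .data$ref_ct)
  per_cond <- dct |>
    dplyr::group_by(.data$gene_id, .data$condition) |>
    dplyr::summarise(dct = mean(.data$dct), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "dct")
  if (!all(conditions %in% names(per_cond))) {
    abort("every target gene needs measurements in both conditions")
  }
  per_cond |>
    dplyr::mutate(
      ddct = .data[[conditions[2L]]] - .data[[conditions[1L]]],
      fold_change = 2^(-.data$ddct),
      log2fc = -.data$ddct
    ) |>
    dplyr::select("gene_id", "ddct", "fold_change", "log2fc")
}

#' RNA-seq / qPCR fold-change concordance
#'
#' Pearson correlation of paired per-gene log2 fold changes from the two
#' platforms, with the exact two-sided p-value from
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom.
#' Correlating on the log scale keeps genes with very large fold changes
#' (the study's span is roughly 70-fold) from dominating by leverage.
#'
#' @param fc_rnaseq,fc_qpcr Named positive numeric vectors of per-gene fold
#'   changes; genes are paired by name and at least 3 shared genes are
#'   required.
#' @return Object of class `concordance_result`: list with `n`, `r`,
#'   `p_value` and a per-gene tibble `data` (`gene_id`, `log2fc_rnaseq`,
#'   `log2fc_qpcr`).
#' @export
concordance <- function(fc_rnaseq, fc_qpcr) {
  if (any(fc_rnaseq <= 0) || any(fc_qpcr <= 0)) {
    abort("fold changes must be positive")
  }
  shared <- intersect(names(fc_rnaseq), names(fc_qpcr))
  if (length(shared) < 3L) abort("need >= 3 shared genes")
  x <- log2(fc_rnaseq[shared]); y <- log2(fc_qpcr[shared])
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    abort("zero variance in one platform's log2 fold changes")
  }
  r <- unname(cor(x, y))
  structure(
    list(
      n = length(shared), r = r, p_value = pearson_p(r, length(shared)),
      data = tibble::tibble(gene_id = shared, log2fc_rnaseq = unname(x),
                            log2fc_qpcr = unname(y))
    ),
    class = "concordance_result"
  )
}

#' Two-sided p-value of a Pearson correlation from (r, n) alone
#'
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` referred to a t distribution with
#' `n - 2` degrees of freedom. For |r| = 1 the underflow-safe minimum
#' representable double is returned instead of 0.
#'
#' @param r Pearson correlation in \[-1, 1\].
#' @param n Number of pairs (>= 3).
#' @return Two-sided p-value in (0, 1].
#' @examples
#' pearson_p(0.986, 10)
#' @export
pearson_p <- function(r, n) {
  if (abs(r) > 1) abort("|r| must be <= 1")
  if (n < 3L) abort("n must be >= 3")
  if (abs(r) == 1) return(.Machine$double.xmin)
  t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  max(2 * pt(-abs(t_stat), df = n - 2), .Machine$double.xmin)
}

#' @exportS3Method base::print
print.concordance_result <- function(x, ...) {
  cat(sprintf("<concordance_result> n = %d, r = %.4f, p = %.3g\n",
              x$n, x$r, x$p_value))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
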