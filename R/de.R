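#' Stabilized fold change between two condition means
#'
#' Ratio of pseudo-abundance-shifted condition means, `(mean_b + epsilon) /
#' (mean_a + epsilon)`. The shift keeps the ratio finite for genes silent in
#' one condition and maps a gene silent in both to fold change 1. The log2
#' fold change negates under swapping the two conditions.
#'
#' @param mean_a,mean_b Non-negative condition means (abundance units);
#'   vectorized.
#' @param epsilon Positive pseudo-abundance (default 0.5).
#' @return Tibble with columns `fold_change` and `log2fc`.
#' @examples
#' fold_change(10, 40)   # 40.5 / 10.5
#' @export
fold_change <- function(mean_a, mean_b, epsilon = 0.5) {
  if (epsilon <= 0) abort("epsilon must be > 0")
  if (any(mean_a < 0) || any(mean_b < 0)) abort("means must be >= 0")
  fc <- (mean_b + epsilon) / (mean_a + epsilon)
  tibble::tibble(fold_change = fc, log2fc = log2(fc))
}

#' Two-sided Welch t-test p-value for two replicate groups
#'
#' Thin wrapper over the Welch (unequal-variance) two-sample t-test with
#' Satterthwaite degrees of freedom, with explicit conventions for the
#' degenerate all-constant cases that arise in expression data: two constant
#' equal groups give p = 1, two constant unequal groups give p = 0.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return Two-sided p-value.
#' @examples
#' welch_t(c(1, 2, 3), c(4, 5, 6))
#' @export
welch_t <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    abort("each group needs >= 2 values")
  }
  va <- stats::var(group_a); vb <- stats::var(group_b)
  if (va == 0 && vb == 0) {
    return(if (group_a[1L] == group_b[1L]) 1 else 0)
  }
  t.test(group_a, group_b, var.equal = FALSE)$p.value
}

#' Call differentially expressed genes by fold change and p-value
#'
#' For each gene, condition means on the abundance scale give the stabilized
#' fold change (second condition over first, see [fold_change()]); the
#' per-gene p-value is a two-sided Welch t-test on `log2(x + 1)` replicate
#' values. A gene is `up` iff `fold_change > fc_cutoff` and `p < p_cutoff`
#' (strict), `down` iff `1/fold_change > fc_cutoff` and `p < p_cutoff`, else
#' `unchanged`. Genes with zero abundance in every sample are reported as
#' unchanged with p = 1 so the gene universe stays intact. With
#' `adjust = "BH"` the direction calls use Benjamini-Hochberg adjusted
#' p-values instead (volcano-legend variant, typically with
#' `p_cutoff = 0.01`).
#'
#' @param x An `expression_matrix` (see [new_expression_matrix()]), or a wide
#'   tibble (`gene_id` + sample columns) together with `conditions`.
#' @param conditions Named character vector sample -> condition; taken from
#'   the `expression_matrix` attribute when omitted. The baseline condition
#'   is the first label in sample order.
#' @param fc_cutoff Fold-change cutoff (default 2, strict `>` on the ratio
#'   magnitude).
#' @param p_cutoff P-value cutoff (default 0.05, strict `<`).
#' @param epsilon Pseudo-abundance for [fold_change()].
#' @param adjust `"none"` (raw p, default) or `"BH"`.
#' @return Tibble of class `de_table`: `gene_id`, `mean_a`, `mean_b`,
#'   `fold_change`, `log2fc`, `ratio_magnitude`, `p_value` (plus `p_adj` when
#'   adjusted), `direction`.
#' @export
call_de <- function(x, conditions = NULL, fc_cutoff = 2, p_cutoff = 0.05,
                    epsilon = 0.5, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is.null(conditions)) conditions <- conditions_of(x)
  if (is.null(conditions)) abort("no condition labels supplied or attached")
  samples <- setdiff(names(x), "gene_id")
  conditions <- conditions[samples]
  labs <- unique(unname(conditions))
  if (length(labs) != 2L) abort("exactly two condition labels required")
  a_samples <- samples[conditions == labs[1L]]
  b_samples <- samples[conditions == labs[2L]]
  if (length(a_samples) < 2L || length(b_samples) < 2L) {
    abort("each condition needs >= 2 samples")
  }
  va <- as.matrix(x[a_samples]); vb <- as.matrix(x[b_samples])
  mean_a <- rowMeans(va); mean_b <- rowMeans(vb)
  fc <- fold_change(mean_a, mean_b, epsilon)
  la <- log2(va + 1); lb <- log2(vb + 1)
  p <- vapply(seq_len(nrow(x)), function(i) welch_t(la[i, ], lb[i, ]),
              numeric(1))
  all_zero <- mean_a == 0 & mean_b == 0
  p[all_zero] <- 1
  p_eff <- if (adjust == "BH") p.adjust(p, method = "BH") else p
  direction <- dplyr::case_when(
    fc$fold_change > fc_cutoff & p_eff < p_cutoff ~ "up",
    1 / fc$fold_change > fc_cutoff & p_eff < p_cutoff ~ "down",
    TRUE ~ "unchanged"
  )
  out <- tibble::tibble(
    gene_id = x$gene_id,
    mean_a = mean_a, mean_b = mean_b,
    fold_change = fc$fold_change, log2fc = fc$log2fc,
    ratio_magnitude = pmax(fc$fold_change, 1 / fc$fold_change),
    p_value = p
  )
  if (adjust == "BH") out$p_adj <- p_eff
  out$direction <- direction
  attr(out, "conditions") <- c(a = labs[1L], b = labs[2L])
  attr(out, "cutoffs") <- c(fc = fc_cutoff, p = p_cutoff)
  class(out) <- unique(c("de_table", class(out)))
  out
}

#' Heatmap leaf orders by Pearson-distance UPGMA clustering
#'
#' Agglomerative hierarchical clustering of the DE-gene expression submatrix
#' with distance `1 - Pearson r` and average linkage (UPGMA), applied to both
#' genes (rows) and samples (columns); returns the dendrogram leaf orders
#' used to draw a clustered heatmap. Genes with zero variance across samples
#' have no defined correlation and are dropped with a warning.
#'
#' @param x Numeric matrix (genes x samples, rownames = gene ids) or a wide
#'   tibble with `gene_id` plus sample columns.
#' @return List with `gene_order`, `sample_order` (leaf-order identifiers),
#'   and the two `hclust` objects (`gene_hclust`, `sample_hclust`).
#' @export
cluster_order <- function(x) {
  if (is.data.frame(x)) {
    m <- as.matrix(x[setdiff(names(x), "gene_id")])
    rownames(m) <- x$gene_id
  } else {
    m <- as.matrix(x)
    if (is.null(rownames(m))) rownames(m) <- paste0("row", seq_len(nrow(m)))
  }
  v <- apply(m, 1, stats::var)
  if (any(v == 0)) {
    warn(sprintf("dropping %d zero-variance gene(s) before clustering", sum(v == 0)))
    m <- m[v > 0, , drop = FALSE]
  }
  if (nrow(m) < 2L) abort("need >= 2 genes with non-zero variance to cluster")
  gene_h <- hclust(pearson_dist(m), method = "average")
  sample_h <- if (ncol(m) >= 2L) {
    hclust(pearson_dist(t(m)), method = "average")
  } else {
    NULL
  }
  list(
    gene_order = rownames(m)[gene_h$order],
    sample_order = if (is.null(sample_h)) colnames(m) else colnames(m)[sample_h$order],
    gene_hclust = gene_h, sample_hclust = sample_h
  )
}

# 1 - Pearson correlation distance over the rows of m
pearson_dist <- function(m) {
  stats::as.dist(1 - stats::cor(t(m)))
}
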