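#' Overlap mouse and human DE gene lists through an ortholog map
#'
#' Maps differentially expressed genes of the two species onto each other
#' through a strictly one-to-one ortholog table and splits them into shared
#' pairs (DE in both species) and species-exclusive genes, the Venn counts
#' of a cross-species comparison. Many-to-many ortholog rows are rejected
#' rather than expanded, which would silently multiply counts.
#'
#' @param mouse_de,human_de DE tables (tibbles with `gene_id`, `log2fc`,
#'   ...), containing only DE-called genes.
#' @param orthologs Tibble with `mouse_gene`, `human_gene`; one-to-one.
#' @return List: `shared` (tibble `mouse_gene`, `human_gene`,
#'   `mouse_log2fc`, `human_log2fc`), `mouse_only`, `human_only` (character
#'   vectors) and `counts` (named: shared, mouse_only, human_only).
#' @export
overlap_de <- function(mouse_de, human_de, orthologs) {
  dup_m <- unique(orthologs$mouse_gene[duplicated(orthologs$mouse_gene)])
  dup_h <- unique(orthologs$human_gene[duplicated(orthologs$human_gene)])
  if (length(dup_m) + length(dup_h) > 0L) {
    abort(paste0("ortholog map is not one-to-one; offending gene(s): ",
                 paste(head(c(dup_m, dup_h), 5L), collapse = ", ")))
  }
  if (anyDuplicated(mouse_de$gene_id) || anyDuplicated(human_de$gene_id)) {
    abort("DE tables must not contain duplicate genes")
  }
  shared <- orthologs |>
    dplyr::inner_join(
      dplyr::select(mouse_de, mouse_gene = "gene_id", mouse_log2fc = "log2fc"),
      by = "mouse_gene"
    ) |>
    dplyr::inner_join(
      dplyr::select(human_de, human_gene = "gene_id", human_log2fc = "log2fc"),
      by = "human_gene"
    )
  mouse_only <- setdiff(mouse_de$gene_id, shared$mouse_gene)
  human_only <- setdiff(human_de$gene_id, shared$human_gene)
  list(
    shared = shared,
    mouse_only = mouse_only,
    human_only = human_only,
    counts = c(shared = nrow(shared), mouse_only = length(mouse_only),
               human_only = length(human_only))
  )
}

#' Classify shared ortholog pairs into concordance categories
#'
#' Assigns each shared DE pair to one of four categories from the signs of
#' its log2 fold changes — `consistent_down`, `consistent_up`,
#' `mouse_down_human_up`, `mouse_up_human_down` — and tallies them. The
#' direction comes from the sign of the fold change of already-DE-called
#' genes, not from re-thresholding, so the classification is independent of
#' either species' cutoffs. A zero log2 fold change has no direction and is
#' an error.
#'
#' @param shared Tibble of shared pairs as returned in
#'   [overlap_de()]`$shared`.
#' @return Object of class `concordance_classification`: list with `pairs`
#'   (input plus `mouse_direction`, `human_direction`, `category`), `counts`
#'   (named, all four categories), `n_consistent`, `n_inconsistent`.
#' @export
classify_concordance <- function(shared) {
  if (any(shared$mouse_log2fc == 0) || any(shared$human_log2fc == 0)) {
    abort("zero log2 fold change: direction undefined")
  }
  pairs <- shared |>
    dplyr::mutate(
      mouse_direction = ifelse(.data$mouse_log2fc > 0, "up", "down"),
      human_direction = ifelse(.data$human_log2fc > 0, "up", "down"),
      category = dplyr::case_when(
        .data$mouse_direction == "down" & .data$human_direction == "down" ~ "consistent_down",
        .data$mouse_direction == "up" & .data$human_direction == "up" ~ "consistent_up",
        .data$mouse_direction == "down" & .data$human_direction == "up" ~ "mouse_down_human_up",
        TRUE ~ "mouse_up_human_down"
      )
    )
  levels_ <- c("consistent_down", "consistent_up",
               "mouse_down_human_up", "mouse_up_human_down")
  counts <- table(factor(pairs$category, levels = levels_))
  counts <- stats::setNames(as.integer(counts), levels_)
  structure(
    list(
      pairs = pairs, counts = counts,
      n_consistent = counts[["consistent_down"]] + counts[["consistent_up"]],
      n_inconsistent = counts[["mouse_down_human_up"]] +
        counts[["mouse_up_human_down"]]
    ),
    class = "concordance_classification"
  )
}

#' @exportS3Method base::print
print.concordance_classification <- function(x, ...) {
  cat("<concordance_classification>\n")
  print(x$counts)
  cat(sprintf("consistent: %d, inconsistent: %d\n",
              x$n_consistent, x$n_inconsistent))
  invisible(x)
}
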