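#' Run the full receptivity analysis pipeline
#'
#' Chains all stages on whatever inputs are supplied: differential expression
#' first, then qPCR concordance, gene-set enrichment, TFBS enrichment,
#' network hub detection, connectivity-map drug ranking and cross-species
#' concordance. Stages whose inputs are missing are skipped with a message.
#' The returned manifest records every resolved parameter and the seed, and
#' suffices to reproduce the run exactly.
#'
#' @param expression An `expression_matrix` (required).
#' @param ct Optional Ct table (see [gen_ct_values()] / [read_table()]).
#' @param annotation Optional gene-set annotation ([read_gmt()]).
#' @param promoters,pwms Optional promoter set and PWM library.
#' @param edges Optional `interaction_edges`.
#' @param profiles Optional `ranked_profiles`.
#' @param human_de,orthologs Optional human DE table and ortholog map.
#' @param fc_cutoff,p_cutoff DE cutoffs (defaults 2 and 0.05).
#' @param rel_score TFBS relative-score cutoff (default 0.9).
#' @param tf_alpha TFBS enrichment cutoff (default 0.01).
#' @param min_edge_score Network score filter (default 0.4).
#' @param go_fdr Gene-set enrichment FDR cutoff (default 0.05).
#' @param n_perm Connectivity-map permutations (default 1000).
#' @param seed Integer seed for all stochastic stages.
#' @return List of class `receptivity_run` with one element per executed
#'   stage (`de`, `cluster`, `qpcr`, `enrichment`, `tfbs`, `network`,
#'   `cmap`, `cross_species`) plus `manifest`.
#' @export
run_pipeline <- function(expression, ct = NULL, annotation = NULL,
                         promoters = NULL, pwms = NULL, edges = NULL,
                         profiles = NULL, human_de = NULL, orthologs = NULL,
                         fc_cutoff = 2, p_cutoff = 0.05, rel_score = 0.9,
                         tf_alpha = 0.01, min_edge_score = 0.4,
                         go_fdr = 0.05, n_perm = 1000L, seed = 1L) {
  res <- list()
  skipped <- character(0)

  de <- call_de(expression, fc_cutoff = fc_cutoff, p_cutoff = p_cutoff)
  res$de <- de
  de_genes <- de$gene_id[de$direction != "unchanged"]
  up <- de$gene_id[de$direction == "up"]
  down <- de$gene_id[de$direction == "down"]

  if (length(de_genes) >= 2L) {
    sub <- expression[expression$gene_id %in% de_genes, ]
    res$cluster <- cluster_order(sub)
  } else {
    skipped <- c(skipped, "cluster")
    inform("cluster: fewer than 2 DE genes, skipped")
  }

  if (!is.null(ct)) {
    qp <- ddct_fold_change(ct)
    fc_rnaseq <- stats::setNames(de$fold_change, de$gene_id)
    res$qpcr <- list(
      fold_changes = qp,
      concordance = concordance(fc_rnaseq[qp$gene_id],
                                stats::setNames(qp$fold_change, qp$gene_id))
    )
  } else skipped <- c(skipped, "qpcr")

  if (!is.null(annotation)) {
    res$enrichment <- enrich_sets(de_genes, de$gene_id, annotation,
                                  fdr_cutoff = go_fdr)
  } else skipped <- c(skipped, "enrichment")

  if (!is.null(promoters) && !is.null(pwms)) {
    res$tfbs <- tf_enrichment(promoters, pwms, up, down, de$gene_id,
                              cutoff = rel_score, alpha = tf_alpha)
  } else skipped <- c(skipped, "tfbs")

  if (!is.null(edges)) {
    filtered <- filter_edges(edges, min_edge_score)
    res$network <- list(edges = filtered, stats = degree_stats(filtered))
  } else skipped <- c(skipped, "network")

  if (!is.null(profiles)) {
    res$cmap <- rank_drugs(profiles, up, down, n_perm = n_perm, seed = seed)
  } else skipped <- c(skipped, "cmap")

  if (!is.null(human_de) && !is.null(orthologs)) {
    mouse_de <- de[de$direction != "unchanged",
                   c("gene_id", "log2fc", "p_value")]
    ov <- overlap_de(mouse_de, human_de, orthologs)
    res$cross_species <- list(
      overlap = ov,
      classification = if (nrow(ov$shared) > 0L) classify_concordance(ov$shared)
    )
  } else skipped <- c(skipped, "cross_species")

  if (length(skipped) > 0L) {
    inform(paste0("stages skipped (no input): ", paste(skipped, collapse = ", ")))
  }
  res$manifest <- list(
    seed = as.integer(seed),
    params = list(fc_cutoff = fc_cutoff, p_cutoff = p_cutoff,
                  rel_score = rel_score, tf_alpha = tf_alpha,
                  min_edge_score = min_edge_score, go_fdr = go_fdr,
                  n_perm = as.integer(n_perm)),
    stages_run = setdiff(c("de", "cluster", "qpcr", "enrichment", "tfbs",
                           "network", "cmap", "cross_species"), skipped),
    stages_skipped = skipped
  )
  class(res) <- "receptivity_run"
  res
}

#' @exportS3Method base::print
print.receptivity_run <- function(x, ...) {
  cat("<receptivity_run>\n")
  cat("stages run:", paste(x$manifest$stages_run, collapse = ", "), "\n")
  if (length(x$manifest$stages_skipped) > 0L) {
    cat("skipped:", paste(x$manifest$stages_skipped, collapse = ", "), "\n")
  }
  tab <- table(x$de$direction)
  cat(sprintf("DE: %d up, %d down of %d genes\n",
              tab[["up"]] %||% 0L, tab[["down"]] %||% 0L, nrow(x$de)))
  invisible(x)
}

#' Write every component of a synthetic bundle to a directory
#'
#' Serializes a [gen_bundle()] result with the package's writers (expression
#' TSV with condition row, promoter FASTA, TRANSFAC-style PWM text, edges /
#' profiles / DE / ortholog / Ct TSVs and a truth table), so a pipeline run
#' can be reproduced from files alone.
#'
#' @param bundle A [gen_bundle()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    promoters = file.path(dir, "promoters.fa"),
    pwms = file.path(dir, "pwms.txt"),
    edges = file.path(dir, "edges.tsv"),
    profiles = file.path(dir, "profiles.tsv"),
    mouse_de = file.path(dir, "mouse_de.tsv"),
    human_de = file.path(dir, "human_de.tsv"),
    orthologs = file.path(dir, "orthologs.tsv"),
    ct = file.path(dir, "ct_values.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_table(bundle$expression, paths["expression"], "expression")
  write_fasta(bundle$promoters, paths["promoters"])
  write_pwm_library(list(bundle$pwm), paths["pwms"])
  write_table(bundle$network, paths["edges"], "edges")
  write_table(bundle$profiles, paths["profiles"], "ranked_profile")
  write_table(bundle$species$mouse_de, paths["mouse_de"], "de_table")
  write_table(bundle$species$human_de, paths["human_de"], "de_table")
  write_table(bundle$species$orthologs, paths["orthologs"], "ortholog_map")
  write_table(bundle$ct, paths["ct"], "ct_values")
  readr::write_tsv(bundle$truth, paths["truth"], progress = FALSE)
  invisible(paths)
}
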