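#' Convert a PWM to a scored (log-odds) matrix with score bounds
#'
#' Adds a pseudocount to every cell, column-normalizes to frequencies, and
#' takes `log2(freq / background)` per base. The minimum and maximum
#' attainable window scores (`s_min`, `s_max`: sums of per-column minima and
#' maxima) anchor the min-max relative score used in scanning.
#'
#' @param pwm A `pwm` object (counts or frequencies).
#' @param background Base frequencies for A,C,G,T (default uniform 0.25);
#'   must sum to 1 within 1e-9.
#' @param pseudocount Added to each cell before normalization (default 0.01).
#' @return Object of class `scored_pwm`: `tf_name`, `log_odds` (4 x L),
#'   `s_min`, `s_max`, `background`, `pseudocount`.
#' @export
score_pwm <- function(pwm, background = rep(0.25, 4), pseudocount = 0.01) {
  stopifnot(inherits(pwm, "pwm"))
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-9 ||
      any(background <= 0)) {
    abort("background must be 4 positive frequencies summing to 1")
  }
  m <- pwm$matrix + pseudocount
  freq <- sweep(m, 2, colSums(m), "/")
  log_odds <- log2(freq / background)
  structure(
    list(tf_name = pwm$tf_name, log_odds = log_odds,
         s_min = sum(apply(log_odds, 2, min)),
         s_max = sum(apply(log_odds, 2, max)),
         background = background, pseudocount = pseudocount),
    class = "scored_pwm"
  )
}

#' Scan one promoter sequence for PWM hits
#'
#' Scores every window on the forward strand and (by default) the reverse
#' strand with the log-odds matrix, min-max normalizes to the relative score
#' `(S - s_min) / (s_max - s_min)`, and emits hits with relative score at or
#' above the cutoff. Windows containing `N` are skipped. Reverse-strand hits
#' are reported at their 1-based start position on the supplied (forward)
#' sequence.
#'
#' @param seq Promoter sequence (string over A,C,G,T,N).
#' @param spwm A `scored_pwm`.
#' @param cutoff Relative-score cutoff in \[0, 1\] (default 0.9).
#' @param strand `"both"` (default) or `"forward"`.
#' @return Tibble of hits: `position`, `strand`, `rel_score`, `score`.
#' @export
scan_promoter <- function(seq, spwm, cutoff = 0.9,
                          strand = c("both", "forward")) {
  strand <- match.arg(strand)
  stopifnot(inherits(spwm, "scored_pwm"))
  L <- ncol(spwm$log_odds)
  codes <- match(strsplit(toupper(seq), "")[[1L]], c("A", "C", "G", "T"))
  if (length(codes) < L) {
    return(tibble::tibble(position = integer(0), strand = character(0),
                          rel_score = numeric(0), score = numeric(0)))
  }
  hits <- list(window_hits(codes, spwm$log_odds, spwm, cutoff, "+"))
  if (strand == "both") {
    # scoring the forward sequence with the reverse-complemented matrix finds
    # minus-strand sites at the same forward coordinates
    lo_rc <- spwm$log_odds[4:1, ncol(spwm$log_odds):1, drop = FALSE]
    rownames(lo_rc) <- c("A", "C", "G", "T")
    hits <- c(hits, list(window_hits(codes, lo_rc, spwm, cutoff, "-")))
  }
  dplyr::arrange(dplyr::bind_rows(hits), .data$position, .data$strand)
}

window_hits <- function(codes, lo, spwm, cutoff, strand_label) {
  L <- ncol(lo)
  n_win <- length(codes) - L + 1L
  s <- numeric(n_win)
  valid <- rep(TRUE, n_win)
  for (j in seq_len(L)) {
    b <- codes[j:(j + n_win - 1L)]
    valid <- valid & !is.na(b)
    s <- s + ifelse(is.na(b), 0, lo[cbind(b, j)])
  }
  rel <- (s - spwm$s_min) / (spwm$s_max - spwm$s_min)
  idx <- which(valid & rel >= cutoff)
  tibble::tibble(position = idx, strand = strand_label,
                 rel_score = rel[idx], score = s[idx])
}

#' Scan a promoter set with a PWM library
#'
#' @param promoters A `promoter_set`.
#' @param pwms List of `pwm` or `scored_pwm` objects (single objects are
#'   accepted).
#' @inheritParams scan_promoter
#' @param background,pseudocount Passed to [score_pwm()] for unscored PWMs.
#' @return Tibble of hits: `gene_id`, `tf_name`, `position`, `strand`,
#'   `rel_score`, `score`.
#' @export
scan_promoters <- function(promoters, pwms, cutoff = 0.9,
                           strand = c("both", "forward"),
                           background = rep(0.25, 4), pseudocount = 0.01) {
  strand <- match.arg(strand)
  spwms <- as_scored_pwms(pwms, background, pseudocount)
  dplyr::bind_rows(purrr::map(spwms, function(sp) {
    per_gene <- purrr::map2(promoters$gene_id, promoters$sequence, function(g, s) {
      h <- scan_promoter(s, sp, cutoff, strand)
      if (nrow(h) > 0L) dplyr::mutate(h, gene_id = g, tf_name = sp$tf_name)
    })
    dplyr::bind_rows(per_gene)
  })) |>
    dplyr::select(dplyr::any_of(c("gene_id", "tf_name", "position", "strand",
                                  "rel_score", "score")))
}

as_scored_pwms <- function(pwms, background, pseudocount) {
  if (inherits(pwms, c("pwm", "scored_pwm"))) pwms <- list(pwms)
  purrr::map(pwms, function(p) {
    if (inherits(p, "scored_pwm")) p else score_pwm(p, background, pseudocount)
  })
}

#' Per-TF promoter site presence across a gene universe
#'
#' Scans every background gene's promoter once per TF and records which genes
#' carry at least one hit — the presence/absence indicator the hypergeometric
#' TFBS enrichment is built on (a gene counts once per TF no matter how many
#' sites it has).
#'
#' @inheritParams scan_promoters
#' @param background_genes Gene universe; every gene must have a promoter.
#' @return Named list: TF name -> character vector of genes with >= 1 site.
#' @export
tf_site_genes <- function(promoters, pwms, background_genes, cutoff = 0.9,
                          strand = c("both", "forward"),
                          background = rep(0.25, 4), pseudocount = 0.01) {
  strand <- match.arg(strand)
  missing <- setdiff(background_genes, promoters$gene_id)
  if (length(missing) > 0L) {
    abort(paste0("no promoter for background gene(s): ",
                 paste(head(missing, 5L), collapse = ", ")))
  }
  sub <- promoters[match(background_genes, promoters$gene_id), ]
  hits <- scan_promoters(sub, pwms, cutoff, strand, background, pseudocount)
  spwms <- as_scored_pwms(pwms, background, pseudocount)
  out <- stats::setNames(
    vector("list", length(spwms)),
    vapply(spwms, function(p) p$tf_name, character(1))
  )
  for (nm in names(out)) out[[nm]] <- character(0)
  if (nrow(hits) > 0L) {
    by_tf <- split(hits$gene_id, hits$tf_name)
    for (nm in names(by_tf)) out[[nm]] <- unique(by_tf[[nm]])
  }
  out
}

#' TFBS enrichment in up- and down-regulated gene sets
#'
#' For each transcription factor, tests whether promoters of the up-regulated
#' (and, separately, down-regulated) genes carry its binding site more often
#' than expected from the background universe, via the upper-tail
#' hypergeometric test with N = background size, K = background genes with a
#' site, n = direction-set size, k = direction genes with a site. A TF with
#' no site anywhere (K = 0) gets p = 1. P-values are reported raw against
#' `alpha` (default 0.01) to match the conventional per-TF criterion; set
#' `bh = TRUE` to flag on Benjamini-Hochberg q-values instead.
#'
#' @inheritParams tf_site_genes
#' @param up_genes,down_genes Direction gene sets (subsets of
#'   `background_genes`).
#' @param alpha Per-direction significance cutoff (default 0.01, strict `<`).
#' @param bh Apply BH correction across TFs within each direction.
#' @param site_genes Optional precomputed [tf_site_genes()] result, reused to
#'   avoid rescanning when testing several query sets.
#' @return Tibble of class `tf_enrichment`: `tf_name`, `direction`, `N`,
#'   `K`, `n`, `k`, `p_value` (plus `fdr` when `bh`), `enriched`.
#' @export
tf_enrichment <- function(promoters, pwms, up_genes, down_genes,
                          background_genes, cutoff = 0.9, alpha = 0.01,
                          strand = c("both", "forward"), bh = FALSE,
                          site_genes = NULL) {
  strand <- match.arg(strand)
  if (!all(up_genes %in% background_genes) ||
      !all(down_genes %in% background_genes)) {
    abort("up_genes and down_genes must be subsets of background_genes")
  }
  if (is.null(site_genes)) {
    site_genes <- tf_site_genes(promoters, pwms, background_genes, cutoff,
                                strand)
  }
  N <- length(unique(background_genes))
  sets <- list(up = unique(up_genes), down = unique(down_genes))
  out <- dplyr::bind_rows(purrr::imap(sets, function(genes, dir_name) {
    tibble::tibble(
      tf_name = names(site_genes),
      direction = dir_name,
      N = N,
      K = unname(lengths(site_genes)),
      n = length(genes),
      k = unname(vapply(site_genes, function(sg) length(intersect(sg, genes)),
                        integer(1)))
    )
  }))
  out$p_value <- ifelse(out$K == 0L, 1,
                        hypergeom_upper(out$N, out$K, out$n, out$k))
  if (bh) {
    out <- out |>
      dplyr::group_by(.data$direction) |>
      dplyr::mutate(fdr = bh_fdr(.data$p_value)) |>
      dplyr::ungroup()
    out$enriched <- out$fdr < alpha
  } else {
    out$enriched <- out$p_value < alpha
  }
  out <- dplyr::arrange(out, .data$direction, .data$p_value, .data$tf_name)
  class(out) <- unique(c("tf_enrichment", class(out)))
  out
}
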