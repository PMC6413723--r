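#' KS enrichment statistic of a query set in a ranked profile
#'
#' The signed Kolmogorov-Smirnov-style enrichment statistic of the
#' connectivity-map method: with `V` the ascending positions of the `t`
#' query genes in a profile of length `n`,
#' `a = max_j (j/t - V(j)/n)` and `b = max_j (V(j)/n - (j-1)/t)`;
#' the statistic is `a` if `a > b`, else `-b`. Positive values mean the set
#' concentrates near the top of the ranking (rank 1 = most up-regulated by
#' the perturbation), negative near the bottom.
#'
#' @param V Integer positions of the query genes in the ranking (distinct,
#'   in 1..n; sorted internally).
#' @param n Profile length.
#' @return The enrichment statistic, in (-1, 1).
#' @examples
#' ks_enrichment(c(1, 2), 10)    #  0.8: set at the very top
#' ks_enrichment(c(9, 10), 10)   # -0.9: set at the very bottom
#' @export
ks_enrichment <- function(V, n) {
  t <- length(V)
  if (t == 0L) abort("empty query set")
  V <- sort(as.numeric(V))
  if (V[1L] < 1 || V[t] > n || anyDuplicated(V)) {
    abort("V must be distinct positions in 1..n")
  }
  j <- seq_len(t)
  a <- max(j / t - V / n)
  b <- max(V / n - (j - 1) / t)
  if (a > b) a else -b
}

#' Combine up- and down-set KS statistics into a connectivity score
#'
#' If the two statistics have the same sign the drug does not oppose (or
#' mimic) the signature coherently and the score is set to zero; otherwise
#' the score is `ks_up - ks_down`. Negative scores mean the drug reverses
#' the query signature. A zero statistic is treated as opposite-direction
#' (the same-sign rule uses a strict product > 0) so the score is defined
#' everywhere.
#'
#' @param ks_up,ks_down KS enrichment statistics in \[-1, 1\].
#' @return Connectivity score in \[-2, 2\].
#' @examples
#' connectivity_score(0.5, 0.3)     # same sign -> 0
#' connectivity_score(-0.15, 0.072) # -0.222
#' @export
connectivity_score <- function(ks_up, ks_down) {
  if (abs(ks_up) > 1 || abs(ks_down) > 1) abort("KS statistics must lie in [-1, 1]")
  if (ks_up * ks_down > 0) 0 else ks_up - ks_down
}

#' Permutation p-value for an observed connectivity score
#'
#' Draws `n_perm` random disjoint (up, down) gene-set pairs of the observed
#' sizes from the profile's universe, scores each with the same KS /
#' same-sign-zero rule, and reports the add-one two-sided p-value
#' `(1 + #{|score_perm| >= |observed|}) / (n_perm + 1)`, which is bounded
#' below by `1/(n_perm + 1)` and equals 1 when the observed score is 0.
#'
#' @param n Profile length.
#' @param t_up,t_down Query set sizes (`t_up + t_down <= n`).
#' @param observed Observed connectivity score.
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param seed Integer seed.
#' @return Permutation p-value in (0, 1].
#' @export
permutation_p <- function(n, t_up, t_down, observed, n_perm = 1000L,
                          seed = 1L) {
  if (t_up + t_down > n) abort("t_up + t_down must be <= n")
  if (n_perm < 100L) abort("n_perm must be >= 100")
  with_offset_seed(seed, 707L, {
    exceed <- sum(abs(null_scores(n, t_up, t_down, n_perm)) >= abs(observed))
    (1 + exceed) / (n_perm + 1)
  })
}

# n_perm null connectivity scores from random disjoint set pairs
null_scores <- function(n, t_up, t_down, n_perm) {
  vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n, t_up + t_down)
    connectivity_score(
      ks_enrichment(idx[seq_len(t_up)], n),
      ks_enrichment(idx[t_up + seq_len(t_down)], n)
    )
  }, numeric(1))
}

#' Rank drugs by signature reversal with permutation p-values
#'
#' Scores every drug profile against the (up, down) query signature: KS
#' enrichment of each set in the drug's ranking, the same-sign-zero
#' connectivity score, a collection-scaled score (negative and positive
#' scores each divided by their own absolute maximum across the queried
#' drugs, per the original connectivity-map convention), and a permutation
#' p-value per drug. Query genes absent from a profile's universe are
#' dropped for that profile with a message. The table is sorted by ascending
#' permutation p, ties broken by ascending score so the strongest reversers
#' come first.
#'
#' @param profiles A `ranked_profiles` tibble (`drug_id`, `rank`, `gene_id`).
#' @param up,down Disjoint query gene sets.
#' @param n_perm Permutations per drug (default 1000).
#' @param seed Integer seed.
#' @return Tibble of class `connectivity_table`: `drug_id`, `n`, `n_up`,
#'   `n_down`, `ks_up`, `ks_down`, `score`, `scaled_score`, `perm_p`.
#' @export
rank_drugs <- function(profiles, up, down, n_perm = 1000L, seed = 1L) {
  if (length(intersect(up, down)) > 0L) abort("up and down sets must be disjoint")
  profiles <- validate_ranked_profiles(profiles)
  per_drug <- split(profiles, profiles$drug_id)
  with_offset_seed(seed, 808L, {
    rows <- purrr::imap(per_drug, function(pr, drug) {
      pos <- stats::setNames(pr$rank, pr$gene_id)
      up_in <- intersect(up, pr$gene_id)
      down_in <- intersect(down, pr$gene_id)
      dropped <- (length(up) - length(up_in)) + (length(down) - length(down_in))
      if (dropped > 0L) {
        inform(sprintf("drug %s: %d query gene(s) absent from profile, dropped",
                       drug, dropped))
      }
      if (length(up_in) == 0L || length(down_in) == 0L) {
        abort(sprintf("drug %s: a query set has no genes in the profile", drug))
      }
      n <- nrow(pr)
      ks_u <- ks_enrichment(pos[up_in], n)
      ks_d <- ks_enrichment(pos[down_in], n)
      sc <- connectivity_score(ks_u, ks_d)
      exceed <- sum(abs(null_scores(n, length(up_in), length(down_in),
                                    n_perm)) >= abs(sc))
      tibble::tibble(
        drug_id = drug, n = n,
        n_up = length(up_in), n_down = length(down_in),
        ks_up = ks_u, ks_down = ks_d, score = sc,
        perm_p = (1 + exceed) / (n_perm + 1)
      )
    })
    out <- dplyr::bind_rows(rows)
    max_neg <- max(abs(out$score[out$score < 0]), 0)
    max_pos <- max(out$score[out$score > 0], 0)
    out$scaled_score <- dplyr::case_when(
      out$score < 0 ~ out$score / max_neg,
      out$score > 0 ~ out$score / max_pos,
      TRUE ~ 0
    )
    out <- dplyr::arrange(out, .data$perm_p, .data$score, .data$drug_id)
    class(out) <- unique(c("connectivity_table", class(out)))
    out
  })
}
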