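uniform_pwm <- function(L = 4) {
  new_pwm("flat", matrix(5, 4, L))
}

test_that("log-odds scoring has the stated closed-form behavior", {
  sp <- score_pwm(uniform_pwm())
  expect_true(all(abs(sp$log_odds) < 1e-12))

  # consensus-only column, pseudocount -> 0: log-odds of the consensus -> 2
  cons <- new_pwm("cons", matrix(rep(c(100, 0, 0, 0), 4), 4, 4))
  sp2 <- score_pwm(cons, pseudocount = 1e-9)
  expect_equal(unname(sp2$log_odds["A", 1]), 2, tolerance = 1e-6)

  expect_error(score_pwm(uniform_pwm(), background = c(0.5, 0.5, 0.1, 0.1)),
               "summing to 1")
})

test_that("score bounds match the exhaustive window oracle", {
  set.seed(5)
  for (L in c(4, 5, 6)) {
    m <- matrix(rpois(4 * L, 6) + 0.0, 4, L)
    m[1, ] <- m[1, ] + 5  # give it some skew
    sp <- score_pwm(new_pwm("x", m))
    ex <- brute_pwm_extrema(sp$log_odds)
    expect_equal(sp$s_min, unname(ex["min"]), tolerance = 1e-12)
    expect_equal(sp$s_max, unname(ex["max"]), tolerance = 1e-12)
    expect_gt(sp$s_max, sp$s_min)
  }
})

test_that("scanning finds the consensus at rel score 1 on either strand", {
  pwm <- example_pwm()
  sp <- score_pwm(pwm)
  consensus <- "GGATTACA"
  seq <- paste0("TTTTTTTTTT", consensus, "TTTTTTTTTT")
  hits <- scan_promoter(seq, sp, 0.9)
  plus <- hits[hits$strand == "+", ]
  expect_equal(plus$position, 11)
  expect_equal(plus$rel_score, 1)

  # reverse complement planted: hit on "-" at the same forward coordinate
  rc <- chartr("ACGT", "TGCA",
               paste(rev(strsplit(consensus, "")[[1]]), collapse = ""))
  seq2 <- paste0("TTTTTTTTTT", rc, "TTTTTTTTTT")
  hits2 <- scan_promoter(seq2, sp, 0.9)
  minus <- hits2[hits2$strand == "-", ]
  expect_equal(minus$position, 11)
  expect_equal(minus$rel_score, 1)
  expect_equal(nrow(scan_promoter(seq2, sp, 0.9, strand = "forward")), 0)
})

test_that("rel score is within [0,1] and windows with N are skipped", {
  sp <- score_pwm(example_pwm())
  set.seed(8)
  seq <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  hits <- scan_promoter(seq, sp, cutoff = 0)
  expect_true(all(hits$rel_score >= 0 & hits$rel_score <= 1))
  # scores of 1 only at per-column argmax windows
  expect_true(all(vapply(hits$position[hits$rel_score == 1 & hits$strand == "+"],
                         function(p) substr(seq, p, p + 7) == "GGATTACA",
                         logical(1))))

  # at cutoff 0 every valid window is emitted; windows covering an N are not
  n_seq <- paste0("ACGNACGT", strrep("A", 20))   # N at position 4, length 28
  hits_n <- scan_promoter(n_seq, sp, cutoff = 0)
  expect_true(all(hits_n$position > 4))          # starts 1..4 cover the N
  expect_equal(sum(hits_n$strand == "+"), (28 - 8 + 1) - 4)
  expect_equal(nrow(scan_promoter(strrep("N", 30), sp, 0)), 0)
})

test_that("strand symmetry: scanning the reverse complement mirrors hits", {
  sp <- score_pwm(example_pwm())
  set.seed(9)
  seq <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
  h1 <- scan_promoter(seq, sp, 0.7)
  h2 <- scan_promoter(rc, sp, 0.7)
  expect_equal(nrow(h1), nrow(h2))
  expect_equal(sort(h1$rel_score), sort(h2$rel_score), tolerance = 1e-12)
  expect_equal(sum(h1$strand == "+"), sum(h2$strand == "-"))
})

test_that("null scan hit probability per 1 kb promoter is low at cutoff 0.9", {
  sp <- score_pwm(example_pwm())
  hit <- vapply(1:100, function(s) {
    ps <- gen_promoters(1, 1000, seed = s)
    nrow(scan_promoter(ps$sequence, sp, 0.9)) > 0
  }, logical(1))
  expect_lt(mean(hit), 0.3)
})

test_that("tf_enrichment composes the hypergeometric on site indicators", {
  pwm <- example_pwm()
  bg <- synth_gene_ids(200)
  up <- bg[1:30]
  ps <- gen_promoters(200, 500, pwm, target_genes = up[1:24],
                      sites_per_target = 2, seed = 2)
  sites <- tf_site_genes(ps, pwm, bg)
  res <- tf_enrichment(ps, pwm, up, bg[31:50], bg, site_genes = sites)
  row_up <- res[res$direction == "up", ]
  expect_equal(row_up$p_value,
               hypergeom_upper(row_up$N, row_up$K, row_up$n, row_up$k))
  expect_true(row_up$enriched)
  expect_lt(row_up$p_value, 0.01)

  # a gene in the background without a promoter is an error naming it
  expect_error(tf_enrichment(ps[-1, ], pwm, up[-1], bg[31:50], bg), "g0001")

  # TF with zero sites anywhere: p = 1, never enriched
  never <- new_pwm("never", matrix(c(25, 0.1, 0.1, 0.1), 4, 12))
  res0 <- tf_enrichment(ps, never, up, bg[31:50], bg, cutoff = 0.999)
  expect_equal(res0$p_value, c(1, 1))
  expect_false(any(res0$enriched))
})
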