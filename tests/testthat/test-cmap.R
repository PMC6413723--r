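test_that("KS enrichment matches direct formula evaluation on worked cases", {
  expect_equal(ks_enrichment(c(1, 2), 10), 0.8)
  expect_equal(ks_enrichment(c(9, 10), 10), -0.9)
  # query = whole universe: forced V(j) = j, es = -1/n
  expect_equal(ks_enrichment(1:10, 10), -0.1)
  expect_error(ks_enrichment(integer(0), 10), "empty")
  expect_error(ks_enrichment(c(1, 1), 10), "distinct")
  expect_error(ks_enrichment(c(0, 5), 10), "1..n")
})

test_that("KS enrichment matches the brute-force running-sum oracle", {
  n <- 12
  for (t in 1:n) {
    placements <- utils::combn(n, t)
    for (col in seq_len(ncol(placements))) {
      V <- placements[, col]
      expect_equal(ks_enrichment(V, n), brute_ks(V, n), tolerance = 1e-12,
                   info = paste("V =", paste(V, collapse = ",")))
    }
  }
})

test_that("the same-sign rule zeroes the connectivity score", {
  expect_equal(connectivity_score(0.5, 0.3), 0)
  expect_equal(connectivity_score(-0.4, -0.2), 0)
  expect_equal(connectivity_score(-0.15, 0.072), -0.222)
  # zero treated as opposite direction
  expect_equal(connectivity_score(0, 0.4), -0.4)
  expect_equal(connectivity_score(0.4, 0), 0.4)
  expect_error(connectivity_score(1.5, 0), "\\[-1, 1\\]")
})

test_that("opposite-sign scores are antisymmetric under set swap", {
  set.seed(2)
  for (i in 1:20) {
    u <- runif(1, -1, 1); d <- runif(1, -1, 1)
    if (u * d < 0) {
      expect_equal(connectivity_score(d, u), -connectivity_score(u, d))
    }
  }
})

test_that("permutation p-values respect their bounds and the zero rule", {
  expect_equal(permutation_p(100, 5, 5, observed = 0, n_perm = 100, seed = 1), 1)
  p <- permutation_p(100, 5, 5, observed = 1.99, n_perm = 100, seed = 1)
  expect_equal(p, 1 / 101)
  expect_equal(permutation_p(100, 5, 5, 0.5, 200, seed = 3),
               permutation_p(100, 5, 5, 0.5, 200, seed = 3))
  expect_error(permutation_p(10, 6, 6, 0.5, 100, 1), "<= n")
  expect_error(permutation_p(100, 5, 5, 0.5, 10, 1), ">= 100")
})

test_that("null permutation p-values are valid (never anti-conservative)", {
  # the same-sign rule puts an atom of null scores at exactly 0, which makes
  # the p-value distribution conservative (a spike at p = 1), so validity --
  # P(p <= a) <= a -- is the calibration property to check, not two-sided
  # uniformity
  ps <- vapply(1:200, function(s) {
    pr <- gen_drug_profiles(1, 60, synth_gene_ids(60)[1:8],
                            synth_gene_ids(60)[9:16], "drug_01",
                            effect = 1e-9, seed = s)
    rd <- rank_drugs(pr, synth_gene_ids(60)[17:24], synth_gene_ids(60)[25:32],
                     n_perm = 100, seed = s)
    rd$perm_p
  }, numeric(1))
  anti_conservative <- max(seq_along(ps) / length(ps) - sort(ps))
  expect_lt(anti_conservative, 0.1)
  expect_lte(mean(ps <= 0.05), 0.10)
  expect_lte(mean(ps <= 0.2), 0.30)
})

test_that("rank_drugs recovers a planted reverser and orders by perm_p", {
  up <- synth_gene_ids(300)[1:30]
  down <- synth_gene_ids(300)[31:55]
  firsts <- vapply(1:5, function(s) {
    pr <- gen_drug_profiles(20, 300, up, down, "drug_07", effect = 0.8,
                            seed = s)
    rd <- rank_drugs(pr, up, down, n_perm = 500, seed = s)
    expect_true(all(diff(rd$perm_p) >= 0))
    expect_true(all(abs(rd$scaled_score) <= 1 + 1e-12))
    rd$drug_id[1]
  }, character(1))
  expect_true(all(firsts == "drug_07"))
})

test_that("swapping the query sets negates every score", {
  up <- synth_gene_ids(200)[1:20]
  down <- synth_gene_ids(200)[21:40]
  pr <- gen_drug_profiles(6, 200, up, down, "drug_03", effect = 0.8, seed = 11)
  a <- rank_drugs(pr, up, down, n_perm = 100, seed = 1)
  b <- rank_drugs(pr, down, up, n_perm = 100, seed = 1)
  merged <- dplyr::inner_join(a, b, by = "drug_id")
  expect_equal(merged$score.y, -merged$score.x, tolerance = 1e-12)

  expect_error(rank_drugs(pr, up, c(down, up[1]), 100, 1), "disjoint")
})

test_that("query genes absent from a profile are dropped with a message", {
  up <- synth_gene_ids(100)[1:10]
  down <- synth_gene_ids(100)[11:20]
  pr <- gen_drug_profiles(2, 100, up, down, "drug_01", effect = 0.8, seed = 1)
  expect_message(
    rd <- rank_drugs(pr, c(up, "ghost_gene"), down, n_perm = 100, seed = 1),
    "absent"
  )
  expect_equal(unique(rd$n_up), 10)
})
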