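test_that("gen_expression plants the requested structure deterministically", {
  spec <- synth_spec(1, 1000, 316, 225)
  b <- gen_expression(spec)
  expect_equal(dim(as.matrix(b$expression[-1])), c(1000, 6))
  expect_equal(sum(b$truth$direction != "unchanged"), 541)
  expect_equal(sum(b$truth$direction == "up"), 316)

  b2 <- gen_expression(spec)
  expect_identical(as.matrix(b$expression[-1]), as.matrix(b2$expression[-1]))

  expect_error(gen_expression(synth_spec(1, 10, 6, 5)), "n_genes")
})

test_that("noiseless expression reproduces the planted effect exactly", {
  spec <- synth_spec(3, 50, 5, 5, log2_effect = 2, noise_sd = 0)
  b <- gen_expression(spec)
  de <- call_de(b$expression, epsilon = 1e-9)
  up <- b$truth$gene_id[b$truth$direction == "up"]
  expect_equal(de$log2fc[match(up, de$gene_id)], rep(2, 5), tolerance = 1e-6)
})

test_that("gen_promoters plants recoverable consensus sites", {
  pwm <- example_pwm()
  ps <- gen_promoters(20, 200, pwm, target_genes = "g0003",
                      sites_per_target = 1, seed = 5, consensus_only = TRUE)
  expect_equal(nrow(ps), 20)
  expect_true(all(nchar(ps$sequence) == 200))

  planted <- attr(ps, "planted_sites")
  hits <- scan_promoter(ps$sequence[ps$gene_id == "g0003"], score_pwm(pwm), 0.9)
  hit_at_planted <- hits[hits$position == planted$position, ]
  expect_equal(nrow(hit_at_planted), 1)
  expect_equal(hit_at_planted$rel_score, 1.0)
  expect_equal(hit_at_planted$strand, planted$strand)

  ps2 <- gen_promoters(20, 200, pwm, "g0003", 1, seed = 5,
                       consensus_only = TRUE)
  expect_identical(ps$sequence, ps2$sequence)

  bg <- gen_promoters(5, 100, seed = 2)
  expect_false(any(grepl("N", bg$sequence)))

  expect_error(gen_promoters(5, 30, pwm, target_genes = "g0001",
                             sites_per_target = 10, seed = 1),
               "non-overlapping")
})

test_that("gen_network grows the forced edge count and a heavy-tailed degree", {
  net <- gen_network(289, 2, seed = 1)
  expect_equal(nrow(net), 2 * (289 - 2))
  g <- igraph::graph_from_data_frame(net[1:2], directed = FALSE)
  expect_true(igraph::is_connected(g))
  expect_true(all(net$combined_score >= 0.4 & net$combined_score <= 1))
  expect_identical(net, gen_network(289, 2, seed = 1))

  slopes <- vapply(1:20, function(s) {
    degree_stats(gen_network(289, 2, seed = s))$powerlaw_slope
  }, numeric(1))
  expect_true(all(slopes < -1))
})

test_that("gen_drug_profiles plants a reverser at the stated strength", {
  up <- synth_gene_ids(100)[1:10]
  down <- synth_gene_ids(100)[11:20]
  pr <- gen_drug_profiles(5, 100, up, down, "drug_02", effect = 1, seed = 1)
  rev_pr <- pr[pr$drug_id == "drug_02", ]
  pos <- stats::setNames(rev_pr$rank, rev_pr$gene_id)
  expect_true(max(pos[down]) < min(pos[up]))

  expect_identical(pr, gen_drug_profiles(5, 100, up, down, "drug_02",
                                         effect = 1, seed = 1))
  expect_error(gen_drug_profiles(5, 100, up, c(down, up[1]), "drug_01",
                                 seed = 1), "disjoint")
})

test_that("gen_species_pair bookkeeping mirrors the requested design", {
  sp <- gen_species_pair(115, 25, 50, 20, 20, 426, 1994, seed = 1)
  expect_equal(nrow(sp$mouse_de), 541)
  expect_equal(nrow(sp$human_de), 2109)
  expect_equal(nrow(sp$orthologs), nrow(sp$mouse_de))
  expect_error(gen_species_pair(100, 25, 50, 20, 20, 1, 1, seed = 1),
               "sum")
})

test_that("gen_ct_values inverts exactly without noise and is seeded", {
  ct <- gen_ct_values(c(gA = 4), noise_sd = 0, seed = 1)
  fc <- ddct_fold_change(ct)
  expect_equal(fc$ddct, -2)
  expect_equal(fc$fold_change, 4)

  expect_identical(gen_ct_values(c(gA = 2, gB = 0.5), seed = 9),
                   gen_ct_values(c(gA = 2, gB = 0.5), seed = 9))
  expect_error(gen_ct_values(c(gA = -1), seed = 1), "positive")
})

test_that("noisy Ct recovery correlates tightly with planted fold changes", {
  fcs <- stats::setNames(2^seq(log2(0.1), log2(70), length.out = 10),
                         paste0("g", 1:10))
  rs <- vapply(1:10, function(s) {
    ct <- gen_ct_values(fcs, noise_sd = 0.1, seed = s)
    rec <- ddct_fold_change(ct)
    cor(log2(fcs[rec$gene_id]), rec$log2fc)
  }, numeric(1))
  expect_true(all(rs > 0.99))
})
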