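test_that("fold change is stabilized, antisymmetric, and handles zeros", {
  fc <- fold_change(10, 40, epsilon = 0.5)
  expect_equal(fc$fold_change, 40.5 / 10.5)
  expect_equal(fc$log2fc, log2(40.5 / 10.5))

  swapped <- fold_change(40, 10, epsilon = 0.5)
  expect_equal(swapped$log2fc, -fc$log2fc)

  expect_equal(fold_change(7, 7)$fold_change, 1)
  expect_equal(fold_change(0, 0)$fold_change, 1)
  expect_error(fold_change(-1, 2), ">= 0")
  expect_error(fold_change(1, 2, epsilon = 0), "> 0")
})

test_that("welch_t matches an independent reference and is symmetric", {
  # frozen from scipy.stats.ttest_ind([1,2,3],[4,5,6], equal_var=False)
  expect_equal(welch_t(c(1, 2, 3), c(4, 5, 6)), 0.021311641128757,
               tolerance = 1e-10)
  expect_equal(welch_t(c(4, 5, 6), c(1, 2, 3)),
               welch_t(c(1, 2, 3), c(4, 5, 6)))
  g <- c(2.2, 3.1, 4.7)
  expect_equal(welch_t(g, g), 1)
  expect_equal(welch_t(c(1, 1, 1), c(2, 2, 2)), 0)
  expect_error(welch_t(1, c(1, 2)), ">= 2")
})

make_expr <- function(vals_a, vals_b, ids = NULL) {
  n <- nrow(vals_a)
  ids <- ids %||% paste0("g", seq_len(n))
  samples <- c(paste0("a", seq_len(ncol(vals_a))),
               paste0("b", seq_len(ncol(vals_b))))
  x <- tibble::tibble(gene_id = ids,
                      !!!stats::setNames(
                        as.data.frame(cbind(vals_a, vals_b)), samples))
  new_expression_matrix(x, stats::setNames(
    rep(c("A", "B"), c(ncol(vals_a), ncol(vals_b))), samples))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("call_de applies strict cutoffs and partitions the gene set", {
  # gene 1 strongly up, gene 2 at exactly fold change 2 (boundary), gene 3
  # flat, gene 4 all-zero
  a <- rbind(c(10, 10, 10), c(19.5, 19.5, 19.5), c(5, 5.2, 4.8), c(0, 0, 0))
  b <- rbind(c(100, 105, 95), c(39.5, 39.5, 39.5), c(5.1, 4.9, 5), c(0, 0, 0))
  de <- call_de(make_expr(a, b))
  expect_equal(de$direction, c("up", "unchanged", "unchanged", "unchanged"))
  expect_equal(de$fold_change[2], 2)          # (39.5+0.5)/(19.5+0.5)
  expect_equal(de$p_value[4], 1)
  expect_equal(de$fold_change[4], 1)
  expect_equal(nrow(de), 4)
  expect_setequal(unique(de$direction), c("up", "unchanged"))
})

test_that("condition swap maps up onto down and preserves p-values", {
  b <- gen_expression(synth_spec(11, 200, 30, 20))
  de1 <- call_de(b$expression)
  cond <- conditions_of(b$expression)
  # the baseline condition is the first to appear in sample order, so putting
  # the day-4 samples first exchanges the roles of the two conditions
  reordered <- c("gene_id", names(cond)[cond == "day4"],
                 names(cond)[cond == "day3"])
  de2 <- call_de(tibble::as_tibble(b$expression)[reordered],
                 conditions = cond)
  expect_equal(de2$p_value, de1$p_value, tolerance = 1e-12)
  expect_setequal(de2$gene_id[de2$direction == "up"],
                  de1$gene_id[de1$direction == "down"])
  expect_setequal(de2$gene_id[de2$direction == "down"],
                  de1$gene_id[de1$direction == "up"])
})

test_that("relaxing either cutoff never shrinks the DE set", {
  b <- gen_expression(synth_spec(13, 300, 40, 30))
  strict <- call_de(b$expression, fc_cutoff = 2, p_cutoff = 0.05)
  lax_p <- call_de(b$expression, fc_cutoff = 2, p_cutoff = 0.2)
  lax_fc <- call_de(b$expression, fc_cutoff = 1.5, p_cutoff = 0.05)
  de_set <- function(d) d$gene_id[d$direction != "unchanged"]
  expect_true(all(de_set(strict) %in% de_set(lax_p)))
  expect_true(all(de_set(strict) %in% de_set(lax_fc)))
})

test_that("BH-adjusted calling is more conservative than raw calling", {
  b <- gen_expression(synth_spec(17, 300, 40, 30))
  raw <- call_de(b$expression)
  adj <- call_de(b$expression, adjust = "BH", p_cutoff = 0.01)
  expect_true(sum(adj$direction != "unchanged") <=
                sum(raw$direction != "unchanged"))
  expect_true(all(adj$p_adj >= adj$p_value))
})

test_that("UPGMA merge heights match the brute-force recursion", {
  set.seed(42)
  m <- matrix(rnorm(6 * 8), nrow = 6,
              dimnames = list(paste0("g", 1:6), NULL))
  co <- cluster_order(m)
  d <- 1 - cor(t(m))
  expect_equal(sort(co$gene_hclust$height),
               brute_upgma_heights(as.dist(d)), tolerance = 1e-12)

  # distance bounds of 1 - r: identical rows at 0, a row and its negation at 2
  x <- rnorm(10)
  m3 <- rbind(a = x, b = x + rnorm(10, 0, 2), c = -x)
  d3 <- 1 - cor(t(m3))
  expect_equal(d3["a", "c"], 2, tolerance = 1e-12)
  co3 <- cluster_order(m3)
  expect_equal(max(co3$gene_hclust$height), max(brute_upgma_heights(as.dist(d3))))
})

test_that("cluster_order drops zero-variance genes and errors when too few", {
  m <- rbind(g1 = c(1, 1, 1, 1), g2 = c(1, 2, 3, 4), g3 = c(4, 3, 2, 1))
  expect_warning(co <- cluster_order(m), "zero-variance")
  expect_setequal(co$gene_order, c("g2", "g3"))
  expect_error(suppressWarnings(cluster_order(m[1:2, ])), ">= 2")
})
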