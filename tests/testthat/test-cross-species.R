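de_tbl <- function(ids, l2fc) {
  tibble::tibble(gene_id = ids, log2fc = l2fc,
                 p_value = rep(0.01, length(ids)))
}

test_that("overlap splits DE genes into shared and exclusive sets", {
  mouse <- de_tbl(c("m1", "m2", "m3"), c(1, -1, 2))
  human <- de_tbl(c("h1", "h2", "h4"), c(1, 1, -2))
  orth <- tibble::tibble(mouse_gene = c("m1", "m2", "m3"),
                         human_gene = c("h1", "h2", "h3"))
  ov <- overlap_de(mouse, human, orth)
  expect_equal(unname(ov$counts), c(2, 1, 1))
  expect_setequal(ov$shared$mouse_gene, c("m1", "m2"))
  expect_equal(ov$mouse_only, "m3")
  expect_equal(ov$human_only, "h4")

  # identity mapping, identical sets: all shared
  ident <- tibble::tibble(mouse_gene = c("g1", "g2"), human_gene = c("g1", "g2"))
  ov2 <- overlap_de(de_tbl(c("g1", "g2"), c(1, 1)),
                    de_tbl(c("g1", "g2"), c(1, -1)), ident)
  expect_equal(unname(ov2$counts), c(2, 0, 0))

  # disjoint: nothing shared
  ov3 <- overlap_de(mouse, de_tbl("hx", 1), orth)
  expect_equal(unname(ov3$counts["shared"]), 0)
})

test_that("many-to-many ortholog rows are rejected with offenders named", {
  orth <- tibble::tibble(mouse_gene = c("m1", "m1"), human_gene = c("h1", "h2"))
  expect_error(overlap_de(de_tbl("m1", 1), de_tbl("h1", 1), orth), "m1")
})

test_that("classification follows the sign pairs", {
  shared <- tibble::tibble(
    mouse_gene = c("a", "b", "c", "d"), human_gene = c("A", "B", "C", "D"),
    mouse_log2fc = c(-1.2, 0.8, -0.5, 2.0),
    human_log2fc = c(-0.8, 1.5, 0.9, -0.5)
  )
  cl <- classify_concordance(shared)
  expect_equal(unname(cl$counts), c(1, 1, 1, 1))
  expect_equal(cl$pairs$category[1], "consistent_down")
  expect_equal(cl$pairs$category[4], "mouse_up_human_down")
  expect_equal(cl$n_consistent + cl$n_inconsistent, nrow(shared))

  shared$mouse_log2fc[1] <- 0
  expect_error(classify_concordance(shared), "zero")
})

test_that("planted categories round-trip through overlap and classify", {
  sp <- gen_species_pair(115, 25, 50, 20, 20, 426, 1994, seed = 3)
  ov <- overlap_de(sp$mouse_de, sp$human_de, sp$orthologs)
  expect_equal(unname(ov$counts), c(115, 426, 1994))
  cl <- classify_concordance(ov$shared)
  expect_equal(unname(cl$counts), c(25, 50, 20, 20))
  expect_equal(sum(cl$counts), nrow(ov$shared))
})

test_that("species swap transposes the inconsistent categories", {
  sp <- gen_species_pair(40, 10, 10, 15, 5, 5, 5, seed = 2)
  ov <- overlap_de(sp$mouse_de, sp$human_de, sp$orthologs)
  cl <- classify_concordance(ov$shared)
  swapped <- tibble::tibble(
    mouse_gene = ov$shared$human_gene, human_gene = ov$shared$mouse_gene,
    mouse_log2fc = ov$shared$human_log2fc,
    human_log2fc = ov$shared$mouse_log2fc
  )
  cl2 <- classify_concordance(swapped)
  expect_equal(cl2$counts[["consistent_down"]], cl$counts[["consistent_down"]])
  expect_equal(cl2$counts[["mouse_down_human_up"]],
               cl$counts[["mouse_up_human_down"]])
  expect_equal(cl2$counts[["mouse_up_human_down"]],
               cl$counts[["mouse_down_human_up"]])
})
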