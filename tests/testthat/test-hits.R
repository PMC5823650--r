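gene_table <- function(genes, p, direction = "depleted") {
  res <- tibble::tibble(gene = genes, k = 3L,
                        Zw = qnorm(1 - p), P_wZP = p,
                        E = p * length(genes), direction = direction,
                        hairpins = "")
  attr(res, "n_genes") <- length(genes)
  class(res) <- c("gene_results", class(res))
  res
}

test_that("hit calling applies a strict threshold to depleted genes", {
  gt <- gene_table(c("A", "B", "C", "D"), c(0.049, 0.050, 0.001, 0.2))
  ht <- call_hits(gt, alpha = 0.05, screen_id = "s1")
  expect_equal(ht$gene, c("C", "A"))  # 0.050 excluded, sorted ascending
  expect_equal(attr(ht, "alpha"), 0.05)
  # enriched genes never enter a synthetic-lethal hit list
  gt2 <- gene_table("E", 0.001, direction = "enriched")
  expect_equal(nrow(call_hits(gt2)), 0)
  expect_equal(nrow(call_hits(gene_table(character(0), numeric(0)))), 0)
})

test_that("screen intersection is a set intersection with per-screen stats", {
  a <- call_hits(gene_table(c("A", "B", "C"), c(0.01, 0.02, 0.03)), screen_id = "s1")
  b <- call_hits(gene_table(c("B", "C", "D"), c(0.02, 0.01, 0.03)), screen_id = "s2")
  cm <- intersect_screens(a, b)
  expect_setequal(cm$gene, c("B", "C"))
  expect_equal(cm$max_P_wZP, pmax(cm$P_wZP_s1, cm$P_wZP_s2))
  # worst-case p ordering
  expect_equal(cm$gene[order(cm$max_P_wZP)], cm$gene)
  # disjoint lists intersect to nothing
  d <- call_hits(gene_table(c("X", "Y"), c(0.01, 0.02)), screen_id = "s3")
  expect_equal(nrow(intersect_screens(a, d)), 0)
  expect_error(intersect_screens(a), "at least two")
})

test_that("intersection is commutative, associative and bounded", {
  withr::with_seed(51, {
    pool <- sprintf("G%03d", 1:40)
    lists <- lapply(1:3, function(i) {
      g <- sample(pool, 20)
      call_hits(gene_table(g, runif(20, 0, 0.04)),
                screen_id = paste0("s", i))
    })
    ab <- intersect_screens(lists[[1]], lists[[2]])
    ba <- intersect_screens(lists[[2]], lists[[1]])
    expect_setequal(ab$gene, ba$gene)
    abc <- intersect_screens(lists)
    expect_setequal(abc$gene,
                    intersect(ab$gene, lists[[3]]$gene))
    expect_lte(nrow(abc), min(vapply(lists, nrow, 0L)))
  })
})

test_that("the packaged twelve-gene fixture intersects exactly", {
  t1 <- common_slic_hits()
  expect_equal(nrow(t1), 12)
  withr::with_seed(52, {
    la <- call_hits(gene_table(sample(c(t1$gene, sprintf("PADA%02d", 1:30))),
                               runif(42, 0, 0.049)), screen_id = "H2228")
    lb <- call_hits(gene_table(sample(c(t1$gene, sprintf("PADB%02d", 1:25))),
                               runif(37, 0, 0.049)), screen_id = "H3122")
  })
  cm <- intersect_screens(la, lb)
  expect_setequal(cm$gene, t1$gene)
  expect_equal(nrow(cm), 12)
  # order-stable: re-running the intersection reproduces the same rows
  expect_identical(cm, intersect_screens(la, lb))
})
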