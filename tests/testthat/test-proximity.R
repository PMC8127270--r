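test_that("proximity window is inclusive below 50 kb and exclusive beyond", {
  el <- data.frame(element_id = "E1", chrom = "chr1",
                   start = 100000, end = 103000)
  genes <- data.frame(
    gene_id = c("inside", "near_up", "far_down"),
    chrom = "chr1",
    start = c(101000, 100000 - 49999 - 1000, 103000 + 50001),
    end = c(101500, 100000 - 49999, 103000 + 50001 + 800),
    stringsAsFactors = FALSE)
  pr <- genes_near_elements(genes, el, window = 50000)
  expect_setequal(pr$gene_id, c("inside", "near_up"))
  expect_equal(pr$distance[pr$gene_id == "inside"], 0)
  expect_equal(pr$distance[pr$gene_id == "near_up"], 49999)
})

test_that("interval-index proximity equals the quadratic scan", {
  set.seed(110)
  for (trial in 1:10) {
    ng <- sample(5:20, 1); ne <- sample(2:8, 1)
    genes <- data.frame(gene_id = sprintf("g%02d", seq_len(ng)),
                        chrom = sample(c("c1", "c2"), ng, TRUE),
                        start = sample.int(3e5, ng))
    genes$end <- genes$start + sample(200:2000, ng, TRUE)
    el <- data.frame(element_id = sprintf("e%02d", seq_len(ne)),
                     chrom = sample(c("c1", "c2"), ne, TRUE),
                     start = sample.int(3e5, ne))
    el$end <- el$start + sample(1500:5000, ne, TRUE)
    got <- genes_near_elements(genes, el, window = 50000)
    want <- brute_force_proximity(genes, el, window = 50000)
    expect_equal(got[, c("gene_id", "element_id", "distance")], want,
                 ignore_attr = TRUE)
  }
})

test_that("expression categories partition RPKM with half-open bounds", {
  x <- c(0, 0.5, 0.999, 1, 9.99, 10, 99.9, 100, 500)
  got <- as.character(categorize_expression(x))
  expect_equal(got, c("not", "not", "not", "low", "low", "medium", "medium",
                      "high", "high"))
  # partition property: every value falls in exactly one class
  set.seed(111)
  v <- rexp(500, 0.05)
  expect_equal(sum(table(categorize_expression(v))), 500)
  expect_error(categorize_expression(-1), "non-negative")
})

test_that("category comparison matches Fisher enumeration", {
  # identical category proportions in both groups: all p = 1
  tab <- cbind(near_expressed = c(not = 10, low = 5, medium = 3, high = 2),
               near_not_expressed = c(20, 10, 6, 4))
  r <- compare_categories(tab)
  expect_equal(r$p, rep(1, 4), tolerance = 1e-9)

  # the 2x2 fixture [[3,1],[1,3]]: two-sided p = 34/70
  p <- stats::fisher.test(matrix(c(3, 1, 1, 3), 2))$p.value
  expect_equal(p, 34 / 70, tolerance = 1e-12)
  expect_equal(enumerate_fisher_two_sided(3, 1, 1, 3), 34 / 70,
               tolerance = 1e-12)

  # extreme table: p < 1e-20
  expect_lt(stats::fisher.test(matrix(c(50, 0, 0, 50), 2))$p.value, 1e-20)

  expect_error(compare_categories(cbind(a = c(1, 0), b = c(0, 0))),
               "non-empty")
})

test_that("Fisher p-values equal hypergeometric enumeration (margins <= 200)", {
  set.seed(112)
  for (trial in 1:40) {
    a <- sample(0:60, 1); b <- sample(0:60, 1)
    c_ <- sample(0:60, 1); d <- sample(0:60, 1)
    if (a + b == 0 || c_ + d == 0 || a + c_ == 0 || b + d == 0) next
    p_pkg <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
    p_or <- enumerate_fisher_two_sided(a, b, c_, d)
    expect_equal(p_pkg, p_or, tolerance = 1e-12)
    p_pkg_g <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                                  alternative = "greater")$p.value
    expect_equal(p_pkg_g, enumerate_fisher_greater(a, b, c_, d),
                 tolerance = 1e-12)
  }
})

test_that("category tests flag planted proximity effects", {
  # genes near expressed elements have 3-fold inflated expression;
  # >= 100 genes per group
  set.seed(113)
  g1 <- rlnorm(150, meanlog = log(8), sdlog = 1)   # boosted group
  g0 <- rlnorm(150, meanlog = log(8 / 3), sdlog = 1)
  tab <- cbind(near_expressed = table(categorize_expression(g1)),
               near_not_expressed = table(categorize_expression(g0)))
  r <- compare_categories(tab)
  expect_true(any(r$significant[r$category %in% c("medium", "high")]))
})

test_that("GO enrichment tests over-representation with BH control", {
  # 10/10 selected genes carry the term vs 12/1000 in the background
  bg <- sprintf("g%04d", 1:1000)
  sel <- bg[1:10]
  ann <- setNames(rep(list("GO:X"), 12), bg[1:12])
  ann <- c(ann, setNames(rep(list("GO:Y"), 988), bg[13:1000]))
  r <- go_enrichment(sel, bg, ann)
  rx <- r[r$term == "GO:X", ]
  expect_true(rx$enriched)
  expect_lt(rx$p, 1e-10)
  expect_equal(enumerate_fisher_greater(10, 0, 2, 988) < 1e-10, TRUE)

  # a term at equal frequency in selection and background is not enriched
  set.seed(114)
  ann2 <- lapply(seq_along(bg), function(i)
    if (i %% 2 == 0) "GO:even" else "GO:odd")
  names(ann2) <- bg
  sel2 <- bg[seq(2, 200, by = 2)]  # all carry GO:even
  r2 <- go_enrichment(bg[1:100], bg, ann2)
  even <- r2[r2$term == "GO:even", ]
  expect_false(even$enriched)
  expect_gt(even$p, 0.2)

  # terms absent from the selection are not tested
  r3 <- go_enrichment(bg[2], bg, ann2)
  expect_false("GO:odd" %in% r3$term)

  expect_error(go_enrichment(character(0), bg, ann2), "empty")
  expect_error(go_enrichment("not_there", bg, ann2), "subset")
})
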