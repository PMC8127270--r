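test_that("read mapping enforces identity and length-fraction thresholds", {
  set.seed(90)
  refA <- rand_dna(2000)
  refs <- Biostrings::DNAStringSet(c(elemA = refA, elemB = rand_dna(2000)))

  # verbatim read: assigned, unique, identity 100%
  read <- substr(refA, 501, 625)
  r1 <- map_reads(Biostrings::DNAStringSet(c(r1 = read)), refs)
  expect_equal(nrow(r1), 1)
  expect_equal(r1$element_id, "elemA")
  expect_equal(r1$identity, 1)
  expect_true(r1$unique)

  # reverse-complement read maps too
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  r1rc <- map_reads(Biostrings::DNAStringSet(c(r1 = rc)), refs)
  expect_equal(r1rc$element_id, "elemA")

  # 15 mismatches in a 100-bp read: identity below 0.9, unassigned
  b <- strsplit(substr(refA, 501, 600), "")[[1]]
  pos <- seq(5, 95, length.out = 15)
  for (h in pos) b[h] <- sample(setdiff(c("A", "C", "G", "T"), b[h]), 1)
  r2 <- map_reads(Biostrings::DNAStringSet(c(bad = paste(b, collapse = ""))),
                  refs)
  expect_equal(nrow(r2), 0)
  expect_equal(attr(r2, "n_unmapped"), 1)

  # read matching two ~95%-identical references: assigned but not unique
  refC <- strsplit(refA, "")[[1]]
  for (h in sample(2000, 100)) refC[h] <- sample(setdiff(c("A", "C", "G", "T"),
                                                         refC[h]), 1)
  refs2 <- Biostrings::DNAStringSet(c(elemA = refA,
                                      elemC = paste(refC, collapse = "")))
  r3 <- map_reads(Biostrings::DNAStringSet(c(r1 = read)), refs2)
  expect_equal(nrow(r3), 1)
  expect_false(r3$unique)
  expect_equal(r3$n_hits, 2)
})

test_that("unique-read fraction is 1 for unrelated reference families", {
  set.seed(91)
  refs <- Biostrings::DNAStringSet(c(a = rand_dna(1500), b = rand_dna(1500),
                                     c = rand_dna(1500)))
  reads <- Biostrings::DNAStringSet(c(
    r1 = substr(as.character(refs[["a"]]), 1, 125),
    r2 = substr(as.character(refs[["b"]]), 701, 825),
    r3 = substr(as.character(refs[["c"]]), 1001, 1125)))
  asn <- map_reads(reads, refs)
  expect_equal(unname(unique_read_fraction(asn)), 1)
})

test_that("average coverage is aligned bases over element length", {
  lens <- c(e1 = 1000, e2 = 500)
  one <- data.frame(element_id = "e1", aligned_bases = 100)
  expect_equal(average_coverage(one, lens)$coverage, c(0.1, 0))
  fifty <- data.frame(element_id = rep("e1", 50), aligned_bases = 100)
  expect_equal(average_coverage(fifty, lens)$coverage[1], 5.0)
  none <- data.frame(element_id = character(0), aligned_bases = numeric(0))
  expect_equal(average_coverage(none, lens)$coverage, c(0, 0))
})

test_that("RPKM matches the closed formula and is scale-invariant", {
  cnt <- matrix(c(10, 0, 100), nrow = 3,
                dimnames = list(c("a", "b", "c"), "L1"))
  lens <- c(a = 1000, b = 2000, c = 5000)
  tot <- c(L1 = 1e6)
  r <- rpkm_matrix(cnt, lens, tot)
  expect_equal(r["a", 1], 10)
  expect_equal(r["b", 1], 0)
  cnt2 <- matrix(100, dimnames = list("x", "L"))
  expect_equal(rpkm_matrix(cnt2, c(x = 5000), c(L = 2e7))[1, 1], 1)
  # doubling every count and the library total leaves RPKM unchanged
  expect_equal(rpkm_matrix(cnt * 2, lens, tot * 2), r)
  expect_error(rpkm_matrix(cnt, lens, c(L1 = 0)), "positive")
})

test_that("expressed calling uses a strict RPKM threshold", {
  m <- rbind(low = c(0.5, 0.5, 0.5), one = c(1.0, 1.0, 1.0),
             hit = c(1.2, 0, 0))
  colnames(m) <- paste0("L", 1:3)
  expect_equal(call_expressed(m), "hit")  # exactly 1.0 everywhere excluded
})

test_that("condition sets build the four-treatment Venn regions", {
  design <- library_design()
  m <- matrix(0, 3, 12, dimnames = list(c("all", "c24", "none"),
                                        design$library))
  m["all", ] <- 5
  m["c24", design$library[design$treatment == "C24"]] <- c(2, 0, 0)
  cs <- condition_sets(m, design)
  expect_true(all(cs$membership["all", ]))
  expect_equal(cs$region_counts[["C24&S24&C48&S48"]], 1)
  expect_equal(unname(cs$membership["c24", ]),
               c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(cs$region_counts[["C24"]], 1)
  expect_equal(cs$region_counts[["none"]], 1)
  # empty matrix -> all counts 0
  cs0 <- condition_sets(m[0, , drop = FALSE], design)
  expect_true(all(cs0$region_counts == 0))
})

test_that("differential expression applies the fold-change and FDR gates", {
  design <- library_design()
  d24 <- design[design$timepoint == 24, ]
  # identical counts in both conditions: FC = 1, ns
  cnt <- matrix(rep(c(50, 60, 70, 50, 60, 70), each = 4), nrow = 4,
                byrow = FALSE, dimnames = list(paste0("e", 1:4), d24$library))
  r <- differential_expression(cnt, design, 24)
  expect_true(all(r$status == "ns"))
  expect_true(all(abs(r$logFC) < 1e-9))

  # a planted 1.5-fold change with overwhelming counts: tiny p-value but
  # gated to ns by |FC| > 2
  set.seed(92)
  n <- 50
  base <- matrix(rnbinom(n * 6, size = 50, mu = 1e4), n, 6,
                 dimnames = list(paste0("e", 1:n), d24$library))
  salt <- d24$condition == "salt"
  base[1, salt] <- rnbinom(3, size = 50, mu = 1.5e4)
  r2 <- differential_expression(base, design, 24)
  expect_lt(r2$pvalue[1], 0.01)
  expect_equal(r2$status[1], "ns")

  # agreement with an independent exact-test implementation at a fixed
  # common dispersion
  suppressMessages(requireNamespace("edgeR"))
  set.seed(93)
  mu <- runif(100, 20, 300)
  cnt3 <- sapply(1:6, function(j)
    rnbinom(100, size = 1 / 0.08, mu = mu * ifelse(j > 3 & seq_len(100) <= 10,
                                                   3, 1)))
  dimnames(cnt3) <- list(paste0("e", 1:100), d24$library)
  mine <- differential_expression(cnt3, design, 24, dispersion = 0.08)
  dg <- edgeR::DGEList(counts = cnt3, group = d24$condition,
                       lib.size = colSums(cnt3))
  dg$samples$norm.factors <- 1
  et <- edgeR::exactTest(dg, dispersion = 0.08, pair = c("control", "salt"))
  expect_gt(cor(-log10(mine$pvalue), -log10(et$table$PValue)), 0.999)
})

test_that("library count sums never exceed the design library size", {
  res <- default_pipeline()
  expect_true(all(colSums(res$counts) <= res$design$size))
})
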