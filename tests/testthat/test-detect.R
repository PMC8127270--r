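test_that("seed repeat finder reports planted repeats and matches brute force", {
  set.seed(21)
  # unique 30-bp repeat at separation ~2000
  R <- rand_dna(30)
  s <- paste0(rand_dna(100), R, rand_dna(1970), R, rand_dna(100))
  seeds <- find_seed_repeats(s, k = 20, max_span = 25000)
  expect_gte(nrow(seeds), 1)
  expect_true(any(seeds$length >= 30 & seeds$pos2 - seeds$pos1 == 2000))

  # no repeated k-mer -> empty
  set.seed(22)
  expect_equal(nrow(find_seed_repeats(rand_dna(300), k = 20,
                                      max_span = 1000)), 0)

  # brute-force all-pairs oracle on small random sequences with planted
  # repeats, and on a poly-A run (maximality merging: one maximal pair per
  # offset)
  for (trial in 1:5) {
    set.seed(30 + trial)
    core <- rand_dna(25)
    s2 <- paste0(rand_dna(60), core, rand_dna(120), core, rand_dna(60),
                 core, rand_dna(30))
    got <- find_seed_repeats(s2, k = 12, max_span = 400)
    want <- brute_force_repeats(s2, k = 12, max_span = 400)
    expect_equal(got, want, ignore_attr = TRUE)
  }
  polyA <- strrep("A", 120)
  got <- find_seed_repeats(polyA, k = 10, max_span = 200, max_occ = 1000)
  want <- brute_force_repeats(polyA, k = 10, max_span = 200)
  expect_equal(got, want, ignore_attr = TRUE)
})

test_that("TSD search honours vicinity, shifts and tie-breaking", {
  params <- detection_params()
  set.seed(40)
  # exact construction: ...ACGTA[element]ACGTA... -> zero shift
  el <- plant_element(rand_dna(50), rand_dna(30), rand_dna(40), rand_dna(30),
                      rand_dna(50), "ACGTA")
  ts <- find_tsd(el$seq, el$start, el$end, params)
  expect_equal(ts$tsd, "ACGTA")
  expect_equal(ts$start, el$start)
  expect_equal(ts$end, el$end)

  # brute-force shift oracle: first (smallest total shift, then leftmost)
  # matching 5-mer pair within the vicinity
  brute_tsd <- function(s, st, en, v = 10, t = 5) {
    for (tot in 0:(2 * v)) for (i in -v:v) for (j in -v:v) {
      if (abs(i) + abs(j) != tot) next
      ls <- st + i; rs <- en + j
      if (ls - t < 0 || rs + t > nchar(s) || ls >= rs) next
      if (substr(s, ls - t + 1, ls) == substr(s, rs + 1, rs + t))
        return(c(i, j))
    }
    NULL
  }

  # a random genome verified (by the oracle) to have no matching 5-mer
  # within +/- 10 bp -> absent
  set.seed(3)
  s <- rand_dna(200)
  expect_null(brute_tsd(s, 60, 140))
  expect_true(is.na(find_tsd(s, 60, 140, params)$tsd))

  # TSD planted so the only minimal match is at shift +3/+3: boundaries
  # move with the shift
  set.seed(1)
  ss <- strsplit(rand_dna(200), "")[[1]]
  st <- 60; en <- 140
  ss[(st - 1):(st + 3)] <- strsplit("GTCAG", "")[[1]]
  ss[(en + 4):(en + 8)] <- strsplit("GTCAG", "")[[1]]
  s3 <- paste(ss, collapse = "")
  expect_equal(brute_tsd(s3, st, en), c(3, 3))
  found <- find_tsd(s3, st, en, params)
  expect_equal(found$tsd, "GTCAG")
  expect_equal(found$start, st + 3)
  expect_equal(found$end, en + 3)
})

test_that("planted elements are detected with tight boundaries", {
  set.seed(50)
  # 500-bp LTRs at ~99% identity, 3-kb internal, TSD ACGTA
  anc <- rand_dna(500)
  pair <- mutate_ltr_pair(anc, 2e6, 2.36e-9)
  el <- plant_element(rand_dna(2000), pair$ltr5, rand_dna(3000), pair$ltr3,
                      rand_dna(2000), "ACGTA")
  genome <- Biostrings::DNAStringSet(c(chr1 = el$seq))
  cands <- detect_full_length(genome)
  expect_equal(nrow(cands), 1)
  expect_lte(abs(cands$start - el$start), 10)
  expect_lte(abs(cands$end - el$end), 10)
  expect_equal(cands$tsd, "ACGTA")

  # a pair at ~80% identity is below the 85% similarity bound
  set.seed(51)
  anc2 <- rand_dna(500)
  b2 <- strsplit(anc2, "")[[1]]
  hit <- sample(500, 110)  # ~22% divergence -> ~80% pair identity
  for (h in hit) b2[h] <- sample(setdiff(c("A", "C", "G", "T"), b2[h]), 1)
  el2 <- plant_element(rand_dna(2000), anc2, rand_dna(3000),
                       paste(b2, collapse = ""), rand_dna(2000), "ACGTA")
  cands2 <- detect_full_length(Biostrings::DNAStringSet(c(chr1 = el2$seq)))
  expect_equal(nrow(cands2), 0)

  # a 1400-bp element violates the minimum element extent (1500 bp)
  set.seed(52)
  anc3 <- rand_dna(200)
  el3 <- plant_element(rand_dna(2000), anc3, rand_dna(1000), anc3,
                       rand_dna(2000), "ACGTA")
  cands3 <- detect_full_length(Biostrings::DNAStringSet(c(chr1 = el3$seq)))
  expect_equal(nrow(cands3), 0)
})

test_that("every reported candidate satisfies the numeric constraints", {
  res <- default_pipeline()
  params <- detection_params()
  cands <- res$candidates
  ltr5_len <- cands$ltr5_end - cands$ltr5_start
  ltr3_len <- cands$ltr3_end - cands$ltr3_start
  span <- cands$end - cands$start
  expect_true(all(pmin(ltr5_len, ltr3_len) >=
                    params$min_ltr_len - params$vicinity))
  expect_true(all(pmax(ltr5_len, ltr3_len) <= params$max_ltr_len))
  expect_true(all(span >= params$min_elem_len - 2 * params$vicinity))
  expect_true(all(span <= params$max_elem_len))
  expect_true(all(cands$ltr_similarity >= params$min_similarity))
  # structural sanity: LTRs inside the element, 5' left of 3'
  expect_true(all(cands$ltr5_start == cands$start))
  expect_true(all(cands$ltr3_end == cands$end))
  expect_true(all(cands$ltr5_end <= cands$ltr3_start))
})

test_that("redundancy clustering groups by identity threshold", {
  set.seed(60)
  a <- rand_dna(1000)
  # b at ~95% to a; c unrelated
  bb <- strsplit(a, "")[[1]]
  for (h in sample(1000, 50)) bb[h] <- sample(setdiff(c("A", "C", "G", "T"),
                                                      bb[h]), 1)
  b <- paste(bb, collapse = "")
  cc <- rand_dna(1000)
  seqs <- Biostrings::DNAStringSet(c(A = a, B = b, C = cc))
  cl <- cluster_elements(seqs, threshold = 90)
  expect_equal(cl$cluster[cl$member == "A"], cl$cluster[cl$member == "B"])
  expect_false(cl$cluster[cl$member == "C"] == cl$cluster[cl$member == "A"])

  # identical pair -> one cluster of size 2
  two <- Biostrings::DNAStringSet(c(x = a, y = a))
  expect_equal(length(unique(cluster_elements(two)$cluster)), 1)

  # ~85% identity pair -> two clusters at threshold 90
  dd <- strsplit(a, "")[[1]]
  for (h in sample(1000, 160)) dd[h] <- sample(setdiff(c("A", "C", "G", "T"),
                                                       dd[h]), 1)
  far <- Biostrings::DNAStringSet(c(x = a, y = paste(dd, collapse = "")))
  expect_equal(length(unique(cluster_elements(far, threshold = 90)$cluster)), 2)

  # deterministic given the input set: permuting input yields the same
  # partition
  perm <- seqs[c(3, 1, 2)]
  cl2 <- cluster_elements(perm, threshold = 90)
  key <- function(cl) {
    parts <- split(cl$member, cl$cluster)
    paste(sort(vapply(parts, function(p) paste(sort(p), collapse = "+"),
                      character(1))), collapse = "|")
  }
  expect_equal(key(cl), key(cl2))
})

test_that("synthetic-genome detection recovers planted elements cleanly", {
  res <- default_pipeline()
  el <- res$elements
  tr <- res$sim$truth
  err <- truth_boundary_errors(el, tr)
  expect_gte(mean(!is.na(err)), 0.9)           # recall
  expect_lte(max(err, na.rm = TRUE), 10)       # boundary accuracy
  # no solo-LTR decoy reported as full-length
  solo <- res$sim$decoys[res$sim$decoys$type == "solo", ]
  for (j in seq_len(nrow(el))) {
    ov <- pmin(el$end[j], solo$end) - pmax(el$start[j], solo$start)
    expect_false(any(ov > 0.5 * (solo$end - solo$start)))
  }
})
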