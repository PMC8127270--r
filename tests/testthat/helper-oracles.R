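# Independent oracles used across the suite. These deliberately take the
# slow, direct route (quadratic scans, exhaustive DP, enumeration) so they
# share no code with the package implementations they check.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# brute-force maximal exact direct repeats of length >= k (0-based output)
brute_force_repeats <- function(s, k, max_span) {
  b <- strsplit(s, "")[[1]]
  n <- length(b)
  out <- list()
  for (i in seq_len(n - k + 1)) {
    for (j in seq_len(n - k + 1)) {
      if (j <= i || j - i > max_span) next
      # must be the start of a maximal match
      if (i > 1 && j > 1 && b[i - 1] == b[j - 1]) next
      L <- 0
      while (i + L <= n && j + L <= n && b[i + L] == b[j + L]) L <- L + 1
      if (L >= k)
        out[[length(out) + 1]] <- c(i - 1, j - 1, L)
    }
  }
  if (length(out) == 0)
    return(data.frame(pos1 = integer(0), pos2 = integer(0),
                      length = integer(0)))
  m <- do.call(rbind, out)
  df <- data.frame(pos1 = m[, 1], pos2 = m[, 2], length = m[, 3])
  df[order(df$pos1, df$pos2), ]
}

# exhaustive affine-gap global alignment score by memoised recursion over
# three states; gap of length L costs open + L * ext
brute_force_global_score <- function(a, b, match = 5, mismatch = -4,
                                     open = 16, ext = 4) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # last op: match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # last op: gap in b (a aligned to -)
  Y <- matrix(NEG, n + 1, m + 1)   # last op: gap in a
  M[1, 1] <- 0
  for (i in 1:(n + 1)) X[i, 1] <- -(open + (i - 1) * ext)
  for (j in 1:(m + 1)) Y[1, j] <- -(open + (j - 1) * ext)
  X[1, 1] <- NEG; Y[1, 1] <- NEG
  for (i in seq_len(n + 1)) {
    for (j in seq_len(m + 1)) {
      if (i > 1 && j > 1) {
        sc <- if (a[i - 1] == b[j - 1]) match else mismatch
        M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + sc
      }
      if (i > 1)
        X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext,
                       Y[i - 1, j] - open - ext)
      if (j > 1)
        Y[i, j] <- max(M[i, j - 1] - open - ext, X[i, j - 1] - open - ext,
                       Y[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# two-sided Fisher p by hypergeometric enumeration over all tables with the
# observed margins, summing probabilities <= that of the observed table
enumerate_fisher_two_sided <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  lo <- max(0, k - n2); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x)
    exp(lchoose(m, x) + lchoose(n2, k - x) - lchoose(m + n2, k)),
    numeric(1))
  pobs <- probs[a - lo + 1]
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# one-sided (greater) Fisher p by enumeration
enumerate_fisher_greater <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  hi <- min(k, m)
  sum(vapply(a:hi, function(x)
    exp(lchoose(m, x) + lchoose(n2, k - x) - lchoose(m + n2, k)),
    numeric(1)))
}

# quadratic-scan proximity oracle (0-based half-open intervals)
brute_force_proximity <- function(genes, elements, window) {
  out <- list()
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(elements))) {
      if (genes$chrom[i] != elements$chrom[j]) next
      gap <- max(elements$start[j] - genes$end[i],
                 genes$start[i] - elements$end[j], 0)
      overlap_ext <- genes$start[i] < elements$end[j] + window &&
        genes$end[i] > elements$start[j] - window
      if (overlap_ext)
        out[[length(out) + 1]] <- data.frame(
          gene_id = genes$gene_id[i], element_id = elements$element_id[j],
          distance = gap, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(gene_id = character(0), element_id = character(0),
                      distance = numeric(0)))
  df <- do.call(rbind, out)
  df[order(df$gene_id, df$element_id), ]
}

# plant a full-length element into a random background: returns genome
# string and truth coordinates (0-based half-open)
plant_element <- function(flank5, ltr5, internal, ltr3, flank3, tsd) {
  genome <- paste0(flank5, tsd, ltr5, internal, ltr3, tsd, flank3)
  s <- nchar(flank5) + nchar(tsd)
  list(seq = genome,
       start = s, end = s + nchar(ltr5) + nchar(internal) + nchar(ltr3),
       ltr5_start = s, ltr5_end = s + nchar(ltr5),
       ltr3_start = s + nchar(ltr5) + nchar(internal),
       ltr3_end = s + nchar(ltr5) + nchar(internal) + nchar(ltr3))
}

# match detected elements to truth intervals at reciprocal 80% overlap;
# returns per-truth boundary error (NA = missed)
truth_boundary_errors <- function(elements, truth) {
  vapply(seq_len(nrow(truth)), function(i) {
    ov <- pmin(elements$end, truth$end[i]) - pmax(elements$start, truth$start[i])
    if (length(ov) == 0) return(NA_real_)
    j <- which.max(ov)
    if (ov[j] < 0.8 * (truth$end[i] - truth$start[i])) return(NA_real_)
    max(abs(elements$start[j] - truth$start[i]),
        abs(elements$end[j] - truth$end[i]))
  }, numeric(1))
}
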