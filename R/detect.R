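#' Find maximal exact direct repeats via a k-mer index
#'
#' Returns all maximal exact direct-repeat pairs of length >= `k` whose start
#' separation is at most `max_span`, found by indexing k-mers and merging
#' co-diagonal runs of seed pairs into maximal matches (one maximal pair per
#' offset). Reverse-complement pairs are not reported. k-mers containing N or
#' occurring more than `max_occ` times are skipped.
#'
#' @param seq DNA sequence (character or [Biostrings::DNAString]).
#' @param k Seed length (>= 8).
#' @param max_span Maximum separation `pos2 - pos1` between repeat starts.
#' @param max_occ Occurrence cap per k-mer.
#' @return A data.frame with 0-based `pos1`, `pos2` (pos1 < pos2) and `length`.
#' @export
find_seed_repeats <- function(seq, k = 20, max_span = 25000, max_occ = 500) {
  stopifnot(k >= 8)
  s <- toupper(as.character(seq))
  n <- nchar(s)
  empty <- data.frame(pos1 = integer(0), pos2 = integer(0),
                      length = integer(0))
  if (n < k) return(empty)
  starts <- seq_len(n - k + 1)
  kmers <- substring(s, starts, starts + k - 1)
  keep <- !grepl("N", kmers, fixed = TRUE)
  idx <- split(starts[keep], kmers[keep])
  idx <- idx[lengths(idx) >= 2 & lengths(idx) <= max_occ]
  if (length(idx) == 0) return(empty)
  p1 <- integer(0); p2 <- integer(0)
  for (pos in idx) {
    cmb <- utils::combn(sort(pos), 2)
    sep <- cmb[2, ] - cmb[1, ]
    ok <- sep <= max_span
    p1 <- c(p1, cmb[1, ok]); p2 <- c(p2, cmb[2, ok])
  }
  if (length(p1) == 0) return(empty)
  d <- p2 - p1
  o <- order(d, p1)
  p1 <- p1[o]; p2 <- p2[o]; d <- d[o]
  # merge runs of consecutive seed starts on the same diagonal into one
  # maximal match
  newrun <- c(TRUE, !(d[-1] == d[-length(d)] & p1[-1] == p1[-length(p1)] + 1L))
  run <- cumsum(newrun)
  first <- !duplicated(run)
  len <- as.integer(tabulate(run) + k - 1L)
  out <- data.frame(pos1 = p1[first] - 1L, pos2 = p2[first] - 1L,
                    length = len)
  out[order(out$pos1, out$pos2), , drop = FALSE]
}

# ungapped X-drop extension: extend comparing s[i] vs s[i + d] outward from
# `from` in direction `dir`, return the position of the maximal score
.xdrop_extend <- function(b, d, from, dir, limit, match = 1, mismatch = -2,
                          xdrop = 20) {
  best <- 0; score <- 0; best_pos <- from
  i <- from + dir
  n <- length(b)
  while (i >= 1 && i <= limit && (i + d) >= 1 && (i + d) <= n) {
    score <- score + if (b[i] == b[i + d] && b[i] != "N") match else mismatch
    if (score > best) { best <- score; best_pos <- i }
    if (score < best - xdrop) break
    i <- i + dir
  }
  best_pos
}

# terminal-repeat check: a genuine LTR pair has no homology continuing past
# its boundaries (the element's outside flank vs the internal region are
# unrelated), whereas repeats internal to a larger shared region (e.g. a
# protein cassette shared by two family members) keep matching on at least
# one side. Compares the `w`-bp windows just outside the two copies by local
# alignment; homology = >= `min_match` matched bases at >= `min_id` identity.
.flank_homologous <- function(s, a_start, a_end, b_start, b_end, w = 1200,
                              min_match = 30, min_id = 85) {
  n <- nchar(s)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                     baseOnly = FALSE)
  check <- function(x1, x2, y1, y2) {
    if (x2 - x1 < 50 || y2 - y1 < 50) return(FALSE)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(substr(s, x1, x2)),
      Biostrings::DNAString(substr(s, y1, y2)),
      type = "local", substitutionMatrix = submat,
      gapOpening = 5, gapExtension = 2)
    cols <- nchar(as.character(Biostrings::alignedPattern(pa)))
    nm <- Biostrings::nmatch(pa)
    cols > 0 && nm >= min_match && 100 * nm / cols >= min_id
  }
  # left flanks (upstream of each copy) and right flanks (downstream)
  left <- check(max(1, a_start - w), a_start - 1, max(1, b_start - w),
                b_start - 1)
  if (left) return(TRUE)
  check(a_end + 1, min(n, a_end + w), b_end + 1, min(n, b_end + w))
}

# percent identity over a global alignment; gap columns count as mismatch
.global_identity <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 5, mismatch = -4, baseOnly = FALSE),
    gapOpening = 16, gapExtension = 4)
  100 * Biostrings::nmatch(pa) / nchar(as.character(Biostrings::alignedPattern(pa)))
}

#' Search for a target-site duplication around a candidate element
#'
#' For boundary shifts of at most `vicinity` bp on each side, looks for an
#' exact `tsd_len`-mer immediately left of the (shifted) element start equal
#' to the `tsd_len`-mer immediately right of the (shifted) element end. Ties
#' are broken by smallest total shift, then leftmost (smallest start shift,
#' then smallest end shift). On success the candidate's boundaries are moved
#' to the shifted positions.
#'
#' @param seq Chromosome sequence (character).
#' @param start,end 0-based half-open element interval.
#' @param params [detection_params()].
#' @return A list with `tsd` (string or NA), `start`, `end` (possibly
#'   shifted).
#' @export
find_tsd <- function(seq, start, end, params = detection_params()) {
  t <- params$tsd_len; v <- params$vicinity
  n <- nchar(seq)
  shifts <- expand.grid(i = -v:v, j = -v:v)
  shifts <- shifts[order(abs(shifts$i) + abs(shifts$j), shifts$i, shifts$j), ]
  for (r in seq_len(nrow(shifts))) {
    i <- shifts$i[r]; j <- shifts$j[r]
    ls <- start + i; rs <- end + j
    if (ls - t < 0 || rs + t > n || ls >= rs) next
    left <- substr(seq, ls - t + 1, ls)
    right <- substr(seq, rs + 1, rs + t)
    if (left == right && !grepl("N", left, fixed = TRUE))
      return(list(tsd = left, start = ls, end = rs))
  }
  list(tsd = NA_character_, start = start, end = end)
}

#' Detect full-length LTR retroelements
#'
#' Structural paired-LTR search: exact k-mer seeds within the allowed element
#' span are clustered by diagonal, extended by ungapped X-drop extension into
#' candidate LTR pairs, and kept when both LTR lengths, the element extent
#' (5' LTR start to 3' LTR end) and the LTR-pair global-alignment identity
#' satisfy `params`. Partially overlapping candidates are resolved by keeping
#' the higher-similarity one; a candidate lying entirely inside another's
#' internal region is kept but marked `nested`. A TSD search then runs;
#' candidates lacking a TSD are kept but flagged (`tsd` NA). Use
#' [filter_elements()] to apply the default reporting rules (require TSD,
#' drop nested).
#'
#' @param genome A named [Biostrings::DNAStringSet].
#' @param params [detection_params()].
#' @return A data.frame of class `ltr_candidates`: `element_id`, `chrom`,
#'   `start`, `end`, LTR intervals, `ltr_similarity`, `tsd`, `nested`
#'   (0-based half-open coordinates).
#' @export
detect_full_length <- function(genome, params = detection_params()) {
  stopifnot(length(genome) > 0)
  res <- list()
  for (ci in seq_along(genome)) {
    chrom <- names(genome)[ci]
    s <- as.character(genome[[ci]])
    b <- strsplit(s, "")[[1]]
    n <- nchar(s)
    seeds <- find_seed_repeats(s, k = params$seed_kmer,
                               max_span = params$max_elem_len,
                               max_occ = params$max_occ)
    if (nrow(seeds) == 0) next
    # cluster seeds: same diagonal neighbourhood, nearby positions
    d <- seeds$pos2 - seeds$pos1
    o <- order(d, seeds$pos1)
    seeds <- seeds[o, ]; d <- d[o]
    grp <- cumsum(c(TRUE, diff(d) != 0))
    cands <- list()
    for (g in unique(grp)) {
      sg <- seeds[grp == g, , drop = FALSE]
      sg <- sg[order(sg$pos1), , drop = FALSE]
      sub <- cumsum(c(TRUE, diff(sg$pos1) > params$max_ltr_len))
      for (u in unique(sub)) {
        su <- sg[sub == u, , drop = FALSE]
        d0 <- su$pos2[which.max(su$length)] - su$pos1[which.max(su$length)]
        if (d0 < params$min_ltr_len) next
        # 1-based positions for extension
        left0 <- min(su$pos1) + 1L
        right0 <- max(su$pos1 + su$length)
        L <- .xdrop_extend(b, d0, left0, -1L, limit = n)
        R <- .xdrop_extend(b, d0, right0, +1L, limit = min(n, L + d0 - 1L))
        ltr_len <- R - L + 1L
        if (ltr_len < params$min_ltr_len || ltr_len > params$max_ltr_len) next
        if (ltr_len > d0) next  # LTRs would overlap
        span <- d0 + ltr_len
        if (span < params$min_elem_len || span > params$max_elem_len) next
        ltr5 <- substr(s, L, R)
        ltr3 <- substr(s, L + d0, R + d0)
        if (mean(strsplit(ltr5, "")[[1]] == "N") > 0.1 ||
            mean(strsplit(ltr3, "")[[1]] == "N") > 0.1) next
        sim <- .global_identity(ltr5, ltr3)
        if (sim < params$min_similarity) next
        if (.flank_homologous(s, L, R, L + d0, R + d0)) next
        cands[[length(cands) + 1]] <- data.frame(
          chrom = chrom, start = L - 1L, end = R + d0,
          ltr5_start = L - 1L, ltr5_end = R,
          ltr3_start = L + d0 - 1L, ltr3_end = R + d0,
          ltr_similarity = sim, stringsAsFactors = FALSE)
      }
    }
    if (length(cands) == 0) next
    cands <- do.call(rbind, cands)
    cands <- cands[!duplicated(cands[, c("start", "end")]), , drop = FALSE]
    # TSD search first, updating boundaries on success
    cands$tsd <- NA_character_
    for (i in seq_len(nrow(cands))) {
      ts <- find_tsd(s, cands$start[i], cands$end[i], params)
      cands$tsd[i] <- ts$tsd
      if (!is.na(ts$tsd)) {
        cands$ltr5_start[i] <- cands$ltr5_start[i] + (ts$start - cands$start[i])
        cands$ltr3_end[i] <- cands$ltr3_end[i] + (ts$end - cands$end[i])
        cands$start[i] <- ts$start
        cands$end[i] <- ts$end
      }
    }
    # overlap resolution by parsimony: prefer TSD-supported candidates, then
    # the shorter (most parsimonious) structure, then higher similarity.
    # Containment within another candidate's internal region is legitimate
    # (a nested insertion): both are kept and the inner one is marked nested.
    cands <- cands[order(is.na(cands$tsd), cands$end - cands$start,
                         -cands$ltr_similarity), , drop = FALSE]
    keep <- logical(nrow(cands)); nested <- logical(nrow(cands))
    for (i in seq_len(nrow(cands))) {
      drop <- FALSE
      mark_i <- FALSE
      mark_j <- integer(0)
      for (j in which(keep)) {
        if (cands$start[i] < cands$end[j] && cands$end[i] > cands$start[j]) {
          i_in_j <- cands$start[i] >= cands$ltr5_end[j] &&
            cands$end[i] <= cands$ltr3_start[j]
          j_in_i <- cands$start[j] >= cands$ltr5_end[i] &&
            cands$end[j] <= cands$ltr3_start[i]
          if (i_in_j) mark_i <- TRUE
          else if (j_in_i && !is.na(cands$tsd[i])) mark_j <- c(mark_j, j)
          else { drop <- TRUE; break }
        }
      }
      # a candidate whose internal region swallows two or more independent
      # kept elements is a false join of shared internal homology, not a
      # doubly-nested element
      if (length(mark_j) >= 2) drop <- TRUE
      if (!drop) {
        keep[i] <- TRUE
        nested[i] <- mark_i
        nested[mark_j] <- TRUE  # marks apply only when the marker survives
      }
    }
    cands <- cands[keep, , drop = FALSE]
    nested <- nested[keep]
    cands$nested <- nested
    res[[length(res) + 1]] <- cands
  }
  if (length(res) == 0) {
    out <- data.frame(element_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      ltr5_start = integer(0), ltr5_end = integer(0),
                      ltr3_start = integer(0), ltr3_end = integer(0),
                      ltr_similarity = numeric(0), tsd = character(0),
                      nested = logical(0))
    class(out) <- c("ltr_candidates", "data.frame")
    return(out)
  }
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out <- cbind(element_id = sprintf("FL%04d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ltr_candidates", "data.frame")
  out
}

#' Apply default reporting rules to detected candidates
#'
#' @param cands Output of [detect_full_length()].
#' @param require_tsd Drop candidates without a TSD (default TRUE; reported
#'   element sets are conventionally TSD-constrained).
#' @param drop_nested Drop candidates nested inside another element's
#'   internal region (default TRUE).
#' @return The filtered candidate table.
#' @export
filter_elements <- function(cands, require_tsd = TRUE, drop_nested = TRUE) {
  if (require_tsd) cands <- cands[!is.na(cands$tsd), , drop = FALSE]
  if (drop_nested) cands <- cands[!cands$nested, , drop = FALSE]
  rownames(cands) <- NULL
  cands
}

#' Extract element (or LTR / internal-region) sequences
#'
#' @param genome A named [Biostrings::DNAStringSet].
#' @param cands Candidate table.
#' @param what One of `"element"`, `"ltr5"`, `"ltr3"`, `"internal"`.
#' @return A named [Biostrings::DNAStringSet].
#' @export
element_sequences <- function(genome, cands,
                              what = c("element", "ltr5", "ltr3", "internal")) {
  what <- match.arg(what)
  iv <- switch(what,
               element = cbind(cands$start, cands$end),
               ltr5 = cbind(cands$ltr5_start, cands$ltr5_end),
               ltr3 = cbind(cands$ltr3_start, cands$ltr3_end),
               internal = cbind(cands$ltr5_end, cands$ltr3_start))
  seqs <- vapply(seq_len(nrow(cands)), function(i) {
    as.character(Biostrings::subseq(genome[[cands$chrom[i]]],
                                    iv[i, 1] + 1L, iv[i, 2]))
  }, character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- cands$element_id
  out
}

#' Greedy incremental redundancy clustering
#'
#' Sequences are sorted by descending length (ties by id); each sequence
#' joins the first existing cluster whose representative aligns locally at
#' >= `threshold` percent identity over >= `min_cov` of the shorter
#' sequence, otherwise it founds a new cluster. Deterministic given the
#' input set (order-independent after the internal sort).
#'
#' @param seqs A named [Biostrings::DNAStringSet].
#' @param threshold Identity threshold (percent), default 90.
#' @param min_cov Minimum aligned fraction of the shorter sequence.
#' @return A data.frame: `member`, `cluster`, `representative`,
#'   `identity_to_rep` (100 for representatives).
#' @export
cluster_elements <- function(seqs, threshold = 90, min_cov = 0.8) {
  stopifnot(length(seqs) >= 1)
  o <- order(-Biostrings::width(seqs), names(seqs))
  seqs <- seqs[o]
  reps <- integer(0)
  assign <- integer(length(seqs))
  ident <- numeric(length(seqs))
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                     baseOnly = FALSE)
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (ri in seq_along(reps)) {
      r <- reps[ri]
      pa <- Biostrings::pairwiseAlignment(seqs[[i]], seqs[[r]],
                                          type = "local",
                                          substitutionMatrix = submat,
                                          gapOpening = 5, gapExtension = 2)
      cols <- nchar(as.character(Biostrings::alignedPattern(pa)))
      if (cols == 0) next
      id <- 100 * Biostrings::nmatch(pa) / cols
      shorter <- min(Biostrings::width(seqs)[c(i, r)])
      cov <- cols / shorter
      if (id >= threshold && cov >= min_cov) {
        assign[i] <- ri; ident[i] <- id; placed <- TRUE; break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assign[i] <- length(reps)
      ident[i] <- 100
    }
  }
  data.frame(member = names(seqs),
             cluster = sprintf("CL%03d", assign),
             representative = names(seqs)[reps[assign]],
             identity_to_rep = ident,
             stringsAsFactors = FALSE)
}
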