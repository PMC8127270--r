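#' Map reads to reference sequences
#'
#' Each read is locally aligned (both strands) against candidate references
#' found through a shared k-mer prefilter. An assignment exists only when
#' alignment identity >= `min_identity` and the aligned fraction of the read
#' length >= `min_len_frac`. All passing references are recorded; the
#' best-scoring one is the primary assignment (ties broken by reference id
#' order). A read is `unique` when exactly one reference passes.
#'
#' @param reads A named [Biostrings::DNAStringSet].
#' @param references A named [Biostrings::DNAStringSet].
#' @param min_identity Identity threshold (fraction of alignment columns).
#' @param min_len_frac Minimum aligned fraction of the read length.
#' @param k Prefilter k-mer length.
#' @return A data.frame with one row per assigned read: `read_id`,
#'   `element_id` (primary), `identity`, `aligned_frac`, `aligned_bases`,
#'   `n_hits`, `unique`; attribute `n_unmapped` counts unassigned reads.
#' @export
map_reads <- function(reads, references, min_identity = 0.9,
                      min_len_frac = 0.9, k = 15) {
  stopifnot(length(references) > 0)
  refnames <- names(references)
  # k-mer -> (reference, position) index
  ref_kmers <- lapply(seq_along(references), function(i) {
    s <- as.character(references[[i]])
    st <- seq_len(max(nchar(s) - k + 1, 0))
    data.frame(ref = rep(i, length(st)), pos = st,
               kmer = substring(s, st, st + k - 1))
  })
  ref_kmers <- do.call(rbind, ref_kmers)
  idx <- split(ref_kmers[, c("ref", "pos")], ref_kmers$kmer)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                     baseOnly = FALSE)
  # candidate (read, ref, strand) tasks via shared k-mers (vectorised over
  # all reads at once)
  rl <- Biostrings::width(reads)
  rc_reads <- Biostrings::reverseComplement(reads)
  kmer_tab <- function(strset) {
    ss <- as.character(strset)
    step <- max(k %/% 2, 1)
    sts <- lapply(nchar(ss), function(n) seq(1, max(n - k + 1, 1), by = step))
    data.frame(read = rep(seq_along(ss), lengths(sts)),
               kmer = substring(rep(ss, lengths(sts)), unlist(sts),
                                unlist(sts) + k - 1))
  }
  tasks <- NULL
  for (strand in c("+", "-")) {
    kt <- kmer_tab(if (strand == "+") reads else rc_reads)
    m <- match(kt$kmer, names(idx))
    kt <- kt[!is.na(m), , drop = FALSE]
    m <- m[!is.na(m)]
    if (nrow(kt) == 0) next
    hits_per <- idx[m]
    df <- data.frame(read = rep(kt$read, vapply(hits_per, nrow, 0L)),
                     do.call(rbind, hits_per), strand = strand)
    # one task per (read, ref): the seed-position envelope on the reference
    key <- paste(df$read, df$ref)
    agg <- data.frame(read = tapply(df$read, key, `[`, 1),
                      ref = tapply(df$ref, key, `[`, 1),
                      wmin = tapply(df$pos, key, min),
                      wmax = tapply(df$pos, key, max),
                      strand = strand)
    tasks <- rbind(tasks, agg)
  }
  if (is.null(tasks) || nrow(tasks) == 0) {
    out <- data.frame(read_id = character(0), element_id = character(0),
                      identity = numeric(0), aligned_frac = numeric(0),
                      aligned_bases = integer(0), n_hits = integer(0),
                      unique = logical(0))
    attr(out, "n_unmapped") <- length(reads)
    return(out)
  }
  # seed-and-extend: align each read against the window around its seed
  # envelope only
  reflens <- Biostrings::width(references)
  pad <- max(rl) + 20
  hits <- list()
  for (t in seq_len(nrow(tasks))) {
    ri <- tasks$read[t]; ref <- tasks$ref[t]
    win1 <- max(1, tasks$wmin[t] - pad)
    win2 <- min(reflens[ref], tasks$wmax[t] + pad)
    pat <- if (tasks$strand[t] == "+") reads[[ri]] else rc_reads[[ri]]
    pa <- Biostrings::pairwiseAlignment(
      pat, Biostrings::subseq(references[[ref]], win1, win2),
      type = "local", substitutionMatrix = submat,
      gapOpening = 1, gapExtension = 1)
    ind <- Biostrings::nindel(pa)
    nm <- Biostrings::nmatch(pa)
    cols <- nm + Biostrings::nmismatch(pa) +
      Biostrings::insertion(ind)[, "WidthSum"] +
      Biostrings::deletion(ind)[, "WidthSum"]
    if (cols == 0) next
    idy <- nm / cols
    aln_read <- Biostrings::end(Biostrings::pattern(pa)) -
      Biostrings::start(Biostrings::pattern(pa)) + 1
    frac <- aln_read / rl[ri]
    if (idy >= min_identity && frac >= min_len_frac)
      hits[[length(hits) + 1]] <- data.frame(
        read = ri, ref = ref, identity = idy, aligned_frac = frac,
        aligned_bases = aln_read, score = Biostrings::score(pa))
  }
  if (length(hits) == 0) {
    out <- data.frame(read_id = character(0), element_id = character(0),
                      identity = numeric(0), aligned_frac = numeric(0),
                      aligned_bases = integer(0), n_hits = integer(0),
                      unique = logical(0))
    attr(out, "n_unmapped") <- length(reads)
    return(out)
  }
  hits <- do.call(rbind, hits)
  # a read may hit the same ref on both strands; keep its best per ref
  hits <- hits[order(hits$read, hits$ref, -hits$score), ]
  hits <- hits[!duplicated(hits[, c("read", "ref")]), ]
  out <- do.call(rbind, lapply(split(hits, hits$read), function(h) {
    h <- h[order(-h$score, refnames[h$ref]), , drop = FALSE]
    data.frame(read_id = names(reads)[h$read[1]],
               element_id = refnames[h$ref[1]],
               identity = h$identity[1], aligned_frac = h$aligned_frac[1],
               aligned_bases = h$aligned_bases[1],
               n_hits = nrow(h), unique = nrow(h) == 1,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- length(reads) - nrow(out)
  out
}

#' Average coverage per element
#'
#' Genomic abundance proxy: the sum of aligned bases of primary read
#' assignments to an element, divided by the element length.
#'
#' @param assignments Assignment table from [map_reads()].
#' @param element_lengths Named numeric vector of element lengths (bp).
#' @return A data.frame: `element_id`, `coverage` (0 for unhit elements),
#'   `n_reads`.
#' @export
average_coverage <- function(assignments, element_lengths) {
  stopifnot(all(element_lengths > 0))
  ids <- names(element_lengths)
  bases <- tapply(assignments$aligned_bases, assignments$element_id, sum)
  nreads <- table(assignments$element_id)
  data.frame(element_id = ids,
             coverage = as.numeric(ifelse(is.na(bases[ids]), 0,
                                          bases[ids])) / element_lengths,
             n_reads = as.integer(ifelse(is.na(nreads[ids]), 0, nreads[ids])),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' RPKM expression matrix
#'
#' `rpkm[e, l] = counts[e, l] * 1e9 / (library_totals[l] * length[e])` —
#' reads per kilobase of sequence per million mapped reads.
#'
#' @param counts Element x library integer matrix.
#' @param element_lengths Named (or matching-order) lengths in bp.
#' @param library_totals Mapped-read totals per library.
#' @return A numeric matrix of RPKM values, same dimnames as `counts`.
#' @export
rpkm_matrix <- function(counts, element_lengths, library_totals) {
  counts <- as.matrix(counts)
  if (!is.null(names(element_lengths)) && !is.null(rownames(counts)))
    element_lengths <- element_lengths[rownames(counts)]
  if (!is.null(names(library_totals)) && !is.null(colnames(counts)))
    library_totals <- library_totals[colnames(counts)]
  if (any(library_totals <= 0)) stop("library totals must be positive")
  stopifnot(all(element_lengths > 0), length(element_lengths) == nrow(counts),
            length(library_totals) == ncol(counts))
  counts * 1e9 / outer(as.numeric(element_lengths),
                       as.numeric(library_totals))
}

#' Call expressed elements
#'
#' An element is expressed when its RPKM is strictly greater than
#' `threshold` in at least one library.
#'
#' @param rpkm RPKM matrix from [rpkm_matrix()].
#' @param threshold RPKM threshold (default 1).
#' @return Character vector of expressed element ids.
#' @export
call_expressed <- function(rpkm, threshold = 1) {
  if (length(rpkm) == 0) return(character(0))
  rownames(rpkm)[apply(rpkm > threshold, 1, any)]
}

#' Per-treatment expressed sets and their intersections
#'
#' An element is expressed in a treatment (condition x timepoint) when its
#' RPKM exceeds `threshold` in at least one of that treatment's replicate
#' libraries.
#'
#' @param rpkm RPKM matrix (columns = libraries).
#' @param design [library_design()] table labelling every column.
#' @param threshold RPKM threshold.
#' @return A list: `membership` (element x treatment logical matrix),
#'   `region_counts` (named counts of every Venn region, names like
#'   `"C24&S24"`; the empty region is `"none"`), `set_sizes`.
#' @export
condition_sets <- function(rpkm, design, threshold = 1) {
  stopifnot(all(colnames(rpkm) %in% design$library))
  treatments <- unique(design$treatment)
  memb <- sapply(treatments, function(t) {
    libs <- design$library[design$treatment == t]
    libs <- intersect(libs, colnames(rpkm))
    if (length(libs) == 0 || nrow(rpkm) == 0)
      return(rep(FALSE, nrow(rpkm)))
    apply(rpkm[, libs, drop = FALSE] > threshold, 1, any)
  })
  if (nrow(rpkm) == 0)
    memb <- matrix(FALSE, 0, length(treatments),
                   dimnames = list(NULL, treatments))
  if (is.null(dim(memb)))
    memb <- matrix(memb, nrow = nrow(rpkm),
                   dimnames = list(rownames(rpkm), treatments))
  rownames(memb) <- rownames(rpkm)
  pattern <- apply(memb, 1, function(m)
    if (!any(m)) "none" else paste(treatments[m], collapse = "&"))
  all_patterns <- c("none", unlist(lapply(seq_along(treatments), function(r)
    apply(utils::combn(treatments, r), 2, paste, collapse = "&"))))
  counts <- stats::setNames(integer(length(all_patterns)), all_patterns)
  tb <- table(pattern)
  counts[names(tb)] <- as.integer(tb)
  list(membership = memb, region_counts = counts,
       set_sizes = colSums(memb))
}

# conditional two-group NB exact test: given group sums sA (nA reps) and sB
# (nB reps) with common per-replicate mean and dispersion phi, the
# distribution of sA given sA + sB is free of the mean; the two-sided
# p-value sums all outcomes no more probable than the observed one
nb_exact_test <- function(sA, sB, nA, nB, phi) {
  s <- sA + sB
  if (s == 0) return(1)
  ks <- 0:s
  if (phi <= 0) {
    lp <- stats::dbinom(ks, s, nA / (nA + nB), log = TRUE)
  } else {
    rA <- nA / phi; rB <- nB / phi
    # conditional distribution: negative hypergeometric in the NB sizes
    lp <- lgamma(ks + rA) - lgamma(ks + 1) +
      lgamma(s - ks + rB) - lgamma(s - ks + 1)
    lp <- lp - max(lp)
    lp <- lp - log(sum(exp(lp)))
  }
  pobs <- lp[sA + 1]
  p <- sum(exp(lp[lp <= pobs + 1e-12]))
  min(p, 1)
}

# pooled method-of-moments common dispersion on normalised counts:
# phi = sum(var - mean) / sum(mean^2) over per-condition element summaries
estimate_dispersion_mom <- function(norm_counts, groups) {
  num <- 0; den <- 0
  for (g in unique(groups)) {
    m <- rowMeans(norm_counts[, groups == g, drop = FALSE])
    v <- apply(norm_counts[, groups == g, drop = FALSE], 1, stats::var)
    keep <- m > 0
    num <- num + sum(v[keep] - m[keep])
    den <- den + sum(m[keep]^2)
  }
  if (den == 0) return(0)
  max(num / den, 0)
}

#' Differential expression between conditions at one timepoint
#'
#' Counts are normalised to a common library size (geometric mean of the
#' library totals); a per-element negative-binomial exact test conditioned
#' on the pooled count is applied, with a common dispersion estimated across
#' elements by the method of moments (Poisson/binomial fallback when the
#' moment estimate is <= 0). P-values are Benjamini-Hochberg adjusted and an
#' element is called up/down only when |fold change| > `fc_threshold` and
#' FDR < `fdr_threshold`.
#'
#' @param counts Element x library matrix of raw counts.
#' @param design [library_design()] table labelling every library.
#' @param timepoint Timepoint (24 or 48) to test.
#' @param fc_threshold Absolute fold-change gate (default 2).
#' @param fdr_threshold FDR threshold (default 0.05).
#' @param library_totals Optional totals (default: column sums).
#' @param dispersion Optional fixed dispersion (default: moment estimate).
#' @return A data.frame of class `ltr_de`: `element_id`, `logFC` (salt vs
#'   control, log2), `pvalue`, `fdr`, `status` (`up`/`down`/`ns`);
#'   attribute `dispersion` carries the estimate used.
#' @export
differential_expression <- function(counts, design, timepoint,
                                    fc_threshold = 2, fdr_threshold = 0.05,
                                    library_totals = NULL,
                                    dispersion = NULL) {
  counts <- as.matrix(counts)
  d <- design[design$timepoint == timepoint & design$library %in% colnames(counts), ]
  stopifnot(sum(d$condition == "control") >= 2, sum(d$condition == "salt") >= 2)
  counts <- counts[, d$library, drop = FALSE]
  if (is.null(library_totals)) library_totals <- colSums(counts)
  else library_totals <- library_totals[d$library]
  if (any(library_totals <= 0)) stop("a condition has all-zero library totals")
  common <- exp(mean(log(library_totals)))
  pseudo <- round(t(t(counts) * (common / library_totals)))
  groups <- d$condition
  if (is.null(dispersion))
    dispersion <- estimate_dispersion_mom(pseudo, groups)
  nA <- sum(groups == "salt"); nB <- sum(groups == "control")
  sA <- rowSums(pseudo[, groups == "salt", drop = FALSE])
  sB <- rowSums(pseudo[, groups == "control", drop = FALSE])
  pv <- vapply(seq_len(nrow(pseudo)), function(i)
    nb_exact_test(sA[i], sB[i], nA, nB, dispersion), numeric(1))
  fc <- (sA / nA + 0.5) / (sB / nB + 0.5)
  logfc <- log2(fc)
  fdr <- stats::p.adjust(pv, method = "BH")
  status <- ifelse(pmax(fc, 1 / fc) > fc_threshold & fdr < fdr_threshold,
                   ifelse(logfc > 0, "up", "down"), "ns")
  out <- data.frame(element_id = rownames(counts), logFC = logfc,
                    pvalue = pv, fdr = fdr, status = status,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "dispersion") <- dispersion
  class(out) <- c("ltr_de", "data.frame")
  out
}

#' Per-library unique-read fraction
#'
#' @param assignments Assignment table from [map_reads()] (optionally with a
#'   `library` column; otherwise a single fraction is returned).
#' @return Named numeric vector of unique fractions.
#' @export
unique_read_fraction <- function(assignments) {
  if (!is.null(assignments$library))
    tapply(assignments$unique, assignments$library, mean)
  else c(all = mean(assignments$unique))
}
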