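#' Read the bundled (or a user-supplied) protein domain reference
#'
#' The reference is a protein FASTA with headers
#' `>NAME|DOMAIN|SUPERFAMILY|LINEAGE`. The bundled file
#' (`domains_synthetic.faa`) is a synthetic stand-in: fixed-seed random
#' proteins, one set of the five retroelement domains (GAG, PR, INT, RT, RH)
#' for each of two Copia lineages (Ale, Angela) and two Gypsy lineages
#' (Tekay, CRM). It supports end-to-end testing with planted cassettes; for
#' real genomes supply a curated domain database in the same format.
#'
#' @param path Protein FASTA path; default is the bundled synthetic reference.
#' @return A data.frame: `name`, `domain`, `superfamily`, `lineage`, `seq`.
#' @export
read_domain_reference <- function(path = system.file("extdata",
                                                     "domains_synthetic.faa",
                                                     package = "ltrdyn")) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  ids <- sub("^>", "", lines[hdr])
  seqs <- vapply(seq_along(hdr), function(i) {
    to <- if (i < length(hdr)) hdr[i + 1] - 1 else length(lines)
    paste(lines[(hdr[i] + 1):to], collapse = "")
  }, character(1))
  parts <- strsplit(ids, "|", fixed = TRUE)
  stopifnot(all(lengths(parts) == 4))
  data.frame(name = vapply(parts, `[`, "", 1),
             domain = vapply(parts, `[`, "", 2),
             superfamily = vapply(parts, `[`, "", 3),
             lineage = vapply(parts, `[`, "", 4),
             seq = seqs, stringsAsFactors = FALSE)
}

#' Translate a DNA sequence in all six frames
#'
#' Standard genetic code; stop codons are rendered as `*`; trailing bases
#' that do not complete a codon are dropped. Reverse frames are the forward
#' frames of the reverse complement.
#'
#' @param dna DNA string (character or [Biostrings::DNAString]).
#' @return Named character vector of 6 amino-acid strings
#'   (`+1`,`+2`,`+3`,`-1`,`-2`,`-3`).
#' @export
translate_six_frames <- function(dna) {
  d <- Biostrings::DNAString(as.character(dna))
  stopifnot(length(d) >= 3)
  rc <- Biostrings::reverseComplement(d)
  tr <- function(x, f) {
    l <- length(x)
    to <- l - ((l - f + 1) %% 3)
    if (to - f + 1 < 3) return("")
    as.character(Biostrings::translate(Biostrings::subseq(x, f, to),
                                       if.fuzzy.codon = "X"))
  }
  c(`+1` = tr(d, 1), `+2` = tr(d, 2), `+3` = tr(d, 3),
    `-1` = tr(rc, 1), `-2` = tr(rc, 2), `-3` = tr(rc, 3))
}

#' Scan an element's internal region for protein domains
#'
#' Each reference protein is locally aligned (BLOSUM62, gap open 10 /
#' extend 4) against all six translation frames; hits passing the identity
#' and reference-coverage thresholds are retained and, per domain name, only
#' the best-scoring hit is kept.
#'
#' @param element_internal DNA string of the internal region.
#' @param refs Domain reference table from [read_domain_reference()].
#' @param min_identity Minimum percent identity over alignment columns.
#' @param min_cov Minimum aligned fraction of the reference protein.
#' @return A data.frame of domain hits: `domain`, `frame`, `start`, `end`
#'   (element-relative nt, 0-based half-open), `identity`, `score`,
#'   `lineage`, `superfamily`.
#' @export
scan_domains <- function(element_internal, refs, min_identity = 40,
                         min_cov = 0.5) {
  stopifnot(nrow(refs) > 0)
  frames <- translate_six_frames(element_internal)
  nt_len <- nchar(as.character(element_internal))
  pats <- Biostrings::AAStringSet(refs$seq)
  hits <- list()
  for (fr in names(frames)) {
    aa <- frames[[fr]]
    if (!nzchar(aa)) next
    pa <- Biostrings::pairwiseAlignment(pats, Biostrings::AAString(aa),
                                        type = "local",
                                        substitutionMatrix = "BLOSUM62",
                                        gapOpening = 10, gapExtension = 4)
    cols <- nchar(as.character(Biostrings::alignedPattern(pa)))
    idy <- ifelse(cols > 0, 100 * Biostrings::nmatch(pa) / cols, 0)
    spans <- Biostrings::nchar(pa)  # aligned subject span (aa)
    covs <- Biostrings::width(
      Biostrings::unaligned(Biostrings::pattern(pa))) # ref lengths
    refcov <- (Biostrings::end(Biostrings::pattern(pa)) -
                 Biostrings::start(Biostrings::pattern(pa)) + 1) / covs
    sstart <- Biostrings::start(Biostrings::subject(pa))
    send <- Biostrings::end(Biostrings::subject(pa))
    f_off <- as.integer(substr(fr, 2, 2))
    neg <- substr(fr, 1, 1) == "-"
    for (i in seq_len(nrow(refs))) {
      if (idy[i] < min_identity || refcov[i] < min_cov) next
      # aa interval -> element-relative nt interval (0-based half-open)
      nt_s <- (sstart[i] - 1) * 3 + (f_off - 1)
      nt_e <- send[i] * 3 + (f_off - 1)
      if (neg) { tmp <- nt_len - nt_e; nt_e <- nt_len - nt_s; nt_s <- tmp }
      hits[[length(hits) + 1]] <- data.frame(
        domain = refs$domain[i],
        frame = if (neg) -f_off else f_off,
        start = nt_s, end = nt_e,
        identity = idy[i], score = Biostrings::score(pa)[i],
        lineage = refs$lineage[i], superfamily = refs$superfamily[i],
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0)
    return(data.frame(domain = character(0), frame = integer(0),
                      start = integer(0), end = integer(0),
                      identity = numeric(0), score = numeric(0),
                      lineage = character(0), superfamily = character(0)))
  hits <- do.call(rbind, hits)
  best <- unlist(lapply(split(seq_len(nrow(hits)), hits$domain),
                        function(ii) ii[which.max(hits$score[ii])]))
  out <- hits[sort(best), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify an element from its domain hits
#'
#' Superfamily is decided by domain order on the coding strand (the strand
#' carrying the best reverse-transcriptase hit, falling back to the strand
#' with the higher summed score): integrase upstream of RT means Copia, RT
#' upstream of integrase means Gypsy; if the order is undecidable the
#' majority superfamily of the hit reference labels is used. Lineage is the
#' modal lineage label among hits (ties by higher summed alignment score,
#' then alphabetical). An element is autonomous iff all five domains (GAG,
#' PR, INT, RT, RH) are hit. No hits yields `unknown`/`unknown`.
#'
#' @param hits Domain-hit table from [scan_domains()] (may be empty).
#' @return A one-row data.frame: `superfamily`, `lineage`, `autonomous`,
#'   `n_domains`, `domain_order`, `conflict` (TRUE when hit labels disagree
#'   on superfamily).
#' @export
classify_element <- function(hits) {
  all5 <- c("GAG", "PR", "INT", "RT", "RH")
  if (is.null(hits) || nrow(hits) == 0)
    return(data.frame(superfamily = "unknown", lineage = "unknown",
                      autonomous = FALSE, n_domains = 0L,
                      domain_order = "", conflict = FALSE,
                      stringsAsFactors = FALSE))
  strand <- if ("RT" %in% hits$domain) {
    sign(hits$frame[hits$domain == "RT"][which.max(hits$score[hits$domain == "RT"])])
  } else {
    pos_score <- sum(hits$score[hits$frame > 0])
    neg_score <- sum(hits$score[hits$frame < 0])
    if (neg_score > pos_score) -1 else 1
  }
  on_strand <- hits[sign(hits$frame) == strand, , drop = FALSE]
  ord <- on_strand[order(if (strand > 0) on_strand$start else -on_strand$end), ]
  sf <- if (all(c("INT", "RT") %in% ord$domain)) {
    if (match("INT", ord$domain) < match("RT", ord$domain)) "Copia" else "Gypsy"
  } else {
    tab <- tapply(hits$score, hits$superfamily, sum)
    names(tab)[which.max(tab)]
  }
  lin_n <- table(hits$lineage)
  cand <- names(lin_n)[lin_n == max(lin_n)]
  if (length(cand) > 1) {
    sc <- tapply(hits$score, hits$lineage, sum)[cand]
    cand <- cand[order(-sc, names(sc))]
  }
  lineage <- cand[1]
  data.frame(superfamily = sf, lineage = lineage,
             autonomous = all(all5 %in% hits$domain),
             n_domains = length(unique(hits$domain)),
             domain_order = paste(ord$domain, collapse = "-"),
             conflict = length(unique(hits$superfamily)) > 1,
             stringsAsFactors = FALSE)
}

#' Annotate detected elements with superfamily, lineage and autonomy
#'
#' @param genome A named [Biostrings::DNAStringSet].
#' @param cands Candidate table from [detect_full_length()].
#' @param refs Domain reference (default: bundled synthetic reference).
#' @param min_identity,min_cov Thresholds passed to [scan_domains()].
#' @return A data.frame with one row per element: `element_id`,
#'   `superfamily`, `lineage`, `autonomous`, `n_domains`, `domain_order`,
#'   `conflict`.
#' @export
annotate_elements <- function(genome, cands, refs = read_domain_reference(),
                              min_identity = 40, min_cov = 0.5) {
  if (nrow(cands) == 0)
    return(data.frame(element_id = character(0), superfamily = character(0),
                      lineage = character(0), autonomous = logical(0),
                      n_domains = integer(0), domain_order = character(0),
                      conflict = logical(0)))
  internals <- element_sequences(genome, cands, "internal")
  out <- do.call(rbind, lapply(seq_along(internals), function(i) {
    h <- scan_domains(as.character(internals[[i]]), refs,
                      min_identity, min_cov)
    classify_element(h)
  }))
  cbind(element_id = cands$element_id, out, stringsAsFactors = FALSE)
}
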