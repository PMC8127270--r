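#' Read a FASTA file into a DNAStringSet
#'
#' Thin FASTA reader with strict diagnostics: residues are upper-cased on
#' ingest, record ids (first whitespace-separated token of the header) must be
#' unique and non-empty, and malformed headers or non-IUPAC residues raise an
#' error naming the offending line. Descriptions (header remainder) are kept
#' in `mcols(x)$description`.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped).
#' @return A [Biostrings::DNAStringSet] named by record id.
#' @export
parse_fasta <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  if (length(lines) == 0)
    return(Biostrings::DNAStringSet())
  lines <- sub("\r$", "", lines)
  hdr <- grepl("^>", lines)
  if (!hdr[which(nzchar(trimws(lines)))[1]])
    stop("FASTA parse error at line ",
         which(nzchar(trimws(lines)))[1], ": sequence before first header")
  ids <- character(0); desc <- character(0)
  seqs <- character(0)
  cur <- NULL
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^>", ln)) {
      h <- sub("^>", "", ln)
      id <- sub("\\s.*$", "", h)
      if (!nzchar(id))
        stop("FASTA parse error at line ", i, ": empty record id")
      if (id %in% ids)
        stop("FASTA parse error at line ", i, ": duplicate record id '", id, "'")
      ids <- c(ids, id)
      desc <- c(desc, trimws(sub("^\\S+\\s*", "", h)))
      seqs <- c(seqs, "")
      cur <- length(seqs)
    } else {
      s <- toupper(gsub("\\s", "", ln))
      if (!nzchar(s)) next
      if (grepl("[^ACGTNRYSWKMBDHV]", s))
        stop("FASTA parse error at line ", i, ": non-IUPAC residue in '",
             substr(s, 1, 20), "'")
      if (is.null(cur))
        stop("FASTA parse error at line ", i, ": sequence before first header")
      seqs[cur] <- paste0(seqs[cur], s)
    }
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out)$description <- desc
  out
}

#' Write sequences to FASTA
#'
#' @param seqs A named [Biostrings::DNAStringSet] (or named character vector).
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, filepath = path, width = width)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Imports gene-typed features from a GFF3 file (1-based closed coordinates
#' per the standard) and converts them to the package's internal 0-based
#' half-open convention. GO terms are read from a companion two-column TSV
#' (gene id, GO id; one pair per line) because gene-function sidecar tables
#' are commonly shipped separately from the GFF. Genes with no GO entry get
#' an empty term set.
#'
#' @param path GFF3 path.
#' @param go_path Optional path to the GO sidecar TSV.
#' @param feature_type Feature type to keep (default `"gene"`).
#' @return A data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, and list-column `go`.
#' @export
parse_gff3 <- function(path, go_path = NULL, feature_type = "gene") {
  stopifnot(file.exists(path))
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("GFF3 parse error: ",
                                          conditionMessage(e)))
  gr <- gr[as.character(gr$type) %in% feature_type]
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-")))
    stop("GFF3 gene with unknown strand symbol (must be '+' or '-')")
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) ids <- gr$Name
  if (is.null(ids) || anyNA(ids))
    ids <- paste0("gene", seq_along(gr))
  genes <- data.frame(gene_id = as.character(ids),
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = BiocGenerics::start(gr) - 1L,
                      end = BiocGenerics::end(gr),
                      strand = strand,
                      stringsAsFactors = FALSE)
  go <- rep(list(character(0)), nrow(genes))
  if (!is.null(go_path)) {
    map <- read_go_table(go_path)
    hit <- match(genes$gene_id, names(map))
    go[!is.na(hit)] <- map[hit[!is.na(hit)]]
  }
  genes$go <- go
  genes
}

#' Read a gene-to-GO sidecar table
#'
#' @param path Two-column TSV: gene id, GO id (one pair per line, no header).
#' @return A named list mapping gene id to a character vector of GO ids.
#' @export
read_go_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("gene_id", "go_id"),
                           stringsAsFactors = FALSE)
  split(tab$go_id, tab$gene_id)
}

#' Write detected elements as GFF3
#'
#' Emits one `LTR_retrotransposon` feature per element with two
#' `long_terminal_repeat` children; internal 0-based half-open coordinates
#' are converted to GFF3 1-based closed at this boundary only.
#'
#' @param elements An element table (see [detect_full_length()]).
#' @param path Output path.
#' @export
write_element_gff <- function(elements, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(elements) == 0) return(invisible(path))
  for (i in seq_len(nrow(elements))) {
    e <- elements[i, ]
    writeLines(sprintf("%s\tltrdyn\tLTR_retrotransposon\t%d\t%d\t.\t+\t.\tID=%s",
                       e$chrom, e$start + 1L, e$end, e$element_id), con)
    writeLines(sprintf("%s\tltrdyn\tlong_terminal_repeat\t%d\t%d\t.\t+\t.\tID=%s_LTR5;Parent=%s",
                       e$chrom, e$ltr5_start + 1L, e$ltr5_end, e$element_id,
                       e$element_id), con)
    writeLines(sprintf("%s\tltrdyn\tlong_terminal_repeat\t%d\t%d\t.\t+\t.\tID=%s_LTR3;Parent=%s",
                       e$chrom, e$ltr3_start + 1L, e$ltr3_end, e$element_id,
                       e$element_id), con)
  }
  invisible(path)
}

#' Read an element GFF3 written by [write_element_gff()]
#'
#' @param path GFF3 path.
#' @return A data.frame with element and LTR coordinates (0-based half-open).
#' @export
read_element_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  par <- gr[as.character(gr$type) == "LTR_retrotransposon"]
  kid <- gr[as.character(gr$type) == "long_terminal_repeat"]
  out <- data.frame(element_id = as.character(par$ID),
                    chrom = as.character(GenomicRanges::seqnames(par)),
                    start = BiocGenerics::start(par) - 1L,
                    end = BiocGenerics::end(par),
                    stringsAsFactors = FALSE)
  kidpar <- vapply(kid$Parent, function(p) as.character(p)[1], character(1))
  for (i in seq_len(nrow(out))) {
    k <- kid[kidpar == out$element_id[i]]
    k <- k[order(BiocGenerics::start(k))]
    out$ltr5_start[i] <- BiocGenerics::start(k)[1] - 1L
    out$ltr5_end[i] <- BiocGenerics::end(k)[1]
    out$ltr3_start[i] <- BiocGenerics::start(k)[2] - 1L
    out$ltr3_end[i] <- BiocGenerics::end(k)[2]
  }
  out
}

#' Write reads to a 4-line FASTQ file
#'
#' @param reads Named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @param quality Constant quality character applied to every base.
#' @export
write_fastq <- function(reads, path, quality = "I") {
  seqs <- as.character(reads)
  out <- character(4 * length(seqs))
  out[seq(1, length(out), 4)] <- paste0("@", names(seqs))
  out[seq(2, length(out), 4)] <- seqs
  out[seq(3, length(out), 4)] <- "+"
  out[seq(4, length(out), 4)] <- vapply(nchar(seqs), function(n)
    strrep(quality, n), character(1))
  writeLines(out, path)
  invisible(path)
}

#' Read a 4-line FASTQ file
#'
#' @param path FASTQ path.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_fastq <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq")
}

write_result_tsv <- function(df, path) {
  df <- as.data.frame(df)
  df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
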