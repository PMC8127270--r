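#' Genes within a window of elements
#'
#' Returns a record for every (gene, element) pair whose intervals overlap
#' after extending the element by `window` bp on both sides; `distance` is
#' the gap between the unextended intervals (0 when they overlap). The
#' overlap query uses an interval index ([GenomicRanges::findOverlaps()]).
#'
#' @param genes Gene table from [parse_gff3()] (0-based half-open).
#' @param elements Element table (0-based half-open).
#' @param window Window size in bp (default 50000).
#' @param expressed_ids Optional character vector of expressed element ids;
#'   fills the `element_expressed` flag.
#' @return A data.frame: `gene_id`, `element_id`, `distance`,
#'   `element_expressed`.
#' @export
genes_near_elements <- function(genes, elements, window = 50000,
                                expressed_ids = NULL) {
  empty <- data.frame(gene_id = character(0), element_id = character(0),
                      distance = numeric(0), element_expressed = logical(0))
  if (nrow(genes) == 0 || nrow(elements) == 0) return(empty)
  g_gr <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start + 1L, genes$end))
  e_gr <- GenomicRanges::GRanges(
    elements$chrom,
    IRanges::IRanges(pmax(elements$start - window + 1L, 1L),
                     elements$end + window))
  ov <- GenomicRanges::findOverlaps(g_gr, e_gr, ignore.strand = TRUE)
  if (length(ov) == 0) return(empty)
  gi <- S4Vectors::queryHits(ov); ei <- S4Vectors::subjectHits(ov)
  dist <- pmax(elements$start[ei] - genes$end[gi],
               genes$start[gi] - elements$end[ei], 0)
  out <- data.frame(gene_id = genes$gene_id[gi],
                    element_id = elements$element_id[ei],
                    distance = dist,
                    stringsAsFactors = FALSE)
  out$element_expressed <- if (!is.null(expressed_ids))
    out$element_id %in% expressed_ids else NA
  out[order(out$gene_id, out$element_id), , drop = FALSE]
}

#' Expression category of a gene
#'
#' Partition of mean RPKM into four half-open-left classes:
#' `[0,1)` not, `[1,10)` low, `[10,100)` medium, `[100,Inf)` high.
#' (Half-open intervals make the partition total; the conventional verbal
#' bounds "RPKM < 1", "1-10", "10-100", "> 100" leave the boundary points
#' unassigned.)
#'
#' @param rpkm_mean Non-negative numeric vector of mean RPKM values.
#' @return Factor with levels `not`, `low`, `medium`, `high`.
#' @export
categorize_expression <- function(rpkm_mean) {
  if (any(is.na(rpkm_mean)) || any(rpkm_mean < 0))
    stop("rpkm_mean must be non-negative")
  cut(rpkm_mean, breaks = c(0, 1, 10, 100, Inf), right = FALSE,
      labels = c("not", "low", "medium", "high"), include.lowest = TRUE)
}

#' Build the category x element-group contingency table
#'
#' Genes near at least one expressed element go to the `near_expressed`
#' group (activity dominates when a gene is near both kinds); genes near
#' only non-expressed elements go to `near_not_expressed`.
#'
#' @param gene_rpkm Named vector of per-gene mean RPKM.
#' @param proximity Proximity table from [genes_near_elements()] with the
#'   `element_expressed` flag filled.
#' @return A 4 x 2 integer matrix (categories x groups).
#' @export
category_table <- function(gene_rpkm, proximity) {
  near_expr <- unique(proximity$gene_id[proximity$element_expressed])
  near_not <- setdiff(unique(proximity$gene_id), near_expr)
  cat_expr <- categorize_expression(gene_rpkm[near_expr])
  cat_not <- categorize_expression(gene_rpkm[near_not])
  cbind(near_expressed = table(cat_expr),
        near_not_expressed = table(cat_not))
}

#' Per-category Fisher tests between element groups
#'
#' For each expression category, tests the 2x2 table (in-category vs not,
#' near-expressed vs near-not-expressed) with a two-sided Fisher's exact
#' test; Benjamini-Hochberg FDR over the categories.
#'
#' @param tab A category x group count matrix (from [category_table()]).
#' @param fdr_threshold Significance threshold on the FDR.
#' @return A data.frame: `category`, group counts, `p`, `fdr`,
#'   `significant`.
#' @export
compare_categories <- function(tab, fdr_threshold = 0.05) {
  stopifnot(ncol(tab) == 2, all(tab >= 0))
  tot <- colSums(tab)
  if (any(tot == 0)) stop("both element groups must be non-empty")
  p <- vapply(seq_len(nrow(tab)), function(i) {
    m <- rbind(tab[i, ], tot - tab[i, ])
    stats::fisher.test(m, alternative = "two.sided")$p.value
  }, numeric(1))
  fdr <- stats::p.adjust(p, method = "BH")
  data.frame(category = rownames(tab),
             near_expressed = tab[, 1], near_not_expressed = tab[, 2],
             p = p, fdr = fdr, significant = fdr < fdr_threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' GO term over-representation in a gene selection
#'
#' Per GO term with at least one selected gene, a one-sided
#' (over-representation) Fisher's exact test on the 2x2 table of term
#' membership x selection membership over the annotated universe, with
#' Benjamini-Hochberg FDR across tested terms. Genes without annotation are
#' excluded from the universe.
#'
#' @param selection Character vector of selected gene ids (subset of
#'   `background`).
#' @param background Character vector of universe gene ids.
#' @param annotations Named list mapping gene id to GO ids.
#' @param fdr_threshold FDR threshold for the `enriched` flag.
#' @return A data.frame: `term`, `n_selection`, `n_background`, `p`, `fdr`,
#'   `enriched`.
#' @export
go_enrichment <- function(selection, background, annotations,
                          fdr_threshold = 0.05) {
  if (length(selection) == 0) stop("empty selection")
  if (!all(selection %in% background))
    stop("selection must be a subset of background")
  background <- intersect(background, names(annotations)[lengths(annotations) > 0])
  selection <- intersect(selection, background)
  if (length(selection) == 0) stop("no annotated gene in selection")
  ann <- annotations[background]
  terms <- unique(unlist(ann, use.names = FALSE))
  gene_terms <- ann
  n_bg <- length(background)
  n_sel <- length(selection)
  in_sel <- background %in% selection
  rows <- lapply(terms, function(t) {
    has <- vapply(gene_terms, function(g) t %in% g, logical(1))
    a <- sum(has & in_sel)
    if (a == 0) return(NULL)  # terms absent from the selection are not tested
    b <- n_sel - a
    cc <- sum(has) - a
    dd <- n_bg - n_sel - cc
    p <- stats::fisher.test(matrix(c(a, b, cc, dd), 2, byrow = TRUE),
                            alternative = "greater")$p.value
    data.frame(term = t, n_selection = a, n_background = sum(has), p = p,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(rows))
    return(data.frame(term = character(0), n_selection = integer(0),
                      n_background = integer(0), p = numeric(0),
                      fdr = numeric(0), enriched = logical(0)))
  rows$fdr <- stats::p.adjust(rows$p, method = "BH")
  rows$enriched <- rows$fdr < fdr_threshold
  rows[order(rows$p), , drop = FALSE]
}
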