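# match detected elements to planted truth records by best coordinate overlap
match_to_truth <- function(cands, truth) {
  if (nrow(cands) == 0 || nrow(truth) == 0)
    return(rep(NA_character_, nrow(cands)))
  vapply(seq_len(nrow(cands)), function(i) {
    same <- truth$chrom == cands$chrom[i]
    ov <- pmin(truth$end, cands$end[i]) - pmax(truth$start, cands$start[i])
    ov[!same] <- -1
    if (max(ov) <= 0) NA_character_ else truth$element_id[which.max(ov)]
  }, character(1))
}

#' Run the full analysis pipeline on a synthetic dataset
#'
#' Exercises every stage end to end: genome simulation with planted
#' elements, structural detection, redundancy clustering, domain annotation,
#' insertion-age dating, DNA-read mapping for genomic abundance, RNA count
#' simulation, RPKM and expressed-set calling, differential expression at
#' both timepoints, gene-proximity category tests, GO enrichment, and the
#' lineage/trend statistics. When `outdir` is given, every result table is
#' written as TSV (plus the element GFF3).
#'
#' @param spec A [synthetic_genome_spec()]; its seed drives all randomness.
#' @param config A [pipeline_config()].
#' @param dna_coverage Fold coverage for the simulated DNA library.
#' @param design RNA library design, default [library_design()].
#' @param outdir Optional output directory for TSV results.
#' @return A list of class `ltr_pipeline` with all intermediate and final
#'   tables.
#' @export
run_ltr_pipeline <- function(spec = synthetic_genome_spec(),
                             config = pipeline_config(seed = spec$seed),
                             dna_coverage = 3,
                             design = library_design(),
                             outdir = NULL) {
  sim <- simulate_genome(spec)
  genome <- sim$genome

  cands <- detect_full_length(genome, config$detection)
  elements <- filter_elements(cands)
  elem_seqs <- element_sequences(genome, elements)
  clusters <- cluster_elements(elem_seqs, threshold = config$cluster_threshold)
  annotation <- annotate_elements(genome, elements)
  ages <- date_elements(genome, elements, rate = config$dating$rate)

  dna <- simulate_dna_reads(genome, fold_coverage = dna_coverage,
                            seed = spec$seed + 1)
  assignments <- map_reads(dna, elem_seqs,
                           min_identity = config$min_identity,
                           min_len_frac = config$min_len_frac)
  lens <- stats::setNames(elements$end - elements$start, elements$element_id)
  abundance <- average_coverage(assignments, lens)

  rna <- simulate_rna_reads(sim$truth, sim$genes, design = design,
                            seed = spec$seed + 2,
                            dispersion = spec$dispersion)
  # re-key truth-level counts to the detected elements they correspond to
  truth_match <- match_to_truth(elements, sim$truth)
  elem_counts <- matrix(0L, nrow(elements), ncol(rna$counts),
                        dimnames = list(elements$element_id,
                                        colnames(rna$counts)))
  hit <- !is.na(truth_match) & truth_match %in% rownames(rna$counts)
  elem_counts[hit, ] <- rna$counts[truth_match[hit], , drop = FALSE]
  gene_ids <- intersect(sim$genes$gene_id, rownames(rna$counts))
  gene_counts <- rna$counts[gene_ids, , drop = FALSE]

  rpkm <- rpkm_matrix(elem_counts, lens, rna$library_totals)
  gene_lens <- stats::setNames(sim$genes$end - sim$genes$start,
                               sim$genes$gene_id)[gene_ids]
  gene_rpkm <- rpkm_matrix(gene_counts, gene_lens, rna$library_totals)

  expressed <- call_expressed(rpkm, config$expressed_threshold)
  venn <- condition_sets(rpkm, design, config$expressed_threshold)
  de24 <- differential_expression(elem_counts, design, 24,
                                  config$fc_threshold, config$fdr_threshold,
                                  library_totals = rna$library_totals)
  de48 <- differential_expression(elem_counts, design, 48,
                                  config$fc_threshold, config$fdr_threshold,
                                  library_totals = rna$library_totals)

  proximity <- genes_near_elements(sim$genes, elements,
                                   window = config$window,
                                   expressed_ids = expressed)
  gene_mean_rpkm <- rowMeans(gene_rpkm)
  categories <- NULL
  if (nrow(proximity) > 0 && any(proximity$element_expressed)) {
    cat_tab <- category_table(gene_mean_rpkm, proximity)
    if (all(colSums(cat_tab) > 0))  # both gene groups populated
      categories <- compare_categories(cat_tab, config$fdr_threshold)
  }
  ann_list <- stats::setNames(sim$genes$go, sim$genes$gene_id)
  near_expr_genes <- unique(proximity$gene_id[proximity$element_expressed])
  enrichment <- if (length(near_expr_genes) > 0)
    go_enrichment(near_expr_genes, sim$genes$gene_id, ann_list,
                  config$fdr_threshold) else NULL

  summary_tab <- lineage_summary(annotation)
  treatments <- unique(design$treatment)
  rpkm_means <- sapply(treatments, function(t)
    rowMeans(rpkm[, design$library[design$treatment == t], drop = FALSE]))
  joined <- data.frame(element_id = elements$element_id,
                       superfamily = annotation$superfamily,
                       lineage = annotation$lineage,
                       age_years = ages$years,
                       coverage = abundance$coverage,
                       stringsAsFactors = FALSE)
  for (t in treatments) joined[[paste0("rpkm_", t)]] <- rpkm_means[, t]
  lin_groups <- split(joined$age_years, joined$lineage)
  lin_groups <- lin_groups[lengths(lin_groups) >= 2]
  age_anova <- if (length(lin_groups) >= 2) anova_tukey(lin_groups) else NULL
  slopes <- if (sum(joined$superfamily == "Copia") >= 3 &&
                stats::var(joined$age_years[joined$superfamily == "Copia"]) > 0)
    slope_table(joined) else NULL

  out <- structure(list(sim = sim, candidates = cands, elements = elements,
                        clusters = clusters, annotation = annotation,
                        ages = ages, assignments = assignments,
                        abundance = abundance, counts = elem_counts,
                        rpkm = rpkm, gene_rpkm = gene_rpkm,
                        expressed = expressed, venn = venn,
                        de24 = de24, de48 = de48,
                        proximity = proximity, categories = categories,
                        enrichment = enrichment,
                        lineage_summary = summary_tab,
                        age_anova = age_anova,
                        joined = joined, slopes = slopes,
                        design = design, config = config),
                   class = "ltr_pipeline")
  if (!is.null(outdir)) write_pipeline_results(out, outdir)
  out
}

#' Write every pipeline result table to a directory
#'
#' @param x An `ltr_pipeline` result.
#' @param outdir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_pipeline_results <- function(x, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_element_gff(x$elements, p("elements.gff3"))
  write_result_tsv(x$elements, p("elements.tsv"))
  write_result_tsv(x$clusters, p("clusters.tsv"))
  write_result_tsv(x$annotation, p("annotation.tsv"))
  write_result_tsv(x$ages, p("ages.tsv"))
  write_result_tsv(x$abundance, p("abundance.tsv"))
  utils::write.table(data.frame(element_id = rownames(x$rpkm),
                                x$rpkm, check.names = FALSE),
                     p("rpkm.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_result_tsv(data.frame(element_id = x$expressed), p("expressed.tsv"))
  write_result_tsv(x$de24, p("de_24.tsv"))
  write_result_tsv(x$de48, p("de_48.tsv"))
  write_result_tsv(x$proximity, p("proximity.tsv"))
  if (!is.null(x$categories))
    write_result_tsv(x$categories, p("categories.tsv"))
  if (!is.null(x$enrichment))
    write_result_tsv(x$enrichment, p("go_enrichment.tsv"))
  write_result_tsv(x$lineage_summary$lineage, p("lineage_summary.tsv"))
  write_result_tsv(x$joined, p("elements_joined.tsv"))
  if (!is.null(x$slopes)) write_result_tsv(x$slopes, p("slopes.tsv"))
  invisible(outdir)
}

#' @export
print.ltr_pipeline <- function(x, ...) {
  cat("LTR retroelement pipeline run\n")
  cat(sprintf("  genome: %d bp, %d planted elements, %d decoys\n",
              sum(Biostrings::width(x$sim$genome)), nrow(x$sim$truth),
              nrow(x$sim$decoys)))
  cat(sprintf("  detected: %d candidates, %d reported elements\n",
              nrow(x$candidates), nrow(x$elements)))
  cat(sprintf("  clusters: %d; autonomous: %d\n",
              length(unique(x$clusters$cluster)),
              sum(x$annotation$autonomous)))
  cat(sprintf("  expressed (RPKM > %g in >= 1 library): %d\n",
              x$config$expressed_threshold, length(x$expressed)))
  cat(sprintf("  DE at 24 d: %d; at 48 d: %d\n",
              sum(x$de24$status != "ns"), sum(x$de48$status != "ns")))
  invisible(x)
}
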