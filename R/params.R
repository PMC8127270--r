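#' Structural detection parameters
#'
#' Parameter set for full-length LTR retroelement detection. Defaults follow
#' the standard paired-LTR search configuration used for plant genomes:
#' LTRs of 100-6000 bp, element extent (5' LTR start to 3' LTR end) of
#' 1500-25000 bp, a 5-bp target-site duplication searched within a 10-bp
#' vicinity of each boundary, and a minimum LTR-pair identity of 85%.
#'
#' @param min_ltr_len Minimum LTR length (bp).
#' @param max_ltr_len Maximum LTR length (bp).
#' @param min_elem_len Minimum element extent (bp), 5' LTR start to 3' LTR end.
#' @param max_elem_len Maximum element extent (bp).
#' @param tsd_len Target-site duplication length (bp); exact length searched.
#' @param min_similarity Minimum LTR-pair identity (percent) over a global
#'   alignment; gap columns count as mismatches.
#' @param vicinity Maximum boundary shift (bp) allowed on each side when
#'   searching for the TSD.
#' @param seed_kmer Exact-match seed length (bp) for the repeat finder.
#' @param max_occ k-mers occurring more often than this are skipped when
#'   seeding (low-complexity guard).
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(min_ltr_len = 100L, max_ltr_len = 6000L,
                             min_elem_len = 1500L, max_elem_len = 25000L,
                             tsd_len = 5L, min_similarity = 85,
                             vicinity = 10L, seed_kmer = 20L, max_occ = 500L) {
  stopifnot(min_ltr_len > 0, min_ltr_len < max_ltr_len,
            min_elem_len > 0, min_elem_len < max_elem_len,
            tsd_len > 0, min_similarity > 0, min_similarity <= 100,
            vicinity >= 0, seed_kmer >= 8)
  structure(list(min_ltr_len = as.integer(min_ltr_len),
                 max_ltr_len = as.integer(max_ltr_len),
                 min_elem_len = as.integer(min_elem_len),
                 max_elem_len = as.integer(max_elem_len),
                 tsd_len = as.integer(tsd_len),
                 min_similarity = min_similarity,
                 vicinity = as.integer(vicinity),
                 seed_kmer = as.integer(seed_kmer),
                 max_occ = as.integer(max_occ)),
            class = "detection_params")
}

#' Dating parameters
#'
#' @param rate Substitution rate per site per year applied to each LTR copy.
#'   The default, 2.36e-9, is two-fold the synonymous rate estimated for
#'   *Populus trichocarpa* genes, reflecting the faster accumulation of
#'   substitutions in retroelements.
#' @return A list of class `dating_params`.
#' @export
dating_params <- function(rate = 2.36e-9) {
  stopifnot(is.numeric(rate), rate > 0)
  structure(list(rate = rate), class = "dating_params")
}

#' Full pipeline configuration
#'
#' Bundles detection, dating, mapping, expression and proximity thresholds
#' with the random seed. All defaults are the pipeline's reference values.
#'
#' @param detection A [detection_params()] list.
#' @param dating A [dating_params()] list.
#' @param min_identity Read-mapping minimum identity fraction.
#' @param min_len_frac Read-mapping minimum aligned fraction of read length.
#' @param cluster_threshold Redundancy clustering identity threshold (percent).
#' @param window Gene-proximity window (bp) on each side of an element.
#' @param expressed_threshold RPKM threshold: an element is expressed when
#'   RPKM is strictly greater in at least one library.
#' @param fc_threshold Differential-expression absolute fold-change gate.
#' @param fdr_threshold FDR significance threshold.
#' @param seed Integer random seed driving every stochastic step.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(detection = detection_params(),
                            dating = dating_params(),
                            min_identity = 0.9, min_len_frac = 0.9,
                            cluster_threshold = 90,
                            window = 50000L,
                            expressed_threshold = 1,
                            fc_threshold = 2, fdr_threshold = 0.05,
                            seed = 1L) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_len_frac > 0, min_len_frac <= 1,
            cluster_threshold > 0, cluster_threshold <= 100,
            window > 0, expressed_threshold > 0,
            fc_threshold > 0, fdr_threshold > 0)
  structure(list(detection = detection, dating = dating,
                 min_identity = min_identity, min_len_frac = min_len_frac,
                 cluster_threshold = cluster_threshold,
                 window = as.integer(window),
                 expressed_threshold = expressed_threshold,
                 fc_threshold = fc_threshold, fdr_threshold = fdr_threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# round half away from zero to `digits`; base round() is round-half-even
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
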