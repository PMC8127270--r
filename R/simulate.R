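#' @keywords internal
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# fixed aa -> codon map for planting protein cassettes in synthetic elements
.codon_map <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
                Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
                L = "CTT", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
                S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

reverse_translate <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  paste(.codon_map[aa], collapse = "")
}

#' Mutate an ancestral LTR into a diverged 5'/3' pair
#'
#' Simulates the post-insertion divergence of the two LTR copies: each copy
#' receives independent substitutions with per-site probability `age * rate`,
#' with transitions twice as likely as transversions (so the transition
#' proportion P is roughly twice the transversion proportion Q). Expected
#' pairwise divergence is `2 * rate * age` per site.
#'
#' @param ancestral_ltr DNA string (character) of the LTR at insertion time.
#' @param age Insertion age in years (>= 0).
#' @param rate Per-site per-year substitution rate (> 0).
#' @param seed Optional integer seed; when given the output is reproducible.
#' @return A list with character elements `ltr5` and `ltr3`.
#' @export
mutate_ltr_pair <- function(ancestral_ltr, age, rate, seed = NULL) {
  stopifnot(rate > 0, age >= 0)
  p <- age * rate
  if (p >= 0.75)
    stop("age * rate >= 0.75: substitution process saturated, pair undatable")
  if (!is.null(seed)) set.seed(seed)
  mutate_copy <- function(s) {
    b <- strsplit(s, "")[[1]]
    hit <- which(stats::runif(length(b)) < p)
    if (length(hit) > 0) {
      ti <- c(A = "G", G = "A", C = "T", T = "C")
      tv <- list(A = c("C", "T"), G = c("C", "T"),
                 C = c("A", "G"), T = c("A", "G"))
      for (i in hit) {
        if (stats::runif(1) < 2 / 3) b[i] <- ti[[b[i]]]
        else b[i] <- sample(tv[[b[i]]], 1)
      }
    }
    paste(b, collapse = "")
  }
  list(ltr5 = mutate_copy(ancestral_ltr), ltr3 = mutate_copy(ancestral_ltr))
}

#' RNA-seq library design
#'
#' The reference design is 2 conditions (control, salt) x 2 timepoints
#' (24, 48 days) x `replicates` biological replicates.
#'
#' @param replicates Replicates per condition/timepoint (default 3).
#' @param library_size Total mapped reads per library.
#' @return A data.frame with columns `library`, `condition`, `timepoint`,
#'   `replicate`, `size` and a derived `treatment` label (C24/S24/C48/S48).
#' @export
library_design <- function(replicates = 3, library_size = 200000) {
  d <- expand.grid(replicate = seq_len(replicates),
                   condition = c("control", "salt"),
                   timepoint = c(24, 48),
                   stringsAsFactors = FALSE)
  d$treatment <- paste0(ifelse(d$condition == "control", "C", "S"),
                        d$timepoint)
  d$library <- paste0(d$treatment, "_", d$replicate)
  d$size <- library_size
  d[, c("library", "condition", "timepoint", "replicate", "treatment", "size")]
}

#' Specification for a synthetic genome with planted LTR retroelements
#'
#' Defaults describe a desk-scale genome emulating the structure of a plant
#' LTR-retroelement population: a 100-kb chromosome carrying 20 full-length
#' elements over four lineages (two per superfamily), lineage mean insertion
#' ages matching typical plant estimates (Ale 6.4, Angela 7.9, Tekay 5.3,
#' CRM 8.8 MY), ~46% non-autonomous elements, 5-bp TSDs, decoy solo LTRs and
#' 5'-truncated copies, ~8% per-element transcription (Copia-biased), and
#' gene models with GO terms.
#'
#' @param genome_length Chromosome length in bp.
#' @param lineage_counts Named integer vector of planted full-length element
#'   counts per lineage (supported: Ale, Angela for Copia; Tekay, CRM for Gypsy).
#' @param ltr_length_range Min/max LTR length (bp).
#' @param internal_length_range Min/max internal-region length (bp).
#' @param tsd_length TSD length (bp).
#' @param age_mean_my Named vector of mean insertion ages (million years) per
#'   lineage; per-element ages are gamma-distributed (shape `age_shape`).
#' @param age_shape Gamma shape of the age distribution.
#' @param age_max_my Upper truncation of planted ages (million years);
#'   older pairs would fall below the 85% LTR-identity detection bound and
#'   are not full-length-detectable by definition.
#' @param substitution_rate Per-site per-year rate for LTR divergence.
#' @param prop_nonautonomous Fraction of elements missing >= 1 domain cassette.
#' @param n_solo_ltr,n_truncated Decoy counts (solo LTRs; 5'-truncated copies
#'   sharing >= 90% identity with a planted element).
#' @param n_genes Gene models to place in the intergenic background.
#' @param gene_length_range Min/max gene length (bp).
#' @param prob_expressed Named vector: per-superfamily probability that an
#'   element is transcribed.
#' @param expressed_rpkm_mean Mean RPKM level of expressed elements
#'   (levels are 1 + exponential).
#' @param baseline_rpkm RPKM level of non-expressed elements.
#' @param de_frac Fraction of expressed elements given a planted salt
#'   fold-change.
#' @param de_fold Planted fold-change (salt vs control) for those elements.
#' @param dispersion Negative-binomial dispersion of replicate counts.
#' @param gene_proximity_boost Expression multiplier for genes lying within
#'   50 kb of an expressed element.
#' @param min_spacing Minimum gap between planted features (bp).
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `synthetic_genome_spec`.
#' @export
synthetic_genome_spec <- function(genome_length = 100000L,
                                  lineage_counts = c(Ale = 6L, Angela = 4L,
                                                     Tekay = 6L, CRM = 4L),
                                  ltr_length_range = c(250L, 450L),
                                  internal_length_range = c(1800L, 2300L),
                                  tsd_length = 5L,
                                  age_mean_my = c(Ale = 6.4, Angela = 7.9,
                                                  Tekay = 5.3, CRM = 8.8),
                                  age_shape = 2,
                                  age_max_my = 20,
                                  substitution_rate = 2.36e-9,
                                  prop_nonautonomous = 0.46,
                                  n_solo_ltr = 6L, n_truncated = 4L,
                                  n_genes = 20L,
                                  gene_length_range = c(400L, 1200L),
                                  prob_expressed = c(Copia = 0.20, Gypsy = 0.02),
                                  expressed_rpkm_mean = 2.74,
                                  baseline_rpkm = 0.05,
                                  de_frac = 0.1, de_fold = 4,
                                  dispersion = 0.1,
                                  gene_proximity_boost = 3,
                                  min_spacing = 1000L,
                                  seed = 1L) {
  stopifnot(genome_length > 0, all(lineage_counts >= 0),
            ltr_length_range[1] > 0, diff(ltr_length_range) >= 0,
            internal_length_range[1] > 0, tsd_length > 0,
            substitution_rate > 0, age_shape > 0, min_spacing >= 0)
  maxlen <- 2 * ltr_length_range[2] + internal_length_range[2]
  minlen <- 2 * ltr_length_range[1] + internal_length_range[1]
  if (minlen < 1500 || maxlen > 25000)
    stop("planted full-length element length must lie within [1500, 25000] bp")
  structure(as.list(environment()), class = "synthetic_genome_spec")
}

.lineage_superfamily <- c(Ale = "Copia", Angela = "Copia",
                          Tekay = "Gypsy", CRM = "Gypsy")
.domain_order <- list(Copia = c("GAG", "PR", "INT", "RT", "RH"),
                      Gypsy = c("GAG", "PR", "RT", "RH", "INT"))

# build the internal region: lineage-ordered domain cassettes (possibly
# dropping some for non-autonomous elements) joined by random spacers
.build_internal <- function(lineage, autonomous, target_len, refs) {
  sf <- .lineage_superfamily[[lineage]]
  doms <- .domain_order[[sf]]
  if (!autonomous) {
    drop_n <- sample(1:2, 1)
    doms <- setdiff(doms, sample(doms, drop_n))
  }
  cass <- vapply(doms, function(d) {
    s <- refs$seq[refs$lineage == lineage & refs$domain == d]
    reverse_translate(s)
  }, character(1))
  cass_len <- sum(nchar(cass))
  pad <- max(target_len - cass_len, 0)
  cuts <- sort(sample(0:pad, length(cass), replace = TRUE))
  spacers <- diff(c(0, cuts, pad))
  out <- random_dna(spacers[1])
  for (i in seq_along(cass))
    out <- paste0(out, cass[i], random_dna(spacers[i + 1]))
  out
}

#' Simulate a genome with planted full-length LTR retroelements
#'
#' Generates a random background chromosome and inserts, at non-overlapping
#' positions with at least `min_spacing` bp between features: full-length
#' elements (paired LTRs diverged according to their planted age, internal
#' domain cassettes in lineage-appropriate order, a TSD duplicated at both
#' flanks), decoy solo LTRs, decoy 5'-truncated copies (placed farther than
#' the maximum element length from their source so they cannot pair with it),
#' and gene models with GO terms.
#'
#' @param spec A [synthetic_genome_spec()].
#' @return A list of class `synthetic_genome` with components `genome`
#'   (a [Biostrings::DNAStringSet]), `truth` (planted-element table),
#'   `decoys`, `genes`, and `spec`.
#' @export
simulate_genome <- function(spec = synthetic_genome_spec()) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  set.seed(spec$seed)
  refs <- read_domain_reference()

  n_elem <- sum(spec$lineage_counts)
  lineages <- rep(names(spec$lineage_counts), spec$lineage_counts)

  elems <- vector("list", n_elem)
  for (i in seq_len(n_elem)) {
    lin <- lineages[i]
    sf <- .lineage_superfamily[[lin]]
    # truncated gamma: pairs older than ~25 MY fall below the 85% identity
    # detection bound, so planted "full-length detectable" ages are capped
    age <- Inf
    while (age > spec$age_max_my * 1e6)
      age <- stats::rgamma(1, shape = spec$age_shape,
                           scale = spec$age_mean_my[[lin]] / spec$age_shape) * 1e6
    ltr_len <- sample(spec$ltr_length_range[1]:spec$ltr_length_range[2], 1)
    int_len <- sample(spec$internal_length_range[1]:spec$internal_length_range[2], 1)
    autonomous <- stats::runif(1) >= spec$prop_nonautonomous
    anc <- random_dna(ltr_len)
    pair <- mutate_ltr_pair(anc, age, spec$substitution_rate)
    internal <- .build_internal(lin, autonomous, int_len, refs)
    tsd <- random_dna(spec$tsd_length)
    expressed <- stats::runif(1) < spec$prob_expressed[[sf]]
    level <- if (expressed) 1 + stats::rexp(1, 1 / max(spec$expressed_rpkm_mean - 1, 0.1))
             else spec$baseline_rpkm
    de_fold <- 1
    elems[[i]] <- list(id = sprintf("TE%03d", i), lineage = lin,
                       superfamily = sf, age = age, autonomous = autonomous,
                       seq = paste0(pair$ltr5, internal, pair$ltr3),
                       ltr_len = ltr_len, tsd = tsd,
                       expressed = expressed, level = level,
                       de_fold = de_fold)
  }
  # planted salt fold-changes among expressed elements
  expr_idx <- which(vapply(elems, `[[`, logical(1), "expressed"))
  n_de <- round(spec$de_frac * length(expr_idx))
  if (n_de > 0)
    for (i in sample(expr_idx, n_de)) elems[[i]]$de_fold <- spec$de_fold

  # decoys: solo LTRs are unrelated single LTRs; truncated copies keep the
  # 3' portion (internal tail + 3' LTR) of a source element, lightly mutated
  decoys <- list()
  if (spec$n_solo_ltr > 0)
    for (j in seq_len(spec$n_solo_ltr)) {
      len <- sample(spec$ltr_length_range[1]:spec$ltr_length_range[2], 1)
      decoys[[length(decoys) + 1]] <- list(id = sprintf("SOLO%02d", j),
                                           type = "solo", source = NA_character_,
                                           seq = random_dna(len))
    }
  if (spec$n_truncated > 0) {
    # sources drawn from distinct lineages where possible, so no two decoy
    # fragments carry the same cassette set
    first_of_lin <- match(unique(lineages), lineages)
    src <- sample(first_of_lin, min(spec$n_truncated, length(first_of_lin)))
    if (spec$n_truncated > length(src))
      src <- c(src, sample(setdiff(seq_len(n_elem), src),
                           spec$n_truncated - length(src)))
    for (j in seq_len(spec$n_truncated)) {
      s <- elems[[src[(j - 1) %% length(src) + 1]]]
      keep <- round(nchar(s$seq) * stats::runif(1, 0.25, 0.45))
      frag <- substr(s$seq, nchar(s$seq) - keep + 1, nchar(s$seq))
      frag <- mutate_ltr_pair(frag, 0.03 / spec$substitution_rate / 2,
                              spec$substitution_rate)$ltr5
      decoys[[length(decoys) + 1]] <- list(id = sprintf("TRUNC%02d", j),
                                           type = "truncated", source = s$id,
                                           seq = frag)
    }
  }

  feats <- c(elems, decoys)
  feat_len <- vapply(feats, function(f) {
    nchar(f$seq) + if (!is.null(f$tsd)) 2L * nchar(f$tsd) else 0L
  }, numeric(1))
  n_feat <- length(feats)
  slack <- spec$genome_length - sum(feat_len) - spec$min_spacing * (n_feat + 1)
  if (slack < 0)
    stop("infeasible packing: planted features exceed genome length")

  # layout attempts: shuffle feature order until truncated decoys land far
  # enough (> max element length) from their source element
  ok <- FALSE
  for (attempt in 1:200) {
    ord <- sample(n_feat)
    extra <- as.vector(stats::rmultinom(1, slack, rep(1, n_feat + 1)))
    gaps <- spec$min_spacing + extra
    pos <- numeric(n_feat)
    cur <- 0
    for (k in seq_len(n_feat)) {
      cur <- cur + gaps[k]
      pos[ord[k]] <- cur
      cur <- cur + feat_len[ord[k]]
    }
    ivs <- cbind(pos, pos + feat_len)
    bad <- FALSE
    for (k in seq_along(feats)) {
      f <- feats[[k]]
      if (!is.null(f$type) && f$type == "truncated") {
        si <- which(vapply(elems, `[[`, character(1), "id") == f$source)
        gap <- max(ivs[si, 1] - ivs[k, 2], ivs[k, 1] - ivs[si, 2])
        if (gap <= 25000) { bad <- TRUE; break }
      }
    }
    if (!bad) { ok <- TRUE; break }
  }
  if (!ok) stop("infeasible packing: could not separate decoys from sources")

  # assemble chromosome
  pieces <- character(0)
  cur <- 0
  truth <- list(); dec_tab <- list()
  ord_feats <- order(pos)
  cursor <- 0
  for (k in ord_feats) {
    f <- feats[[k]]
    gap_len <- pos[k] - cursor
    pieces <- c(pieces, random_dna(gap_len))
    start <- pos[k]
    if (is.null(f$type)) {  # full-length element with TSD flanks
      t <- nchar(f$tsd)
      pieces <- c(pieces, f$tsd, f$seq, f$tsd)
      es <- start + t
      ee <- es + nchar(f$seq)
      truth[[length(truth) + 1]] <- data.frame(
        element_id = f$id, chrom = "chr1", start = es, end = ee,
        ltr5_start = es, ltr5_end = es + f$ltr_len,
        ltr3_start = ee - f$ltr_len, ltr3_end = ee,
        tsd = f$tsd, lineage = f$lineage, superfamily = f$superfamily,
        age_years = f$age, autonomous = f$autonomous, copy_number = 1L,
        expressed = f$expressed, rpkm_level = f$level, de_fold = f$de_fold,
        stringsAsFactors = FALSE)
    } else {
      pieces <- c(pieces, f$seq)
      dec_tab[[length(dec_tab) + 1]] <- data.frame(
        decoy_id = f$id, type = f$type, chrom = "chr1",
        start = start, end = start + nchar(f$seq), source = f$source,
        stringsAsFactors = FALSE)
    }
    cursor <- pos[k] + feat_len[k]
  }
  pieces <- c(pieces, random_dna(spec$genome_length - cursor))
  chrom <- paste(pieces, collapse = "")
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(element_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0),
               ltr5_start = integer(0), ltr5_end = integer(0),
               ltr3_start = integer(0), ltr3_end = integer(0),
               tsd = character(0), lineage = character(0),
               superfamily = character(0), age_years = numeric(0),
               autonomous = logical(0), copy_number = integer(0),
               expressed = logical(0), rpkm_level = numeric(0),
               de_fold = numeric(0))
  truth <- truth[order(truth$start), ]
  rownames(truth) <- NULL
  dec_tab <- if (length(dec_tab)) do.call(rbind, dec_tab) else
    data.frame(decoy_id = character(0), type = character(0),
               chrom = character(0), start = integer(0), end = integer(0),
               source = character(0))

  # gene models in the intergenic background
  occupied <- rbind(cbind(truth$start - spec$tsd_length,
                          truth$end + spec$tsd_length),
                    cbind(dec_tab$start, dec_tab$end))
  genes <- .place_genes(spec, occupied)
  if (nrow(genes) > 0 && any(truth$expressed)) {
    expr <- truth[truth$expressed, , drop = FALSE]
    near <- vapply(seq_len(nrow(genes)), function(i) {
      any(pmax(expr$start - genes$end[i], genes$start[i] - expr$end, 0) < 50000)
    }, logical(1))
    genes$rpkm_level[near] <- genes$rpkm_level[near] * spec$gene_proximity_boost
  }

  genome <- Biostrings::DNAStringSet(chrom)
  names(genome) <- "chr1"
  structure(list(genome = genome, truth = truth, decoys = dec_tab,
                 genes = genes, spec = spec),
            class = "synthetic_genome")
}

.place_genes <- function(spec, occupied) {
  n <- spec$n_genes
  out <- list()
  go_pool <- sprintf("GO:%07d", 1:30)
  if (n > 0) {
    placed <- occupied
    for (g in seq_len(n)) {
      len <- sample(spec$gene_length_range[1]:spec$gene_length_range[2], 1)
      done <- FALSE
      for (try in 1:50) {
        s <- sample.int(spec$genome_length - len, 1)
        e <- s + len
        if (nrow(placed) == 0 ||
            all(pmax(placed[, 1] - e, s - placed[, 2]) >= 0)) {
          placed <- rbind(placed, c(s, e))
          out[[length(out) + 1]] <- data.frame(
            gene_id = sprintf("G%03d", g), chrom = "chr1",
            start = s, end = e,
            strand = sample(c("+", "-"), 1),
            rpkm_level = stats::rlnorm(1, meanlog = 0, sdlog = 2),
            stringsAsFactors = FALSE)
          done <- TRUE
          break
        }
      }
      if (!done) next
    }
  }
  genes <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               rpkm_level = numeric(0))
  genes$go <- lapply(seq_len(nrow(genes)), function(i)
    sample(go_pool, sample(1:4, 1)))
  genes
}

#' Simulate whole-genome DNA reads
#'
#' Reads are drawn uniformly from both strands of the genome; the read count
#' is `round(fold_coverage * genome_length / read_length)`. Substitution
#' errors are applied at `error_rate` per base.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param fold_coverage Target fold coverage.
#' @param read_length Read length in bp.
#' @param error_rate Per-base substitution error rate.
#' @param seed Integer seed.
#' @return A named [Biostrings::DNAStringSet] of reads.
#' @export
simulate_dna_reads <- function(genome, fold_coverage, read_length = 125,
                               error_rate = 0.002, seed = 1) {
  glen <- sum(Biostrings::width(genome))
  stopifnot(read_length <= min(Biostrings::width(genome)))
  set.seed(seed)
  n <- round(fold_coverage * glen / read_length)
  chrom <- sample(seq_along(genome), n, replace = TRUE,
                  prob = Biostrings::width(genome))
  reads <- character(n)
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(n)) {
    w <- Biostrings::width(genome)[chrom[i]]
    s <- sample.int(w - read_length + 1, 1)
    r <- as.character(Biostrings::subseq(genome[[chrom[i]]], s,
                                         s + read_length - 1))
    if (stats::runif(1) < 0.5)
      r <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r)))
    if (error_rate > 0) {
      hit <- which(stats::runif(read_length) < error_rate)
      if (length(hit)) {
        b <- strsplit(r, "")[[1]]
        for (h in hit) b[h] <- sample(setdiff(bases, b[h]), 1)
        r <- paste(b, collapse = "")
      }
    }
    reads[i] <- r
  }
  out <- Biostrings::DNAStringSet(reads)
  names(out) <- sprintf("r%06d", seq_len(n))
  out
}

#' Simulate RNA-seq counts (or reads) for the 12-library design
#'
#' Per-library expected counts scale as
#' `level * length_kb * library_size / 1e6` (the RPKM inversion); replicate
#' noise is negative-binomial, realised as gamma-distributed expression
#' weights sampled multinomially together with a background transcriptome
#' bucket, so each library total equals the design's library size exactly.
#' Elements with a planted fold-change have `level * de_fold` in salt
#' libraries.
#'
#' @param truth Planted-element table from [simulate_genome()].
#' @param genes Gene table from [simulate_genome()].
#' @param design A [library_design()] table; a warning (not an error) is
#'   raised when it does not have 12 libraries.
#' @param seed Integer seed.
#' @param dispersion Negative-binomial dispersion.
#' @param output `"counts"` for a count matrix; `"fastq"` additionally
#'   samples read sequences (requires `genome`).
#' @param genome Genome [Biostrings::DNAStringSet] (for `output = "fastq"`).
#' @param read_length Read length for FASTQ output.
#' @return A list with `counts` (feature x library integer matrix),
#'   `library_totals`, `design`, `features` (id, type, length, level), and,
#'   for FASTQ output, `reads` (list of DNAStringSet per library).
#' @export
simulate_rna_reads <- function(truth, genes, design = library_design(),
                               seed = 1, dispersion = 0.1,
                               output = c("counts", "fastq"),
                               genome = NULL, read_length = 125) {
  output <- match.arg(output)
  if (nrow(design) != 12)
    warning("design has ", nrow(design), " libraries, not the full 12")
  set.seed(seed)
  feats <- rbind(
    data.frame(id = truth$element_id, type = "element",
               length = truth$end - truth$start, level = truth$rpkm_level,
               de_fold = truth$de_fold, start = truth$start,
               chrom = truth$chrom, stringsAsFactors = FALSE),
    if (nrow(genes) > 0)
      data.frame(id = genes$gene_id, type = "gene",
                 length = genes$end - genes$start, level = genes$rpkm_level,
                 de_fold = 1, start = genes$start, chrom = genes$chrom,
                 stringsAsFactors = FALSE))
  counts <- matrix(0L, nrow(feats), nrow(design),
                   dimnames = list(feats$id, design$library))
  reads <- if (output == "fastq") vector("list", nrow(design)) else NULL
  for (j in seq_len(nrow(design))) {
    lib <- design[j, ]
    lev <- feats$level * ifelse(feats$de_fold != 1 & lib$condition == "salt",
                                feats$de_fold, 1)
    mu <- lev * (feats$length / 1000) * (lib$size / 1e6)
    w <- ifelse(mu > 0,
                stats::rgamma(length(mu), shape = 1 / dispersion,
                              scale = mu * dispersion),
                0)
    bg <- max(lib$size - sum(mu), 0)
    cc <- stats::rmultinom(1, lib$size, c(w, bg))[seq_along(mu), 1]
    counts[, j] <- cc
    if (output == "fastq") {
      stopifnot(!is.null(genome))
      rs <- character(sum(cc))
      pos <- 1
      for (f in which(cc > 0)) {
        for (r in seq_len(cc[f])) {
          len <- min(read_length, feats$length[f])
          off <- sample.int(feats$length[f] - len + 1, 1)
          s <- feats$start[f] + off
          rs[pos] <- as.character(
            Biostrings::subseq(genome[[feats$chrom[f]]], s, s + len - 1))
          pos <- pos + 1
        }
      }
      rr <- Biostrings::DNAStringSet(rs)
      names(rr) <- sprintf("%s_r%05d", lib$library, seq_along(rr))
      reads[[j]] <- rr
    }
  }
  out <- list(counts = counts, library_totals = stats::setNames(design$size,
                                                                design$library),
              design = design,
              features = feats[, c("id", "type", "length", "level", "de_fold")])
  if (output == "fastq") out$reads <- stats::setNames(reads, design$library)
  out
}
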