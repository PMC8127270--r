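#' Globally align the two LTRs of an element
#'
#' End-to-end (Needleman-Wunsch) alignment with match +5, mismatch -4, gap
#' open 16, gap extend 4 (a gap of length L costs 16 + 4L). Scoring is
#' configurable; the default is fixed for reproducibility.
#'
#' @param ltr5,ltr3 DNA strings (character or [Biostrings::DNAString]).
#' @param match,mismatch,gap_open,gap_ext Scoring parameters.
#' @return A list of class `ltr_alignment`: `aligned5`, `aligned3` (gapped
#'   strings of equal length), `n_columns`, `n_gap_columns`, `score`.
#' @export
align_ltrs <- function(ltr5, ltr3, match = 5, mismatch = -4,
                       gap_open = 16, gap_ext = 4) {
  stopifnot(nchar(as.character(ltr5)) > 0, nchar(as.character(ltr3)) > 0)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(as.character(ltr5)),
    Biostrings::DNAString(as.character(ltr3)),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch, baseOnly = FALSE),
    gapOpening = gap_open, gapExtension = gap_ext)
  a5 <- as.character(Biostrings::alignedPattern(pa))
  a3 <- as.character(Biostrings::alignedSubject(pa))
  gaps <- sum(strsplit(a5, "")[[1]] == "-" | strsplit(a3, "")[[1]] == "-")
  structure(list(aligned5 = a5, aligned3 = a3,
                 n_columns = nchar(a5), n_gap_columns = gaps,
                 score = Biostrings::score(pa)),
            class = "ltr_alignment")
}

#' Kimura two-parameter divergence of an LTR alignment
#'
#' Over gap-free columns with unambiguous bases on both rows, computes the
#' transition proportion P, the transversion proportion Q, and the K2P
#' distance `K = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)`. Columns containing a
#' gap or an ambiguous base (N etc.) are excluded from P, Q and the site
#' count. When a logarithm argument is non-positive the distance is
#' saturated and `K` is `NA` with `saturated = TRUE`.
#'
#' @param aln An `ltr_alignment` from [align_ltrs()], or a list with
#'   `aligned5`/`aligned3`.
#' @return A list of class `k2p_estimate`: `P`, `Q`, `K`,
#'   `comparable_sites`, `saturated`.
#' @export
k2p_distance <- function(aln) {
  a <- strsplit(aln$aligned5, "")[[1]]
  b <- strsplit(aln$aligned3, "")[[1]]
  stopifnot(length(a) == length(b))
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (sum(ok) < 1) stop("no comparable (gap-free, unambiguous) columns")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  diff <- a != b
  purine <- c("A", "G")
  ti <- diff & ((a %in% purine) == (b %in% purine))
  P <- sum(ti) / n
  Q <- sum(diff & !ti) / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  saturated <- arg1 <= 0 || arg2 <= 0
  K <- if (saturated) NA_real_ else -0.5 * log(arg1) - 0.25 * log(arg2)
  structure(list(P = P, Q = Q, K = K, comparable_sites = n,
                 saturated = saturated),
            class = "k2p_estimate")
}

#' Insertion age from an LTR divergence estimate
#'
#' The two LTR copies are identical at insertion and each accumulates
#' substitutions at rate `r` per site per year, so the expected pairwise
#' distance after T years is 2rT and the age estimate is `T = K / (2r)`.
#'
#' @param est A `k2p_estimate` from [k2p_distance()].
#' @param params A [dating_params()] list (or a rate via `rate`).
#' @param rate Substitution rate; overrides `params` when given.
#' @param min_sites Below this many comparable sites the age is flagged
#'   `too_short`.
#' @return A list of class `insertion_age`: `years`, `flag` (one of `ok`,
#'   `saturated`, `too_short`).
#' @export
insertion_time <- function(est, params = dating_params(), rate = NULL,
                           min_sites = 50) {
  r <- if (!is.null(rate)) rate else params$rate
  stopifnot(r > 0)
  if (isTRUE(est$saturated))
    return(structure(list(years = NA_real_, flag = "saturated"),
                     class = "insertion_age"))
  flag <- if (est$comparable_sites < min_sites) "too_short" else "ok"
  structure(list(years = est$K / (2 * r), flag = flag),
            class = "insertion_age")
}

#' Date all elements of a candidate table
#'
#' Aligns each element's 5' and 3' LTRs, computes the K2P distance and
#' converts it to an insertion age.
#'
#' @param genome A named [Biostrings::DNAStringSet].
#' @param cands Candidate table from [detect_full_length()].
#' @param rate Substitution rate per site per year.
#' @return A data.frame: `element_id`, `P`, `Q`, `K`, `comparable_sites`,
#'   `years`, `age_my`, `flag`.
#' @export
date_elements <- function(genome, cands, rate = 2.36e-9) {
  if (nrow(cands) == 0)
    return(data.frame(element_id = character(0), P = numeric(0),
                      Q = numeric(0), K = numeric(0),
                      comparable_sites = integer(0), years = numeric(0),
                      age_my = numeric(0), flag = character(0)))
  l5 <- element_sequences(genome, cands, "ltr5")
  l3 <- element_sequences(genome, cands, "ltr3")
  rows <- lapply(seq_len(nrow(cands)), function(i) {
    aln <- align_ltrs(as.character(l5[[i]]), as.character(l3[[i]]))
    est <- k2p_distance(aln)
    age <- insertion_time(est, rate = rate)
    data.frame(element_id = cands$element_id[i], P = est$P, Q = est$Q,
               K = est$K, comparable_sites = est$comparable_sites,
               years = age$years,
               age_my = round_half_up(age$years / 1e6, 1),
               flag = age$flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
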