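---
title: "Methods: detecting, dating and profiling full-length LTR retrotransposons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting, dating and profiling full-length LTR retrotransposons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`ltrdyn` characterises the full-length LTR-retrotransposon complement of a
genome assembly and relates three per-element quantities — genomic
abundance, insertion age, and transcription — to each other and to nearby
genes. The pipeline has seven stages: structural detection, redundancy
clustering, protein-domain annotation, insertion-age dating, read-based
quantification (DNA abundance and RNA expression with differential calls),
gene-proximity statistics with GO enrichment, and per-lineage trend
analyses. A synthetic-genome simulator with complete ground truth makes
every stage testable without external data; this vignette records the
models, the parameter choices, and the places where a design decision was
genuinely open.

# Structural detection

A full-length LTR retroelement is recognised purely structurally: two
similar direct repeats (the LTRs) whose extent and separation fall within
biological bounds, ideally flanked by a short target-site duplication (TSD)
created at insertion. The default parameter set is the standard one for
plant genomes:

| parameter | default | meaning |
|---|---|---|
| `min_ltr_len` / `max_ltr_len` | 100 / 6000 bp | admissible LTR length |
| `min_elem_len` / `max_elem_len` | 1500 / 25000 bp | element extent, 5' LTR start to 3' LTR end |
| `tsd_len` | 5 bp | exact TSD length searched |
| `min_similarity` | 85% | LTR-pair identity over a global alignment |
| `vicinity` | 10 bp | boundary shift allowed during TSD search |
| `seed_kmer` | 20 bp | exact seed length for the repeat finder |

The detector works seed-and-extend. All maximal exact direct repeats of at
least `seed_kmer` bp within the allowed span are found from a k-mer index
(a 20-mer seed is shared by an LTR pair with high probability even at the
85% identity floor). Seeds are grouped by exact diagonal and extended
outward by ungapped X-drop extension (match +1, mismatch -2, drop-off 20);
the extension stops where the two copies stop being homologous, i.e. at the
repeat boundaries. Pair identity is then scored on a gapped global
alignment (gaps count as mismatched columns), so substitutions *and* indels
inside the LTRs are tolerated at the identity stage; only the extension
assumes collinearity. On divergence dominated by indels the exact-diagonal
clustering would fragment a repeat — a known limitation relative to
suffix-array detectors, acceptable here because LTR pairs diverge mostly by
substitution on the time scales where they remain detectable.

Two structural filters remove the main false-positive classes:

* **Terminal-repeat (flank) check.** A genuine LTR pair has no homology
  continuing past its boundaries: outside the element lies host flank,
  inside lies internal sequence, and the two are unrelated. A repeat pair
  internal to a larger shared region — typically a protein-coding cassette
  shared by two family members sitting within 25 kb of each other — keeps
  matching on at least one side. Candidates whose outside flanks align
  locally (>= 30 matched bases at >= 85% identity within 1200 bp) are
  rejected.
* **Parsimony overlap resolution.** The TSD search runs first; conflicts
  between partially overlapping candidates are then resolved preferring
  TSD-supported candidates, then the shorter structure, then higher
  similarity. A candidate lying wholly inside another's internal region is
  a legitimate nested insertion: both are kept and the inner one flagged
  `nested`. A candidate whose internal region would swallow two or more
  independently-kept elements is treated as a false join and dropped.

Default reporting (`filter_elements()`) keeps TSD-supported, non-nested
candidates, the convention under which element catalogues are normally
counted. TSD-less and nested candidates remain available in the raw
candidate table.

Redundancy clustering is greedy-incremental in the CD-HIT style: sequences
sorted by decreasing length join the first cluster whose representative
aligns locally at >= 90% identity over >= 80% of the shorter sequence.
The internal sort makes the partition independent of input order.

# Domain annotation

Internal regions are translated in six frames and scanned against a
protein reference of the five retroelement domains (GAG, PR, INT, RT, RH)
by local alignment (BLOSUM62, gap open 10 / extend 4). Hits require >= 40%
identity over >= 50% of the reference protein — permissive enough for
diverged domains at protein level, strict enough that random 1.6-kb
sequences produce no hits. Per domain only the best-scoring hit is kept.

Classification follows standard retroelement biology: on the coding strand
(the strand of the best RT hit), integrase upstream of RT means Copia, RT
upstream of integrase means Gypsy; when the order is undecidable the
majority superfamily among hit labels is used, and conflicting labels are
flagged rather than forced to `unknown`. Lineage is the modal hit label
(ties by summed alignment score, then alphabetically). An element is
autonomous iff all five domains are present.

The bundled reference (`inst/extdata/domains_synthetic.faa`) is a
**synthetic stand-in**: fixed-seed random proteins for two Copia lineages
(Ale, Angela) and two Gypsy lineages (Tekay, CRM). It exists so that the
simulator can plant cassettes the annotator provably recovers; it carries
no real biological signal, and analyses of real genomes should substitute a
curated domain database in the same `>NAME|DOMAIN|SUPERFAMILY|LINEAGE`
FASTA dialect.

# Insertion-age dating

The two LTRs are identical at insertion and drift apart afterwards, so
their divergence clocks the insertion. The LTRs are aligned end-to-end
(match +5, mismatch -4, gap open 16, gap extend 4 — fixed for
reproducibility, configurable). Over gap-free, unambiguous columns the
transition proportion P and transversion proportion Q give the Kimura
two-parameter distance

K = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q),

and the age is T = K / (2r): both copies mutate, so the pair accumulates
divergence at twice the per-copy rate r. The default
r = 2.36 x 10^-9 substitutions/site/year is twice the synonymous rate
estimated for *Populus trichocarpa* genes, the convention for plant
retroelements, which accumulate substitutions faster than genes. Gap and
ambiguous columns are excluded from P, Q and the site count (the behaviour
of the standard distance tools; the alternative — counting them as
mismatches — would bias K upward for indel-rich pairs). Estimates carry a
flag: `saturated` when a logarithm argument is non-positive, `too_short`
below 50 comparable sites. Ages are reported in years; summaries round MY
to one decimal.

# The synthetic data generator

The generator is first-class, tested code; its defaults *are* the study
conditions for every property the suite asserts.

* **Genome**: one 100-kb random chromosome carrying 20 full-length
  elements (Ale 6, Angela 4, Tekay 6, CRM 4 — two lineages per
  superfamily), LTRs 250-450 bp, internals 1800-2300 bp, 5-bp TSDs
  duplicated at both flanks, features separated by >= 1 kb.
* **Ages**: per-lineage gamma (shape 2) with means Ale 6.4, Angela 7.9,
  Tekay 5.3, CRM 8.8 MY — the scale of published plant lineage means —
  truncated at 20 MY, because a pair older than ~25 MY falls below the 85%
  identity bound and is no longer a *detectable* full-length element; a
  generator of detectable elements should not plant undetectable ones.
* **Divergence model**: each LTR copy receives independent substitutions
  with per-site probability (age x rate), transitions twice as likely as
  transversions, so P is roughly 2Q and both logarithm terms of K are
  exercised. Expected pairwise divergence is 2 x rate x age. Indels are
  not simulated by default (the aligner must still handle them; the
  identity stage does).
* **Autonomy**: 46% of elements lack 1-2 domain cassettes, matching the
  published proportion of non-autonomous full-length elements.
* **Decoys**: 6 solo LTRs (unrelated sequence, must never be reported
  full-length) and 4 5'-truncated copies at ~97% identity to a planted
  element, which stress the unique-read accounting. Truncated decoys are
  placed more than the maximum element length away from their source, and
  sources are drawn from distinct lineages, so decoy fragments cannot pair
  with their relatives into pseudo-elements across the span limit.
* **Expression**: elements are transcribed with probability 0.20 (Copia)
  / 0.02 (Gypsy) — reproducing both the ~8% overall expressed fraction and
  its Copia bias — at RPKM levels 1 + Exp(mean 1.74) (mean 2.74);
  non-expressed elements sit at 0.05 RPKM. 10% of expressed elements get a
  planted 4-fold salt fold-change. Gene levels are log-normal (meanlog 0,
  sdlog 2), so the four expression categories are all populated; genes
  within 50 kb of an expressed element get a 3-fold boost, planting the
  proximity effect the category tests look for.
* **Reads**: DNA reads are uniform over both strands at
  round(coverage x genome / read length) reads of 125 bp with 0.002
  substitution errors. RNA counts follow the 2 x 2 x 3 design (control /
  salt, 24 / 48 days, 3 replicates, 200k reads per library): expected
  counts scale as level x kb x library-size/10^6, replicate noise is
  negative-binomial (dispersion 0.1; the choice is ours — published
  read-mapping summaries do not constrain it), realised as gamma expression
  weights sampled multinomially together with a background-transcriptome
  bucket so library totals are exact.

What passing tests on this generator do *not* show about real data: no
indel divergence in LTR pairs, no nested insertions, no sequencing-quality
structure, no tandem or centromeric repeat background, uniform read
sampling without GC bias, and a domain reference the elements match
verbatim. The detection and annotation accuracies measured here are
therefore upper bounds.

# Quantification and differential expression

Reads map by seed-and-extend local alignment; an assignment requires >= 90%
identity and >= 90% of the read aligned, matching stringent-mapping
conventions. All passing references are recorded; the best-scoring one is
the primary assignment (ties broken deterministically by reference id), a
multi-mapping read contributes exactly one count, and the `unique` flag
(exactly one passing reference) yields the per-library unique-read
fraction.

Genomic abundance is average coverage: aligned bases of primary
assignments divided by element length. Expression is
RPKM = counts x 10^9 / (library total x length in bp); an element is
*expressed* when RPKM exceeds 1 in at least one library (strict
inequality). Per-treatment expressed sets (>= 1 replicate above threshold)
feed the four-set intersection table.

Differential expression between conditions at one timepoint uses a
negative-binomial exact test: counts are scaled to the geometric-mean
library size, a common dispersion is estimated across elements by the
method of moments (phi = sum(var - mean) / sum(mean^2) over per-condition
summaries; non-positive estimates fall back to the Poisson/binomial
conditional), and the group sums are tested conditionally on their total —
a distribution free of the unknown mean — summing the probabilities of all
outcomes no more probable than the observed one. This is an approximation
of the widely-used pairwise exact test with common dispersion (on shared
fixtures the two agree to r > 0.999 on -log10 p); trended or tagwise
dispersion estimation is deliberately out of scope at 3 + 3 replicates.
Calls require both FDR < 0.05 (Benjamini-Hochberg) and |fold change| > 2;
the fold change is computed on prior-damped group means (prior 0.5), so a
significant 1.5-fold shift is still reported `ns`.

# Proximity and GO statistics

Genes within 50 kb of an element (interval overlap after extending the
element both ways; with half-open coordinates a 49,999-bp gap is in, a
50,001-bp gap is out) form (gene, element) pairs with the gap as distance
(0 on overlap). The interval query runs on an interval index and is tested
identical to a quadratic scan.

Gene expression categories partition mean RPKM as [0,1) not / [1,10) low /
[10,100) medium / [100,inf) high; the conventional verbal bounds leave the
boundary points unassigned, so half-open-left intervals were adopted to
make the partition total (10.0 is medium). A gene near both an expressed
and a non-expressed element counts in the near-expressed group — activity
dominates. Category differences use two-sided Fisher tests on the per-
category 2x2 tables with BH correction across the four categories; GO
enrichment of genes near expressed elements against the annotated gene
universe uses one-sided (over-representation) Fisher tests, BH-corrected
across terms with at least one selected gene. Term annotations are used as
given — no propagation up the ontology graph.

# Trend statistics

Per-lineage summaries report counts and percentages (rounded half away
from zero to 2 decimals; summaries expose both the grand total and the
classified total since catalogues often disagree between the two).
Across-lineage comparisons of coverage, age and RPKM use one-way ANOVA
with Tukey HSD (Tukey-Kramer under unequal n) on untransformed values — the
conventional presentation; a log10(x+1) alternative is available — and a
compact letter display built by insert-and-absorb over the
non-significance graph, letters ordered by descending group mean.
Age-abundance-expression trends are ordinary least squares with Pearson r
and a t-based two-sided p (reported as NA below n = 3); the slope table
mirrors the four-treatment layout (C24, S24, C48, S48) for expression
against age and against abundance, restricted to Copia elements for the
expression correlations because Gypsy expression is too low to regress
meaningfully. Slope differences between treatments are reported
descriptively, without an interaction test.

# Numerical and scale choices

* All internal coordinates are 0-based half-open; GFF3 conversion happens
  only at the I/O boundary.
* Candidate LTRs with > 10% N are discarded; alignment identity over Ns is
  undefined.
* The problem sizes exercised by the test-suite and the acceptance script
  — a 100-kb genome with 20 elements and 10 decoys, 3x DNA coverage,
  200k-read RNA libraries, 100 dating replicates per age, 50 DE power and
  20 null simulations — are the package's reference study conditions,
  chosen to estimate each property with comfortable Monte-Carlo margins at
  desk scale.
* Tie-breaks are deterministic everywhere: TSD shifts by smallest total
  shift then leftmost; clustering by length then id; read assignment by
  score then reference id; lineage by score then alphabet.

# Known limitations

* Ungapped seed extension under-performs on indel-rich LTR pairs.
* Paired fragments of two same-lineage truncated copies can occasionally
  mimic a full-length structure that passes every filter (the flank check
  cannot see past a truncation breakpoint); published catalogues handle
  such cases by manual curation.
* The exact DE test with a single moment-estimated dispersion is
  conservative-to-nominal at small replicate counts but does not model
  per-element dispersion.
* PBS/PPT annotation, inverted-repeat elements, spliced alignment and
  TMM-style normalisation are out of scope.
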