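# ltrdyn

Detection, dating and expression dynamics of full-length LTR
retrotransposons.

## The problem

Long-terminal-repeat (LTR) retrotransposons make up a large share of plant
genomes. With a contiguous long-read assembly it becomes possible to
catalogue every *full-length* element — two similar LTRs flanking an
internal coding region, bracketed by a target-site duplication (TSD) — and
then ask how the catalogue behaves: which superfamilies (Copia, Gypsy) and
lineages (Ale, Angela, Tekay, CRM, ...) dominate, how abundant each element
is in the genome, when it inserted, whether it is transcribed (e.g. under
salinity stress), and how its activity relates to genes within 50 kb.
`ltrdyn` implements that entire workflow as a tested R package, for
genome/repeat biologists who want the analysis reproducible end to end.

At its core are three standard models:

* **Structural detection** — paired direct repeats with LTR length in
  [100, 6000] bp, element extent in [1500, 25000] bp, pair identity >= 85%,
  and a 5-bp TSD searched within +/-10 bp of each boundary.
* **K2P insertion dating** — from the LTR-pair alignment's transition (P)
  and transversion (Q) proportions,
  `K = -1/2 ln(1-2P-Q) - 1/4 ln(1-2Q)`, and the age `T = K/(2r)` with
  `r = 2.36e-9` substitutions/site/year (both copies mutate, hence the 2).
* **Expression quantification** — stringent read mapping (>= 90% identity
  over >= 90% of the read), `RPKM = counts * 1e9 / (total * length)`,
  expressed means RPKM > 1 in at least one library, and a
  negative-binomial exact test (common moment-estimated dispersion,
  BH-FDR < 0.05, |FC| > 2) for differential expression between control and
  salt-treated libraries.

Everything runs against a synthetic-genome simulator that plants elements
with known coordinates, lineage, age, autonomy and expression, so every
stage is verifiable against ground truth.

## Worked example

```r
library(ltrdyn)

spec <- synthetic_genome_spec(seed = 1)     # 100-kb genome, 20 planted elements
res  <- run_ltr_pipeline(spec, outdir = "results/run1")
res
#> LTR retroelement pipeline run
#>   genome: 100000 bp, 20 planted elements, 10 decoys
#>   detected: 20 candidates, 20 reported elements
#>   clusters: 20; autonomous: 7
#>   expressed (RPKM > 1 in >= 1 library): 8
#>   DE at 24 d: 0; at 48 d: 0
```

All 20 planted elements are recovered (boundary error <= a few bp), each
with a TSD; 7 carry all five protein domains (GAG-PR-INT-RT-RH for Copia,
GAG-PR-RT-RH-INT for Gypsy) and are therefore autonomous; 8 exceed the
RPKM > 1 expression threshold in at least one of the 12 libraries. Per-
element detail:

```r
head(res$ages[, c("element_id", "K", "age_my", "flag")], 3)
#>   element_id           K age_my flag
#> 1     FL0001 0.030541035    6.5   ok
#> 2     FL0002 0.103668942   22.0   ok
#> 3     FL0003 0.007407543    1.6   ok
```

`K` is the K2P distance between the element's two LTRs and `age_my` the
implied insertion age in million years. `results/run1/` holds the full set
of TSV tables (elements, clusters, annotation, ages, abundance, RPKM,
expressed set, DE at both timepoints, gene proximity, GO enrichment,
lineage summary, regression slopes) plus the element GFF3.

Individual stages are exported too — `detect_full_length()`,
`cluster_elements()`, `annotate_elements()`, `date_elements()`,
`map_reads()`, `rpkm_matrix()`, `differential_expression()`,
`genes_near_elements()`, `go_enrichment()`, `anova_tukey()`,
`slope_table()` — and accept ordinary FASTA/GFF3/TSV inputs for use on
real data.

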