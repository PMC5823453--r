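# rnaeditome

Discovery of A-to-I RNA editing sites from RNA-seq variant calls alone.

ADAR enzymes deaminate adenosine to inosine in double-stranded RNA, and
inosine is read as guanosine, so an edited adenosine shows up as an A>G
mismatch between RNA-seq reads and the reference genome. Without matched
DNA from the same individual, every germline SNP, sequencing error and
alignment artefact mimics that signal. `rnaeditome` is for researchers who
have per-sample RNA-seq variant calls (VCFs with allele depths and
GATK-style site annotations) from several individuals and tissues and want
a high-confidence, annotated editome out of them.

The core is a deterministic filter cascade with single-reason provenance:

1. remove known SNPs (position-based);
2. GATK-style site quality — fail iff HRun > 5, DP < 10, MQ < 40, QD < 2,
   MQRankSum < −12.5 or ReadPosRankSum < −8;
3. allele filters — one non-reference allele, heterozygous call, DP ≥ 10
   with ≥ 3 supporting reads, and editing ratio
   *r* = AD<sub>alt</sub>/DP in [0.10, 1.0);
4. sequence context — no bidirectional transcription, outside simple
   sequence repeats (motif 1–8 nt, span ≥ 6, ±3 bp offset), > 5 bp from
   intron/exon boundaries, and a 101-bp flank window unique in the
   assembly (seeded Smith–Waterman, ≥ 90% identity / ≥ 90% coverage rule);
5. recurrence — a site must be seen in ≥ 2 individuals.

Survivors are classified on the transcribed strand (a genomic T>C in a
minus-strand gene is A>G), grouped into hyper-editing clusters (gaps
≤ 100 bp), and the editome is extended by recruiting quality-passing
variants within 100 bp of a high-confidence A>G site. Sites are annotated
(region, coding consequence, repeat family), summarised as a 12-way
mismatch spectrum and per-tissue statistics (pooled-variance t-tests with
Benjamini–Hochberg FDR), profiled for neighbour preferences (position
frequency matrix, G depletion/enrichment at −1/+1), and optionally
validated by flank alignment against EST or known-editome sequence sets
with Karlin–Altschul e-values.

A seeded synthetic-study generator (`simulate_study()`) produces a
complete miniature study — genome, gene models, SINE-like repeats, known
SNPs, 3 individuals × 9 tissues of VCFs, and a planted-site truth ledger —
for end-to-end recovery evaluation.

## Worked example

```r
library(rnaeditome)

cfg <- synthetic_config(seed = 1)          # 1 Mb genome, 120 planted sites
st  <- simulate_study(cfg, "study")
res <- run_pipeline("study", "out")
#> [cascade] filtering 13274 observations
#> [recurrence] 2328 passing observations
#> [clusters] 120 high-confidence sites
#> [done] 120 high-confidence sites, 2 extended, 68.0s

ev <- evaluate_recovery(res$sites, st$planted$truth)
ev$precision; ev$recall
#> [1] 1
#> [1] 1

attr(res$spectrum_raw,   "a_to_i_fraction")   # % A>G before filtering
#> [1] 68.35085
attr(res$spectrum_final, "a_to_i_fraction")   # % A>G after the cascade
#> [1] 100
nrow(res$clusters)                            # hyper-editing clusters
#> [1] 23
res$pfm$g_fraction_p1                         # G at +1 of the edited A
#> [1] 0.475
```

Reading the numbers: 27 sample VCFs contribute 13,274 observations; known
SNPs, quality, allele, context and recurrence filters reduce them to the
120 planted A>G sites (precision and recall 1 against the truth ledger —
the planted error SNVs are singletons, so recurrence removes every one).
The A>G share of the surviving set rises from 68% in the raw pool to 100%,
the spectrum-enrichment signature of a working cascade; 110 of the sites
lie in 23 clusters, and the planted T(−1)/G(+1) context bias appears as a
G fraction of 0.475 at +1 against the 0.25 background.

`run_pipeline()` writes `sites.tsv`, `clusters.tsv`, `extended_sites.tsv`,
`spectrum.tsv`, `tissue_matrix.tsv`, `filter_ledger.tsv`, `pfm.tsv` and a
JSON run manifest with per-stage counts. A thin command-line front-end
lives at `inst/scripts/editome.R` (`run`, `simulate`, `evaluate`
subcommands).

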