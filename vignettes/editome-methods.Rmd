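---
title: "Detecting A-to-I RNA editing from RNA-seq variant calls: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting A-to-I RNA editing from RNA-seq variant calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaeditome)
```

## The problem

ADAR enzymes deaminate adenosine to inosine in double-stranded RNA; the
sequencing and splicing machinery read inosine as guanosine, so an edited
adenosine appears as an A>G mismatch between RNA reads and the reference
genome. Calling the editome from RNA-seq alone — without matched DNA from
the same animal — means every germline SNP, sequencing error and alignment
artefact is a potential false positive. `rnaeditome` implements a
filter-cascade strategy for this setting: per-sample variant calls (VCFs
with allele depths and GATK-style site annotations) are pushed through a
fixed sequence of quality, allele, sequence-context and cross-sample
filters, and the survivors are characterised as an editome.

## The filter cascade

Each per-sample observation is tested in a fixed order, and a rejected
observation records exactly the **first** failing stage, so that the stage
counts in the run ledger sum exactly to input minus survivors:

1. **Known SNPs** — observations at positions present in the known-SNP VCF
   are removed. Matching is by position, not allele, because a site that is
   polymorphic in the population is unreliable evidence of editing whatever
   allele was seen; allele-aware matching is available
   (`snp_match_alleles`).
2. **Site quality** (GATK annotations, strict inequalities as stated):
   fails when HRun > 5, depth < 10, MQ < 40, QD < 2, MQRankSum < −12.5 or
   ReadPosRankSum < −8. A value exactly at a boundary passes. Missing
   annotations pass — third-party VCFs often lack INFO keys, and failing
   them would silently zero a run; HRun is recomputed from the genome when
   absent (longest run of bases equal to the ALT allele adjacent to the
   site).
3. **Alleles and editing ratio**: fails on more than one non-reference
   allele, a homozygous-alternative genotype, depth < 10, fewer than 3
   supporting reads, editing ratio (= alt depth / total depth) below 10%,
   or a ratio of exactly 100% (full variation is a genotype, not editing).
   The ratio comes from the caller's AD/DP fields, not a recomputed pileup.
4. **Bidirectional transcription** — positions covered by genes on both
   strands are removed; the transcribed strand there is ambiguous.
5. **Simple sequence repeats** — maximal perfect tandem repeats with a
   primitive motif of 1–8 nt spanning ≥ 6 bases mask positions within ±3
   bases. The canonical motif is the lexicographically minimal rotation,
   and a run is reported once (a poly-A run is "A", never also "AA"); this
   maximal-perfect-repeat reading is the defensible reconstruction of a
   microsatellite scanner whose exact tie-breaking is not documented.
6. **Splice junctions** — intronic positions within 5 bp of an exon
   boundary are removed (misalignment around junctions).
7. **Flank uniqueness** — the 101-bp window (50 bp each side) must occur
   exactly once in the assembly. The window is searched on both strands
   with exact 12-mer seeding followed by Smith–Waterman verification of
   each seeded locus; a locus counts when identity ≥ 90% over ≥ 90% of the
   window. The named aligner of the original protocol publishes no
   acceptance rule, so this mirrors common near-duplicate practice and is
   configurable; an external aligner's PSL output can be substituted
   (`uniqueness_from_psl()`).

**Strand.** The mismatch class is reported on the transcribed strand: a
genomic T>C inside a minus-strand gene is A>G. Strand comes from the
covering gene when all covering genes agree, else from the single gene
within 5 kb; fully intergenic sites keep the plus-strand label with
`strand_source = "unknown"` rather than a guess, because a VCF carries no
read-level orientation.

**Recurrence.** Surviving observations are grouped by (contig, position,
transcribed-strand alleles); a site becomes *high-confidence* when it is
supported in at least 2 of the study's individuals — in any tissue, since
the defining property of editing is recurrence across animals, not within a
tissue (`recurrence_same_tissue` restricts it). A site's tissue set is
every tissue with at least one passing support; its per-tissue editing
ratio is the mean over that tissue's supporting samples.

## Clusters and extension

ADAR edits promiscuously within double-stranded regions, so true sites
cluster. Sites joined by gaps of ≤ 100 bp (single linkage, inclusive at
100) form clusters; "within a 100 bp window" is ambiguous between
span-bounded and gap-bounded grouping, and the gap-bounded reading is used
because it is the one under which chains of near neighbours stay together.
The editome is then *extended*: every variant that survived known-SNP
subtraction and the quality filters (a deliberately relaxed pool) and lies
within 100 bp of a high-confidence A>G site is recruited with
`origin = "extended"`, keeping its own mismatch class and without
re-applying allele filters. Extension is single-pass — newly recruited
sites do not recruit further — because recruitment is anchored on the
initial high-confidence candidates; `transitive_extension` enables the
iterated closure for comparison.

## Annotation and statistics

Region classification uses the precedence CDS > UTR5/UTR3 > intron >
pseudogene > upstream (≤ 5 kb, strand-aware) > downstream (≤ 5 kb) >
intergenic; when transcripts disagree the highest-precedence region wins
(no canonical-transcript selection). Bodies of non-coding genes that are
neither protein-coding nor pseudogenes are classed as intronic, the closest
member of the closed region vocabulary. Coding consequences rebuild the
codon from the CDS phase on the coding strand and translate with the
standard genetic code; stop gain/loss are reported alongside
synonymous/non-synonymous for completeness. Repeat overlap reports the
single covering repeat, longest first on ties.

Tissue contrasts of editing ratios use the classic pooled-variance
two-sample Student t-test (Welch is available via `var_equal = FALSE`) on
per-site per-tissue mean ratios, Benjamini–Hochberg corrected across all
tissue pairs at q < 0.05. When both groups are constant and equal, p = 1 by
convention. Deaminase-expression association is a Pearson correlation
between summed family TPM and per-tissue editing counts.

## Neighbour preferences and validation

The neighbour-preference matrix counts bases at −10..+10 around the edited
adenosine on the transcribed strand; edge-clipped sites are excluded
column-wise, so every column sums to its number of contributing sites, and
position 0 is pure A by construction. Information content is `2 − H` bits
with no small-sample correction — the headline numbers are the G fractions
at −1 (depletion) and +1 (enrichment), not the logo heights.

Flank validation aligns each 101-nt flank against a reference set (ESTs,
or a known editome for conservation) with a shared 11-mer prefilter and
Smith–Waterman scoring +1/−2, gap open 5, gap extend 2. E-values follow
Karlin–Altschul, `E = K·m·N·exp(−λS)` with `N` the total reference length:
λ is solved numerically for this scheme under uniform base composition
(λ ≈ 1.33) and K is the standard tabulated constant 0.621 for +1/−2;
replicating a full BLAST statistics stack is a non-goal since the
accept/reject thresholds dominate. Profiles: EST support requires e ≤ 1e-5;
conservation requires e ≤ 1e-3, identity ≥ 0.85 and alignment length ≥ 50
(the source's "> 0.85% identity" is read as the 85% it plainly intends;
identity counts matches over all alignment columns, gaps included).
External tabular (outfmt-6) hits can be ingested instead.

## The synthetic study

`synthetic_config()` defines a miniature version of the study design the
pipeline expects — 3 individuals × 9 tissues of strand-specific calls — on
a 1 Mb single-contig genome with 30 genes laid out in equal slots with wide
intergenic margins. Defaults and the reasoning behind the free choices:

* **120 A>G edit sites** planted at transcribed-strand adenosines inside
  genes or their 2 kb flanks, in clusters with geometric sizes (mean 3) and
  member gaps ≤ 100 bp; 80% of clusters inside repeats. Each site carries a
  Beta(2, 4) editing ratio truncated to [0.10, 0.95], is present in 2 or 3
  individuals, and in each tissue independently with probability 0.6.
* **Sequence context**: sites are drawn with 3× selection weight for T at
  −1 and for G at +1, giving ≈ 50% marginal frequency for each against the
  25% background — enough for the depletion/enrichment signal to be
  testable without rewriting the genome.
* **200 SINE-like repeats**, 150 bp copies of one consensus with 15%
  per-base divergence, 30% inserted in inverted orientation. The
  divergence level matters: at 15% per copy, two copies agree at roughly
  72%, so the 101-bp flanks of sites inside repeats stay below the 90%
  near-duplicate threshold and survive the uniqueness filter — the
  behaviour of genuinely diverged genomic repeat families. Near-identical
  copies would make the uniqueness filter erase most of the planted truth.
* **Confounds**: 400 known SNPs (listed, all individuals, 30% homozygous),
  300 error SNVs (each in exactly one sample, ratio 0.10–0.25, alternative
  alleles drawn uniformly), and 60 private het SNPs in one individual each,
  deliberately *not* listed — the acknowledged blind spot of any
  RNA-only pipeline. Because private SNPs sit in a single individual they
  die at the recurrence stage here; a *shared* unknown SNP would be
  indistinguishable from an edit, and no test pretends otherwise.
* Read support is Poisson depth (mean 40, floor 10) with binomial
  alternative counts at the true ratio; no base-quality or read-level
  simulation, since the pipeline consumes VCFs, not reads. GATK annotations
  are emitted as clean passing values, and HRun is left out so the
  pipeline's local recomputation is exercised.

What passing on this generator shows — and what it does not: recovery of
clustered, repeat-enriched, recurrent A>G sites against positionally random
confounds, with error leakage ≈ 0 because singleton errors cannot recur.
It does not emulate alignment artefacts that correlate across individuals,
shared unknown SNPs, or depth that varies systematically between
individuals; real-data precision will be lower than synthetic precision.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive throughout (VCF-native); BED is
  converted at the boundary.
* All printed thresholds are strict as printed: HRun 6 fails and 5 passes,
  depth 10 passes, ratio 0.10 passes, ratio 1.0 fails, a 100 bp cluster gap
  joins.
* Multi-allelic records are kept at parse time and rejected by the allele
  filter, so the ledger shows the documented reason rather than a parser
  side-effect.
* Windows clipped at contig ends are flagged and searched at their reduced
  length; an all-N window is non-unique by convention.
* The t-test falls back to t = 0, p = 1 on constant equal groups;
  `evaluate_recovery()` reports precision `NA` on an empty call set.

## Problem sizes

The default generator (1 Mb, 120 sites, 27 samples) runs the full pipeline
in about a minute on one core and is the configuration used by the
package's own end-to-end checks and by `scripts/acceptance.R`; unit tests
use 100–200 kb studies. These sizes were chosen so that the exhaustive
oracles (brute-force repeat enumeration, connected components, full
Smith–Waterman scans) remain feasible alongside the implementation.

## Known limitations

* RNA-only calling cannot separate editing from SNPs shared across
  individuals but absent from the SNP catalogue.
* Strand assignment for intergenic sites more than 5 kb from any gene is
  unresolved; such sites keep genomic labels and are excluded from A>G
  accounting rather than guessed.
* The built-in uniqueness and validation aligners are desk-scale; for
  genome-scale work, feed BLAT PSL or BLAST tabular output through the
  provided ingest functions.
* Per-tissue editing ratios average over supporting samples; no shrinkage
  or depth weighting is applied.
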