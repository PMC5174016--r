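---
title: "Methods: whole-ecosystem saliva metagenome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-ecosystem saliva metagenome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salivalink)
```

## The problem

Shotgun sequencing of total saliva DNA captures two genomes at once: the
human host's and that of the resident microbial community. salivalink
implements the downstream analysis of such "whole-ecosystem" data in four
stages — host/microbiota read partitioning, hierarchical functional
profiling, genome–function linkage, and consensus host SNP calling — and
pairs each stage with a synthetic-data generator whose ground truth makes
the statistical behaviour of every step testable.

The package consumes the products of upstream tools rather than running
them: alignment tables (reads mapped to the host genome and to reference
microbial genomes), gene catalogs in the style of subsystem-annotation
exports, gene models, reference sequences, and VCF callsets. Read mapping,
assembly and annotation themselves are out of scope.

## Read partitioning

A read pair is labelled **host-originating** when both mates map to the
host genome with mapping quality strictly exceeding a threshold (default
MAPQ 100); every other pair is **microbiota-originating**. Two boundary
choices are deliberate and tested:

* *strict inequality* — a mate at exactly the threshold fails the rule;
* *missing mates count as MAPQ 0* — the rule requires evidence from both
  mates, so a single-mapped pair is classed microbial. Upstream practice
  varies here and no convention is universal; ours is declared rather than
  inferred, and encoded in one place.

The synthetic read simulator emits MAPQ pairs from a two-point mixture:
host pairs produce both mates at MAPQ 150 with probability
`1 - crossmap_rate`, otherwise both mates uniform on 0–100, and microbial
pairs do the reverse. This makes the expected misclassification rate of
the partition rule *exactly* `crossmap_rate`, so recovery tests have an
analytic target rather than an empirical one. Origins are drawn
multinomially from `(host_fraction, (1 - host_fraction) * abundances)`,
which introduces the sampling variability a recovery test must tolerate.
The demo study uses host fractions of 0.7 for healthy-host samples and
0.45 for caries-active samples, i.e. microbial fractions of roughly 30%
and 55%, the regime reported for such cohorts.

## Functional profiles

Gene catalogs assign each gene a path through a four-level subsystem-style
hierarchy (hierarchy 1–3 plus the function level). Profiles at level *k*
aggregate per-gene hit counts by the level-*k* ancestor, so counts are
conserved exactly across levels; relative abundances are computed over
known-function records only, with unknown-function genes tracked as a
separate fraction (real annotation exports leave 25–63% of sequences
unknown, and folding that into the denominator would make profiles
incomparable across samples).

Derived statistics:

* **Core/pan functions** — intersection/union of per-sample function sets.
  The paired "gene sequence" counts are defined as the across-sample sum
  of hits annotated to core (respectively any) functions; this definition
  is declared because set sizes alone say nothing about how much sequence
  supports them.
* **Enrichment signatures** — `100 * (RA_a - RA_b) / RA_b` per category.
  The formula satisfies the antisymmetry
  `(1 + e_ab/100) * (1 + e_ba/100) = 1`, which the suite tests. Categories
  absent from the reference profile get an `exclusive_a` sentinel rather
  than an infinite percentage.
* **Pathway-unique proteins** — distinct functions under a pathway seen in
  one group but not the other, with their relative excess.
* **Ordination** — PCA on centred, unscaled relative-abundance vectors
  over the union category universe (zero-filled). Centring without scaling
  keeps the analysis on the abundance scale the profiles are reported in;
  scaling would inflate rare categories. Coordinates are deterministic up
  to component sign, which is the invariance the tests assert.
* **Clustering** — agglomerative clustering of Euclidean distances between
  relative-abundance vectors; exported as Newick.

The generator expresses group shifts on *relative abundances*: a 2× shift
on chosen categories multiplies their expected share by 2 and shrinks all
other categories proportionally. A count-multiplication shift would be
partially absorbed by renormalisation and could not be recovered as +100%
enrichment; the relative formulation makes the generative parameter and
the estimand coincide.

## Genome–function linkage

The linkage database couples each annotated gene to its originating genome
and stores per-genome mapped-read abundances. From the genome × category
count matrix `M` at any level:

* **dominant genomes** — top-*k* (default 5) by mapped-read abundance, the
  read-based definition rather than gene-hit counts; ties break
  lexicographically for reproducibility;
* **dominant functions** — top-*k* categories by column sum;
* **functional diversity** — per genome, the fraction of the community's
  observed categories it encodes (`M > 0` presence, not Shannon entropy:
  the statistic mirrors "fraction of functions encoded");
* **dominant contribution** — per category, the fraction of gene sequences
  originating from the dominant genomes (monotone non-decreasing in *k*,
  equal to 1 at *k* = number of genomes);
* **diversity–abundance trend** — Spearman rank correlation (average-rank
  ties) between abundance and diversity; when either variable is constant
  the statistic is defined as 0;
* **origin breadth** — number of genomes contributing to each category,
  with its rank correlation against category totals.

These statistics can reproduce a characteristic dissociation of such
communities: when dominant genomes hold 70% of mapped reads but every
functional category is spread over many genomes, no category draws even
half its sequences from the dominant set — functional redundancy makes no
single phylotype irreplaceable. The suite constructs exactly this
configuration and checks both numbers.

## Consensus host variants

Two caller outputs are intersected exactly on `(chrom, pos, ref, alt)`;
SNVs only. The consensus depth is the **minimum** of the two callers'
depths — conservative, since which caller's depth field to trust is
unspecified in common practice. The depth filter is inclusive
(`depth >= 30` keeps a 30× site). Sites where callers disagree on the
reference allele are excluded with a warning and counted.

Region classification uses the precedence
`exonic > splicing > UTR > intronic > intergenic` (exonic = coding
sequence; splicing = first/last 2 bp of an intron), so classes are
exhaustive and mutually exclusive even where annotations overlap. Coding
effects are resolved at the codon level: the variant's codon is located
from the CDS frame, minus-strand genes complement the alleles, and
reference versus alternate codons are translated with the standard
genetic code into synonymous / nonsynonymous / stopgain / stoploss. The
test suite checks every call against an independent oracle that
translates the entire mutated CDS (with the initiator-codon special case
disabled, matching codon-table semantics).

The callset simulator draws per-site false negatives independently per
caller and visits every non-variant position independently with the
caller's false-positive rate. The erroneous allele at a site is a
deterministic transition of its reference base — a property of the site,
emulating systematic alignment-driven errors — so both callers report an
identical record when they hit the same site, and the consensus
false-positive count is `Binomial(candidates, fp_a * fp_b)`. With
independent random alt alleles instead, the intersection-survival rate
would carry an extra factor of 1/3 and the independence product would not
be the analytic target.

Chromosome-level uniformity is summarised by the chi-square statistic of
per-chromosome SNP counts against a length-proportional expectation
(degrees of freedom = chromosomes − 1; undefined for a single
chromosome).

## The synthetic generators: what they do and do not emulate

The generators reproduce the *statistical structure* the analysis relies
on: skewed genome abundances (log-normal by default — a modelling choice,
as no distributional form is established for saliva communities),
genome-specific functional repertoires whose size is a monotone function
of abundance rank plus Gaussian noise, a tunable host-DNA fraction, the
MAPQ mixture above, toy gene models with exon/intron structure and framed
CDS (always a multiple of 3), and paired noisy callsets.

They do **not** emulate nucleotide-level read errors, assembly artefacts,
annotation bias, linkage disequilibrium, or realistic genome sizes.
Passing tests therefore demonstrate that the *algorithms* recover known
structure under the stated noise models — not that real saliva data meet
those models. In particular, the demo's core/pan set sizes are properties
of its 90-function toy catalog, orders of magnitude below the thousands of
functions a real annotation yields.

## Numerical choices and problem sizes

* Abundance vectors are normalised to sum to 1 (checked to 1e-12);
  relative abundances per profile to 1e-9.
* All top-*k* selections break ties lexicographically.
* Every generator takes an explicit integer seed and restores the RNG
  state afterwards; identical seeds give byte-identical outputs, which the
  suite asserts at file level for the demo fixtures.
* Validation sizes were chosen to make 3-standard-deviation binomial
  checks sharp while keeping the whole suite fast on one CPU: 50,000 read
  pairs for partition recovery, 10,000 true variants over 10^6 candidate
  positions for consensus calibration, 1000 random exonic SNVs for the
  translation oracle, and a 4 × 20,000-pair demo study.

## Known limitations

* The gene catalog treats genes as exchangeable annotation records; gene
  length and copy number are not modelled.
* Coding-effect classification assumes a single transcript per locus
  (transcripts are non-overlapping by construction); overlapping isoforms
  would need a precedence rule the package does not define.
* The consensus caller intersects exact SNV records only; indels and
  multi-allelic sites are out of scope.
* Group enrichment pools samples within a group rather than modelling
  between-sample dispersion; with two samples per group, as in the demo
  design, a dispersion model would be unidentifiable anyway.
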