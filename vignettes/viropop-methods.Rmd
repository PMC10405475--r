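---
title: "Methods: community and population inference in viropop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community and population inference in viropop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

viropop implements the downstream half of a viromics study: it starts where
assembly and viral detection end (contigs, detector score tables, read
alignments) and produces community-level ("macrodiversity") and
population-level ("microdiversity") inference. This vignette documents the
models, the parameters that matter, the numerical conventions, and the
design choices that were genuinely open — so that every number the package
prints can be traced to an explicit rule.

## Coordinate and orientation conventions

All internal coordinates are 0-based, half-open. Conversion to and from the
1-based conventions of SAM (`POS`) and GFF3 happens exactly once, at the
file boundary, in `read_alignments()` / `write_alignments()` and
`read_gff()` / `write_gff()`. Reverse-strand reads are stored
reference-forward; pileup statistics are strand-agnostic. `N` bases in a
reference have no defined allele and are masked out of allele counts (and
therefore out of every pileup statistic). Circular contigs are analysed as
linear sequences: the generator writes linearized alignments with no
wrap-around records, and no analysis module treats the origin specially.
This is the simplest convention that keeps coverage, HVR and π arithmetic
identical for circular and linear replicons; positions spanning the join of
a circular contig are the one place it can bias results (see Limitations).

## Viral classification and vOTU clustering

`classify_viral()` combines three detector outputs by the standard
four-criterion union rule (VirSorter category 1/2/4/5; DeepVirFinder
≥ 0.9 with p < 0.05; MARVEL ≥ 90%; DeepVirFinder ≥ 0.7 with p < 0.05 and
MARVEL ≥ 70%). Absent scores fail their criteria; every satisfied
criterion is reported, not just the first.

`cluster_votus()` builds species-level units greedily: contigs sorted by
length (descending, ties by lexicographic id, so the procedure is
order-deterministic) either join the first cluster whose representative
they match at ≥ 95% ANI across ≥ 80% of the shorter sequence, or found a
new cluster. Because processing is longest-first, every representative is
the longest member of its cluster by construction. Two genuinely open
choices are resolved as follows:

* *Which length the 80% applies to.* The aligned fraction is measured
  against the **shorter** sequence, the convention of the clustering
  lineage this rule comes from; it makes a fully contained fragment join
  its parent. A stricter both-lengths rule can be had by swapping the
  comparison function.
* *Greedy versus single-linkage.* Greedy representative-anchored
  clustering matches the longest-as-seed description and cannot chain
  distant members through intermediates.

`pairwise_ani()` is anchor-based: shared 15-mers grouped by diagonal,
chained across gaps up to 200 bp, extended to nearby sequence ends so that
terminal mismatches are counted, blocks under 100 bp discarded, and
non-conflicting blocks merged greedily. Within-block comparison is
gap-free, which is exact for substitution-structured divergence — the
regime the 95%/80% rule operates in. The test suite holds it against a
Smith–Waterman oracle (`Biostrings::pairwiseAlignment`) on 50-contig
fixtures; the oracle is also pluggable into `cluster_votus()` directly.

## Coverage, abundance, presence

`filter_alignments()` retains records with edit-distance identity
`1 − NM/aligned columns` ≥ 0.95 and aligned read fraction ≥ 0.90 (the
strict viromic pair). The identity denominator includes indel columns,
matching NM semantics. Depth follows the genomecov convention (deletions
consume and cover reference). Abundance is mean depth over **all**
positions (zeros included) scaled to a 10⁹-base library — "coverage per
gigabase" — which keeps the normalisation a pure ratio of totals.
Presence of a vOTU in a sample, used by the shared/unique (Venn) and
rarefaction analyses, defaults to breadth ≥ 0.70 at depth ≥ 1: the
detection convention commonly used for read-mapping-based vOTU calls. It
is a parameter (`presence_breadth`), not a constant, because no single
value suits all sequencing depths.

For metatranscriptomic recruitment the identity threshold is separately
configurable and defaults to 0.90 — the fully specified 90/90/50 triple
(identity / read coverage / genome breadth) — with activity called at
breadth ≥ 0.50, inclusive. Where two published statements of the
transcript identity threshold disagree (95 vs 90), the package defaults to
the triple that is stated together and exposes both knobs.

## Hypervariable regions

`detect_hvrs()` takes three criteria literally: a contig is eligible when
its median depth (all positions, zeros included) is ≥ 5×; a position is
"low" when its depth is ≤ 20% of that median (inclusive, matching the
stated "≤"); an HVR is a maximal run of low positions ≥ 500 bp. Median
(not mean) gates eligibility because the other two criteria are
median-referenced and a mean would let a single deep hotspot qualify a
mostly uncovered contig. Runs are strict by default; `max_gap` can bridge
short non-low interruptions, default 0, because no merging rule is part of
the criteria. The rule is scale-free: multiplying depth by a constant
leaves the detected set unchanged (given eligibility), which the suite
checks as a property.

## SNPs, π, and pN/pS

The pileup thresholds are explicit package defaults, all exposed as
arguments: site depth ≥ 10 (`min_cov`), variant allele count ≥ 4
(`min_count`), variant frequency ≥ 1% (`min_freq`). The consensus (most
frequent, ties toward the reference) anchors variant status, so the
reference allele itself is reported when it is minor.

Site diversity uses the unbiased estimator
π = Σ_{a≠b} cₐ c_b / (n(n−1)); region π averages site π over eligible
sites. Site π is evaluated **at called SNP sites only**, with eligible
non-SNP sites contributing zero. The reason is numerical: with per-base
error rate *e*, unconditioned heterozygosity is inflated by ≈ 2e at every
site, which at e = 10⁻³ adds ≈ 0.002 to π — larger than realistic viral π
values. The SNP thresholds (count ≥ 4) filter that noise; at 50× depth an
error allele reaches four copies with negligible probability, while true
strain variants at frequency ≥ 0.25 are essentially never missed.

pN/pS per gene is Nei–Gojobori-style: each codon's nine single-nucleotide
mutants are classified against the standard genetic code (the bacterial
table's codon translations; mutants creating stops count nonsynonymous) to
give per-codon site counts summing exactly to 3; a codon contributes to
the site totals only when all three positions are eligible, keeping
numerator and denominator on the same site set. Observed N and S sum each
variant allele once, with its effect determined by substituting the allele
into the reference codon on the gene's strand. `pN = N/N_sites`,
`pS = S/S_sites`; a gene with no variants is "no-variation"; when S = 0
with N > 0 the ratio uses (N+1)/(S+1) pseudocounts on the observed counts
only and carries a `pseudocount` flag — this avoids infinite ratios while
preserving the >1 decision for genuinely nonsynonymous-dominated genes.
Positive selection is ratio > 1. Genes whose reference copy contains an
internal stop are excluded with a warning; genes whose length is not a
multiple of 3 never enter codon arithmetic (dropped at GFF import).
Habitat contrasts use the two-sided Wilcoxon rank-sum test on per-contig
or per-gene statistics.

## Macrodiversity

Shannon diversity uses the natural log (base exposed as an argument);
richness under a virome presence rule typically puts H near ln(richness)
for even communities, which is the sanity check the suite applies.
Rarefaction subsamples reads without replacement at a user-supplied depth
grid (seeded), recomputes breadth-based presence at each depth, fits an
ordinary least-squares line through the last four points, and reports the
slope as vOTUs gained per million additional reads. Rank-abundance
ordering follows the reference sample descending (abundance ties by id),
with the other sample's exclusive vOTUs appended by their own abundance.

## The synthetic-community generator

The generator is first-class, tested code, and defines the conditions
under which the analysis claims are verified:

* **Genomes** — random composition, with non-overlapping genes
  (ATG…stop, length a multiple of 3, no internal stop, mixed strands) at a
  gene density in genes/kb.
* **Abundances** — log-normal (σ_log default 0.5). No abundance family is
  canonical for viromes; log-normal is the standard heavy-tailed choice
  for metagenomic relative abundances and is a modelling decision of this
  package.
* **Strains** — per genome, `n_strains` haplotypes (equal frequencies by
  default). Mutated sites are accumulated until the summed site
  heterozygosity 2f(1−f) reaches `target_pi × L`, so the expected
  genome-wide π equals the target by construction. The nonsynonymous
  fraction of coding mutations is realised *exactly* (running-quota
  allocation) rather than in expectation, which makes truth-based pN/pS
  tests noise-free. Mutations that would create stop codons, fall in a
  stop codon, or land in an injected HVR are re-drawn, and sites stay out
  of the terminal `end_margin` (default 100 bp, one read length): with
  uniform read starts the ends of a linearized genome sit on a coverage
  ramp and never reach nominal depth, so a variant there could not carry
  the promised, recoverable diversity.
* **HVR analogues** — an interval replaced by unrelated same-length
  sequence in a chosen fraction of strain mass, so reads from replaced
  strains fail the identity filter there and coverage collapses toward
  (1 − replaced fraction) × depth. At a replaced fraction of exactly 0.8
  the expected depth ratio sits exactly on the inclusive 20% threshold;
  verification runs therefore use 0.9, which tests the rule rather than
  the knife edge.
* **Reads** — uniform start positions, substitution-only errors at a
  per-base rate, forward strand, constant length. The truth alignment
  table records each read's exact placement and NM, so the pipeline runs
  without an external mapper; a real mapper's SAM is accepted
  interchangeably. Transcriptome reads are drawn from gene intervals of a
  chosen active set only.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: indels and structural variation (and so
gapped-alignment identity), GC/positional coverage bias, strand-specific
artefacts, chimeric assembly, linkage between nearby variants beyond
shared strain origin, and mapping ambiguity between related vOTUs.

## Problem sizes and tolerances used in verification

The acceptance-level checks run on: five 50-kb genomes (2–4 strains,
target π ∈ {0.001, 0.005, 0.02}, 50×, error 10⁻³) for π recovery within
15% of a direct strain-pairwise oracle; an error-free 40-kb community at
60× for exact SNP precision/recall; two 40-kb arms at equal mutational
load with nonsynonymous fractions 0.9 vs 0.1 for pN/pS directionality;
twenty 20-kb genomes with one injected 1.0–1.5-kb HVR each (replaced mass
0.9, 30× background) plus 400-bp and median-4× negative controls; fifty
0.6–1.5-kb contigs against the Smith–Waterman clustering oracle; and a
two-habitat demo pipeline rerun for byte-identical outputs. These sizes
are the package's chosen verification conditions: large enough for the
statistics to concentrate, small enough to run routinely.

## Limitations

* π is conditioned on called SNPs; with very low depth (< `min_cov`) or
  very rare strains (frequency × depth < `min_count`) it is biased low.
  The thresholds are printed with every run precisely so this conditioning
  is visible.
* The anchor-based ANI is gap-free within blocks; for indel-rich homology
  it underestimates identity relative to a gapped aligner, and the DP
  comparison function should be swapped in.
* Circular contigs: coverage and HVR calls treat the join as two contig
  ends, so an HVR spanning the origin would be reported as two intervals
  (or missed if each half is < 500 bp).
* Rarefaction detects vOTUs by mapping-based presence, not by
  re-assembly; curves saturate at the reference set's richness.
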