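# viropop

Downstream viromics for viral communities and their populations: from
assembled contigs and read alignments to species-level vOTUs, abundance
profiles, hypervariable regions, transcriptional activity, and
population-genetic microdiversity — with a synthetic-community generator
that makes every stage verifiable against known ground truth.

## Who this is for

Researchers analysing environmental viromes (e.g. brine, sea-ice, marine or
soil metagenomes) who have assembled contigs, detector scores and read
mappings in hand and want the downstream inference — community structure
and within-population evolution — as reproducible, tested R functions with
explicit thresholds, rather than as a chain of one-off scripts.

## What it computes

* **Viral classification** — contigs are called viral if they satisfy any
  of the four standard detector criteria: VirSorter category ∈ {1,2,4,5};
  DeepVirFinder score ≥ 0.9 with p < 0.05; MARVEL ≥ 90%; or DeepVirFinder
  ≥ 0.7 with p < 0.05 and MARVEL ≥ 70%.
* **vOTU clustering** — greedy, longest-first clustering at ≥ 95% average
  nucleotide identity across ≥ 80% of the shorter sequence; the longest
  contig seeds each cluster. `n50()` summarises assemblies.
* **Coverage and abundance** — reads filtered at ≥ 95% identity and ≥ 90%
  aligned fraction; per-base depth (genomecov convention); abundances as
  mean depth normalised to *coverage per gigabase* of library; breadth-based
  presence calls.
* **Hypervariable regions** — maximal runs where depth ≤ 20% of the contig
  median, at least 500 bp long, on contigs with median depth ≥ 5×.
* **Activity** — a vOTU is putatively active when recruited
  metatranscriptomic reads (90% identity / 90% read coverage) cover ≥ 50%
  of its genome.
* **Macrodiversity** — Shannon diversity H = −Σ pᵢ ln pᵢ, shared/unique
  vOTU (Venn) accounting with abundance shares, rank-abundance curves, and
  rarefaction with the tail slope over the last four subsampled libraries
  extrapolated to vOTUs per million additional reads.
* **Microdiversity** — pileup SNP calling (depth ≥ 10, allele count ≥ 4,
  frequency ≥ 1%, all configurable); nucleotide diversity
  π = Σ_{a≠b} cₐc_b / (n(n−1)) averaged over eligible sites; SNP density;
  codon-aware Nei–Gojobori pN/pS per gene with positive-selection calls
  (pN/pS > 1); Wilcoxon rank-sum contrasts between habitats.
* **Synthetic communities** — log-normal abundances, per-genome strain
  pools hitting a target π exactly in expectation, exact
  synonymous/nonsynonymous mutation fractions, injected HVR analogues,
  substitution-error reads, transcriptome reads from a chosen active set,
  and a truth bundle (SNPs with coding effects, HVR intervals, expected π,
  abundances, active genomes) for oracle-based testing.

## Worked example

Simulate a two-genome community with two strains per genome at a target
nucleotide diversity of 0.005, then recover π from the read pileup:

```r
library(viropop)
spec <- community_spec(n_genomes = 2, genome_len_range = c(12000L, 12000L),
                       depth_mean = 50, error_rate = 0.001, seed = 1)
cm <- simulate_community(spec, strain_spec(n_strains = 2, target_pi = 0.005))

kept <- filter_alignments(cm$aln)            # >=95% id, >=90% read coverage
id <- names(cm$contigs)[1]
counts <- allele_counts(kept[kept$contig_id == id, ], cm$contigs[[id]])
snps <- call_snps(counts, cm$contigs[[id]])
length(unique(snps$pos))                     # 120 segregating sites
region_pi(counts, snps)$pi                   # 0.00502
cm$truth$expected_pi[[id]]                   # 0.005

gg <- cm$genes[cm$genes$contig_id == id, ]
head(gene_microdiversity(gg, snps, counts, cm$contigs[[id]])[,
     c("gene_id", "pi", "snp_density", "pnps", "class")], 4)
#>          gene_id          pi snp_density      pnps     class
#> 1 genome_01_g001 0.003063954    5.988024 0.1439655 purifying
#> 2 genome_01_g002 0.002462907    5.012531 0.9013086 purifying
#> 3 genome_01_g003 0.001456947    2.923977 0.2889590 purifying
#> 4 genome_01_g004 0.001293513    2.554278 0.3197970 purifying
```

The estimated genome-wide π (0.00502) recovers the injected 0.005; the
per-gene pN/pS ratios sit below 1 because half of the injected coding
mutations are synonymous while synonymous sites are only ~1/4 of the
mutational opportunity. `cluster_votus(cm$contigs)` leaves the two
unrelated genomes in 2 vOTUs, and `shannon(rep(1, 4))` returns
`1.386294` = ln 4.

An end-to-end, multi-sample run is available through a config file:

```r
run <- run_pipeline("run.yaml")   # simulate -> votu -> coverage -> hvr ->
summarize_run(run)                #   microdiv -> ecology, all seeded
```

or from a shell via the thin wrapper `inst/cli/viropop.R`
(`simulate`, `run`, `summarize` verbs).

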