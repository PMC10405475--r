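spec_small <- community_spec(n_genomes = 2, genome_len_range = c(12000L, 12000L),
                             gene_density = 1, depth_mean = 20,
                             error_rate = 0, seed = 101)

test_that("genome generation is deterministic and genes are well-formed", {
  g1 <- generate_genomes(spec_small)
  g2 <- generate_genomes(spec_small)
  expect_identical(g1, g2)

  expect_named(g1$contigs, c("genome_01", "genome_02"))
  expect_true(all(nchar(g1$contigs) == 12000L))
  ## ~1 gene/kb, length divisible by 3, inside bounds, non-overlapping
  for (id in names(g1$contigs)) {
    gg <- g1$genes[g1$genes$contig_id == id, ]
    expect_equal(nrow(gg), 12, tolerance = 0.5)
    expect_true(all((gg$end - gg$start) %% 3 == 0))
    expect_true(all(gg$start >= 0 & gg$end <= 12000))
    o <- order(gg$start)
    expect_true(all(gg$start[o][-1] >= gg$end[o][-nrow(gg)]))
  }
  ## every CDS translates with no internal stop
  for (i in seq_len(nrow(g1$genes))) {
    g <- g1$genes[i, ]
    cds <- substr(g1$contigs[[g$contig_id]], g$start + 1, g$end)
    if (g$strand == "-")
      cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_identical(substr(aa, 1, 1), "M")
    expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }
  expect_error(community_spec(n_genomes = 0), "n_genomes")
  expect_error(generate_one_genome <- generate_genomes(
    community_spec(n_genomes = 1, genome_len_range = c(3000L, 3000L),
                   gene_density = 8, seed = 1)), "infeasible")
})

test_that("strain injection honours target_pi, effects, and determinism", {
  gen <- generate_genomes(spec_small)
  id <- "genome_01"
  gg <- gen$genes[gen$genes$contig_id == id, ]

  ## target_pi = 0: no mutations at all
  st0 <- inject_strains(gen$contigs[[id]], gg, strain_spec(3, target_pi = 0),
                        seed = 1)
  expect_identical(unique(st0$strains), gen$contigs[[id]])
  expect_identical(nrow(st0$truth_snps), 0L)

  ## two strains at 50/50: every site has expected_freq 0.5, site pi 0.5
  st <- inject_strains(gen$contigs[[id]], gg,
                       strain_spec(2, target_pi = 0.004), seed = 2)
  expect_true(all(st$truth_snps$expected_freq == 0.5))
  expect_equal(truth_pi(st$truth_snps, 12000), 0.004, tolerance = 0.05)

  ## truth pi agrees with the direct pairwise-difference oracle
  expect_equal(oracle_pi_strains(st$strains, st$freqs),
               truth_pi(st$truth_snps, 12000), tolerance = 1e-12)

  ## frac_nonsyn = 1: all coding truth SNPs nonsynonymous
  st1 <- inject_strains(gen$contigs[[id]], gg,
                        strain_spec(2, target_pi = 0.01, frac_nonsyn = 1),
                        seed = 3)
  coding <- st1$truth_snps$effect[st1$truth_snps$effect != "noncoding"]
  expect_true(length(coding) > 10)
  expect_true(all(coding == "nonsynonymous"))

  ## frac_nonsyn = 0: all synonymous
  st2 <- inject_strains(gen$contigs[[id]], gg,
                        strain_spec(2, target_pi = 0.01, frac_nonsyn = 0),
                        seed = 4)
  coding <- st2$truth_snps$effect[st2$truth_snps$effect != "noncoding"]
  expect_true(all(coding == "synonymous"))

  ## determinism
  expect_identical(
    inject_strains(gen$contigs[[id]], gg, strain_spec(2, target_pi = 0.004),
                   seed = 2),
    st)

  ## HVR out of bounds
  expect_error(
    inject_strains(gen$contigs[[id]], gg,
                   strain_spec(2, target_pi = 0,
                               hvr = list(start = 11000, end = 13000,
                                          replaced_fraction = 0.9)),
                   seed = 5),
    "outside contig")
})

test_that("read simulation: count arithmetic, NM, determinism, frequencies", {
  gen <- generate_genomes(spec_small)
  id <- "genome_01"
  ref <- gen$contigs[[id]]

  ## read count = round(depth * L / read_len)
  sim <- simulate_reads(ref, 1, ref, id, depth_mean = 10, read_len = 100L,
                        error_rate = 0, seed = 1)
  expect_identical(nrow(sim$aln), as.integer(round(10 * 12000 / 100)))

  ## error-free single reference strain: all NM = 0
  expect_true(all(sim$aln$nm == 0))
  expect_true(all(sim$aln$seq ==
                    substring(ref, sim$aln$start + 1, sim$aln$start + 100)))

  ## deterministic under seed
  sim2 <- simulate_reads(ref, 1, ref, id, depth_mean = 10, read_len = 100L,
                         error_rate = 0, seed = 1)
  expect_identical(sim, sim2)

  ## error rate shows up in NM at roughly read_len * rate per read
  sime <- simulate_reads(ref, 1, ref, id, depth_mean = 20, read_len = 100L,
                         error_rate = 0.01, seed = 2)
  expect_equal(mean(sime$aln$nm), 1, tolerance = 0.2)

  ## pooled allele frequency at truth SNPs converges to expected_freq
  gg <- gen$genes[gen$genes$contig_id == id, ]
  st <- inject_strains(ref, gg, strain_spec(2, target_pi = 0.005), seed = 3)
  simd <- simulate_reads(st$strains, st$freqs, ref, id, depth_mean = 80,
                         read_len = 100L, error_rate = 0, seed = 4)
  counts <- allele_counts(simd$aln, ref)
  for (i in seq_len(nrow(st$truth_snps))) {
    s <- st$truth_snps[i, ]
    c4 <- counts[s$pos + 1, ]
    f_obs <- c4[[s$alt]] / sum(c4)
    ## binomial 4-sigma band at the site's realized depth
    tol <- 4 * sqrt(s$expected_freq * (1 - s$expected_freq) / sum(c4))
    expect_lt(abs(f_obs - s$expected_freq), tol)
  }

  expect_error(simulate_reads(ref, 1, ref, id, depth_mean = 10,
                              read_len = 20000L, error_rate = 0, seed = 1),
               "read_len")
})

test_that("transcriptome simulation targets only active genomes' genes", {
  gen <- generate_genomes(spec_small)
  txn <- simulate_transcriptome(gen$contigs, gen$genes, "genome_01",
                                depth = 10, read_len = 100L, seed = 1)
  expect_true(all(txn$aln$contig_id == "genome_01"))
  ## every read falls inside an annotated gene
  gg <- gen$genes[gen$genes$contig_id == "genome_01", ]
  inside <- vapply(seq_len(nrow(txn$aln)), function(i)
    any(gg$start <= txn$aln$start[i] & txn$aln$start[i] + 100 <= gg$end),
    logical(1))
  expect_true(all(inside))

  ## empty active set -> no reads
  txn0 <- simulate_transcriptome(gen$contigs, gen$genes, character(0),
                                 depth = 10, seed = 1)
  expect_identical(nrow(txn0$aln), 0L)

  ## active genome with no genes -> warning, skipped
  expect_warning(
    txn_na <- simulate_transcriptome(
      c(gen$contigs, bare = mk_dna(5000, seed = 9)),
      gen$genes, "bare", depth = 10, seed = 1),
    "no usable genes")
  expect_identical(nrow(txn_na$aln), 0L)
})

test_that("injected HVR collapses coverage for replaced strain mass", {
  gen <- generate_genomes(spec_small)
  id <- "genome_01"
  ref <- gen$contigs[[id]]
  st <- inject_strains(ref, NULL,
                       strain_spec(4, target_pi = 0,
                                   hvr = list(start = 5000, end = 6200,
                                              replaced_fraction = 0.75)),
                       seed = 6)
  expect_equal(st$truth_hvr$replaced_fraction, 0.75)
  sim <- simulate_reads(st$strains, st$freqs, ref, id, depth_mean = 40,
                        read_len = 100L, error_rate = 0, seed = 7)
  kept <- filter_alignments(sim$aln)
  dp <- depth_profile(kept, nchar(ref))
  inside <- mean(dp[5100:6100])
  outside <- mean(dp[c(1:4900, 6300:12000)])
  expect_lt(inside / outside, 0.35)   # ~25% of strain mass remains
  expect_gt(inside / outside, 0.10)
})
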