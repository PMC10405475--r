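## build an L x 4 count matrix from a reference with uniform depth, then
## overlay per-site allele mixes
counts_from_ref <- function(ref, depth = 20L) {
  code <- vapply(strsplit(ref, "")[[1]],
                 function(b) match(b, c("A", "C", "G", "T")), integer(1))
  m <- matrix(0L, nrow = nchar(ref), ncol = 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  m[cbind(seq_len(nchar(ref)), code)] <- depth
  m
}

test_that("SNP calling applies depth, count and frequency thresholds", {
  ref <- strrep("A", 5)
  m <- counts_from_ref(ref, 100L)
  m[2, ] <- c(90L, 10L, 0L, 0L)   # clean biallelic site
  m[3, ] <- c(97L, 3L, 0L, 0L)    # alt count below min_count
  m[4, ] <- c(4L, 4L, 0L, 0L)     # depth 8 < min_cov
  snps <- call_snps(m, ref)
  expect_identical(snps$pos, 1L)
  expect_identical(snps$alt, "C")
  expect_equal(snps$freq, 0.10)
  expect_identical(snps$site_depth, 100)

  ## consensus anchors variant status; reference can be the minor allele
  m2 <- counts_from_ref(ref, 100L)
  m2[2, ] <- c(20L, 80L, 0L, 0L)
  s2 <- call_snps(m2, ref)
  expect_identical(s2$consensus, "C")
  expect_identical(s2$alt, "A")

  ## multi-allelic: one row per variant allele at the site
  m3 <- counts_from_ref(ref, 100L)
  m3[2, ] <- c(70L, 20L, 10L, 0L)
  s3 <- call_snps(m3, ref)
  expect_identical(s3$alt, c("C", "G"))

  ## consensus ties break toward the reference
  m4 <- counts_from_ref(ref, 100L)
  m4[2, ] <- c(50L, 50L, 0L, 0L)
  s4 <- call_snps(m4, ref)
  expect_identical(s4$consensus, "A")
  expect_identical(s4$alt, "C")
})

test_that("site and region pi follow the unbiased heterozygosity formula", {
  ref <- strrep("A", 100)
  m <- counts_from_ref(ref, 4L)
  m[10, ] <- c(2L, 2L, 0L, 0L)
  snps <- call_snps(m, ref, min_cov = 4L, min_count = 2L)
  ## site pi = (2*2*2)/(4*3) = 0.6667 over 100 eligible sites
  rp <- region_pi(m, snps, min_cov = 4L)
  expect_equal(rp$pi, (2 * 2 * 2) / (4 * 3) / 100, tolerance = 1e-12)
  expect_identical(rp$eligible_sites, 100L)
  expect_identical(rp$snp_sites, 1L)

  ## monomorphic region: pi = 0
  rp0 <- region_pi(counts_from_ref(ref, 4L), call_snps(counts_from_ref(ref, 4L),
                                                       ref, min_cov = 4L),
                   min_cov = 4L)
  expect_identical(rp0$pi, 0)

  ## allele relabeling leaves pi unchanged
  m5 <- counts_from_ref(ref, 10L)
  m5[10, ] <- c(6L, 4L, 0L, 0L)
  m6 <- counts_from_ref(ref, 10L)
  m6[10, ] <- c(0L, 4L, 6L, 0L)
  pi5 <- region_pi(m5, call_snps(m5, ref, min_cov = 10L), min_cov = 10L)$pi
  pi6 <- region_pi(m6, call_snps(m6, ref, min_cov = 10L), min_cov = 10L)$pi
  expect_equal(pi5, pi6)

  ## no eligible sites: flagged undefined
  rp_na <- region_pi(counts_from_ref(ref, 2L), call_snps(counts_from_ref(ref, 2L), ref))
  expect_true(is.na(rp_na$pi))
})

test_that("SNP density and genes-with-SNP fraction are plain rates", {
  expect_equal(snp_density(5, 10000), 0.5)
  expect_equal(snp_density(0, 10000), 0)
  expect_true(is.na(snp_density(3, 0)))
  gt <- data.frame(snp_sites = c(1, 0, 2, 0, 0, 0, 0, 0, 0, 1, 0, 3),
                   eligible_sites = rep(100, 12))
  expect_equal(genes_with_snp_fraction(gt), 4 / 12)
  gt$eligible_sites[2] <- 0
  expect_equal(genes_with_snp_fraction(gt), 4 / 11)
})

test_that("Nei-Gojobori site counts match the 9-mutant enumeration oracle", {
  ## hand-checked codons
  expect_equal(ng_sites("TTT"), c(n_sites = 8 / 3, s_sites = 1 / 3))
  expect_equal(ng_sites("GGG"), c(n_sites = 2, s_sites = 1))
  expect_equal(ng_sites("ATG"), c(n_sites = 3, s_sites = 0))
  expect_error(ng_sites("TAA"), "stop")
  expect_error(ng_sites("ANG"), "non-ACGT")

  ## independent oracle via seqinr translation over all 61 sense codons
  skip_if_not_installed("seqinr")
  bases <- c("A", "C", "G", "T")
  for (codon in sense_codons()) {
    s_oracle <- 0
    for (p in 1:3) for (alt in setdiff(bases, substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- alt
      aa_ref <- seqinr::translate(strsplit(codon, "")[[1]])
      aa_mut <- seqinr::translate(strsplit(mut, "")[[1]])
      if (identical(aa_ref, aa_mut)) s_oracle <- s_oracle + 1 / 3
    }
    got <- ng_sites(codon)
    expect_equal(unname(got["s_sites"]), s_oracle, tolerance = 1e-12)
    expect_equal(unname(sum(got)), 3, tolerance = 1e-12)
  }
})

test_that("pN/pS classifies constructed genes correctly on both strands", {
  ## gene: ATG GGG TTT AAA TAA (15 bp) on a contig with 10 bp flanks
  cds <- "ATGGGGTTTAAATAA"
  flank5 <- "ACGTACGTAC"; flank3 <- "GTACGTACGT"
  ref_fwd <- paste0(flank5, cds, flank3)
  gene_fwd <- data.frame(gene_id = "g+", contig_id = "c", start = 10L,
                         end = 25L, strand = "+", frame = 0L,
                         stringsAsFactors = FALSE)
  m <- counts_from_ref(ref_fwd, 20L)
  ## site 15 (0-based): third position of GGG -> any change synonymous
  m[16, ] <- c(4L, 0L, 16L, 0L)   # G -> A : synonymous
  ## site 16: first position of TTT -> T->C gives CTT (Leu) nonsynonymous
  m[17, ] <- c(0L, 5L, 0L, 15L)
  snps <- call_snps(m, ref_fwd)
  res <- pnps(gene_fwd, snps, m, ref_fwd)
  expect_identical(res$n_obs, 1)
  expect_identical(res$s_obs, 1)
  ## site totals over the 4 non-stop codons
  sites <- ng_sites("ATG") + ng_sites("GGG") + ng_sites("TTT") + ng_sites("AAA")
  expect_equal(res$n_sites, unname(sites["n_sites"]))
  expect_equal(res$s_sites, unname(sites["s_sites"]))
  expect_equal(res$pnps, (1 / res$n_sites) / (1 / res$s_sites))
  expect_false(res$pseudocount)

  ## same gene encoded on the minus strand must give identical effects
  ref_rev <- paste0(flank5, revcomp(cds), flank3)
  gene_rev <- data.frame(gene_id = "g-", contig_id = "c", start = 10L,
                         end = 25L, strand = "-", frame = 0L,
                         stringsAsFactors = FALSE)
  mr <- counts_from_ref(ref_rev, 20L)
  ## mirror of site 15: genome pos = 10 + (24-15) = 19 carries complement
  mr[20, ] <- c(0L, 16L, 0L, 4L)  # genome C->T == CDS G->A, synonymous
  mr[19, ] <- c(15L, 0L, 5L, 0L)  # A->G on genome == T->C on CDS
  snps_r <- call_snps(mr, ref_rev)
  res_r <- pnps(gene_rev, snps_r, mr, ref_rev)
  expect_identical(res_r$n_obs, 1)
  expect_identical(res_r$s_obs, 1)
  expect_equal(res_r$pnps, res$pnps)

  ## no SNPs: "no-variation"
  res0 <- pnps(gene_fwd, call_snps(counts_from_ref(ref_fwd, 20L), ref_fwd),
               counts_from_ref(ref_fwd, 20L), ref_fwd)
  expect_identical(res0$class, "no-variation")
  expect_true(is.na(res0$pnps))

  ## S_obs = 0 with N_obs > 0: pseudocount ratio, flagged
  m2 <- counts_from_ref(ref_fwd, 20L)
  m2[17, ] <- c(0L, 5L, 0L, 15L)
  res2 <- pnps(gene_fwd, call_snps(m2, ref_fwd), m2, ref_fwd)
  expect_true(res2$pseudocount)
  expect_equal(res2$pnps, (2 / res2$n_sites) / (1 / res2$s_sites))

  ## internal reference stop: excluded with warning
  bad_ref <- paste0(flank5, "ATGTAATTTAAATAA", flank3)
  expect_warning(res3 <- pnps(gene_fwd, call_snps(counts_from_ref(bad_ref, 20L),
                                                  bad_ref),
                              counts_from_ref(bad_ref, 20L), bad_ref),
                 "internal stop")
  expect_identical(res3$class, "excluded")
})

test_that("codons count toward site totals only when fully covered", {
  cds <- "ATGGGGTTTAAATAA"
  ref <- paste0(strrep("A", 9), cds, strrep("A", 9))
  gene <- data.frame(gene_id = "g", contig_id = "c", start = 9L, end = 24L,
                     strand = "+", frame = 0L, stringsAsFactors = FALSE)
  m <- counts_from_ref(ref, 20L)
  m[11, ] <- 0L   # second base of ATG uncovered -> whole codon ineligible
  res <- pnps(gene, call_snps(m, ref), m, ref)
  sites <- ng_sites("GGG") + ng_sites("TTT") + ng_sites("AAA")
  expect_equal(res$n_sites, unname(sites["n_sites"]))
  expect_equal(res$s_sites, unname(sites["s_sites"]))
})

test_that("group comparisons use the rank-sum test", {
  res <- compare_groups(list(a = rep(c(0.001, 0.0011), 10),
                             b = rep(c(0.01, 0.011), 10)))
  expect_lt(res$p_value, 1e-6)
  expect_lt(res$medians[1], res$medians[2])

  same <- compare_groups(list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4)))
  expect_gt(same$p_value, 0.9)

  expect_error(compare_groups(list(a = 1:3)), "two groups")
  expect_error(compare_groups(list(a = 1:3, b = numeric(0))), "empty group")
})
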