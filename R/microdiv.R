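#' Call SNPs from per-site allele counts
#'
#' A site is eligible when its total count (depth of retained, aligned
#' bases) is at least `min_cov`. At an eligible site the consensus is the
#' most frequent allele (ties broken toward the reference base), and every
#' allele differing from the consensus is reported as a variant when its
#' count is at least `min_count` and its frequency at least `min_freq`.
#' The reference allele itself can be a reported variant when it is minor.
#'
#' @param counts `L x 4` allele-count matrix from [allele_counts()].
#' @param ref reference sequence of the contig.
#' @param min_cov minimum site depth for eligibility.
#' @param min_count minimum allele count for a variant.
#' @param min_freq minimum allele frequency for a variant.
#' @return data.frame with one row per variant allele: `pos` (0-based),
#'   `ref`, `consensus`, `alt`, `count`, `freq`, `site_depth`.
#' @export
call_snps <- function(counts, ref, min_cov = 10L, min_count = 4L,
                      min_freq = 0.01) {
  depth <- rowSums(counts)
  ref_code <- chars_to_code(ref)
  ## only sites where at least two alleles reach min_count can yield a
  ## variant (the consensus is always one of the top-count alleles)
  candidate <- which(depth >= min_cov &
                       rowSums(counts >= max(min_count, 1L)) >= 2L)
  rows <- list()
  for (p in candidate) {
    c4 <- counts[p, ]
    mx <- which(c4 == max(c4))
    cons <- if (!is.na(ref_code[p]) && ref_code[p] %in% mx) ref_code[p]
            else mx[1]
    alts <- which(c4 >= min_count & c4 / depth[p] >= min_freq)
    alts <- setdiff(alts, cons)
    for (a in alts) {
      rows[[length(rows) + 1L]] <- data.frame(
        pos = p - 1L,
        ref = BASE4[ref_code[p]],
        consensus = BASE4[cons],
        alt = BASE4[a],
        count = c4[[a]],
        freq = c4[[a]] / depth[p],
        site_depth = depth[p],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) {
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  } else {
    data.frame(pos = integer(0), ref = character(0), consensus = character(0),
               alt = character(0), count = integer(0), freq = numeric(0),
               site_depth = numeric(0), stringsAsFactors = FALSE)
  }
}

## Unbiased per-site heterozygosity: sum_{a != b} c_a c_b / (n (n-1)).
site_pi <- function(c4) {
  n <- sum(c4)
  if (n < 2) return(0)
  (n^2 - sum(c4^2)) / (n * (n - 1))
}

#' Nucleotide diversity of a region
#'
#' Mean per-site heterozygosity over eligible sites (depth >= `min_cov`).
#' Site heterozygosity is the unbiased estimator
#' `sum_{a!=b} c_a c_b / (n(n-1))`, evaluated at called SNP sites;
#' eligible sites without a called variant contribute zero, which keeps
#' sequencing-error noise (filtered by the SNP thresholds) out of pi.
#'
#' @param counts `L x 4` allele-count matrix.
#' @param snps SNP table from [call_snps()] on the same counts.
#' @param min_cov minimum site depth for eligibility.
#' @param region optional `c(start, end)` 0-based half-open restriction.
#' @return list with `pi` (`NA` if no eligible sites), `eligible_sites`,
#'   and `snp_sites`.
#' @export
region_pi <- function(counts, snps, min_cov = 10L, region = NULL) {
  idx <- seq_len(nrow(counts))
  if (!is.null(region)) idx <- idx[idx > region[1] & idx <= region[2]]
  depth <- rowSums(counts[idx, , drop = FALSE])
  n_elig <- sum(depth >= min_cov)
  if (n_elig == 0)
    return(list(pi = NA_real_, eligible_sites = 0L, snp_sites = 0L))
  spos <- unique(snps$pos)
  spos <- spos[(spos + 1L) %in% idx]
  if (!is.null(region))
    spos <- spos[spos >= region[1] & spos < region[2]]
  tot <- if (length(spos))
    sum(vapply(spos, function(p) site_pi(counts[p + 1L, ]), numeric(1)))
  else 0
  list(pi = tot / n_elig, eligible_sites = as.integer(n_elig),
       snp_sites = length(unique(spos)))
}

#' SNP density and the fraction of genes carrying SNPs
#'
#' @param n_snp_sites number of variant sites.
#' @param eligible_sites number of eligible sites.
#' @return SNPs per kb of eligible sequence (`NA` when nothing eligible).
#' @export
snp_density <- function(n_snp_sites, eligible_sites) {
  if (eligible_sites <= 0) return(NA_real_)
  n_snp_sites / (eligible_sites / 1000)
}

#' @rdname snp_density
#' @param gene_table per-gene data.frame with columns `snp_sites` and
#'   `eligible_sites` (see [gene_microdiversity()]).
#' @return for `genes_with_snp_fraction`: fraction of genes with at least
#'   one SNP among genes with at least one eligible site.
#' @export
genes_with_snp_fraction <- function(gene_table) {
  ok <- gene_table$eligible_sites > 0
  if (!any(ok)) return(NA_real_)
  mean(gene_table$snp_sites[ok] > 0)
}

#' Nei-Gojobori synonymous and nonsynonymous site counts of a codon
#'
#' Each of the nine single-nucleotide mutants of the codon is classified
#' against the standard genetic code; the synonymous site count is the sum
#' over the three positions of (synonymous changes at that position)/3 and
#' the nonsynonymous count is its complement to 3. Mutants that create a
#' stop codon count as nonsynonymous.
#'
#' @param codon 3-letter string over `{A,C,G,T}`, not a stop codon.
#' @return named numeric vector `c(n_sites, s_sites)` summing to 3.
#' @export
ng_sites <- function(codon) {
  if (grepl("[^ACGT]", codon)) stop("codon contains non-ACGT base")
  if (codon %in% STOP_CODONS) stop("stop codon has no defined sites")
  aa <- Biostrings::GENETIC_CODE[[codon]]
  s <- 0
  for (p in 1:3) {
    for (alt in setdiff(BASE4, substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- alt
      if (Biostrings::GENETIC_CODE[[mut]] == aa) s <- s + 1 / 3
    }
  }
  c(n_sites = 3 - s, s_sites = s)
}

## Per-gene codon bookkeeping shared by pnps(): genome coordinates of each
## codon of the CDS (excluding the terminal stop), reading-frame oriented.
gene_codons <- function(gene, ref_chars) {
  len <- gene$end - gene$start
  n_codons <- len %/% 3L - 1L          # drop the stop codon
  if (n_codons < 1L) return(NULL)
  if (gene$strand == "+") {
    starts <- gene$start + 3L * (seq_len(n_codons) - 1L)
    pos <- cbind(starts, starts + 1L, starts + 2L)   # 0-based genome coords
    codons <- paste0(ref_chars[pos[, 1] + 1L], ref_chars[pos[, 2] + 1L],
                     ref_chars[pos[, 3] + 1L])
  } else {
    ends <- gene$end - 3L * (seq_len(n_codons) - 1L) # just past codon
    pos <- cbind(ends - 1L, ends - 2L, ends - 3L)    # CDS order
    codons <- paste0(comp_base[ref_chars[pos[, 1] + 1L]],
                     comp_base[ref_chars[pos[, 2] + 1L]],
                     comp_base[ref_chars[pos[, 3] + 1L]])
  }
  list(pos = pos, codons = codons)
}

#' Codon-aware pN/pS for one gene
#'
#' Observed nonsynonymous and synonymous changes are summed over the
#' gene's called SNPs (each variant allele counted once, its effect
#' determined by substituting it into the reference codon on the gene's
#' strand). Site totals are Nei-Gojobori counts summed over codons whose
#' three positions are all eligible (depth >= `min_cov`), so numerator and
#' denominator live on the same site set. `pN = N_obs / N_sites`,
#' `pS = S_obs / S_sites`. A gene with no SNPs is classed "no-variation";
#' when `S_obs = 0` but `N_obs > 0` the ratio uses `(N_obs+1)/(S_obs+1)`
#' pseudocounts on the observed counts only and is flagged. Positive
#' selection is called when the ratio exceeds 1.
#'
#' @param gene one row of a gene data.frame.
#' @param snps SNP table of the gene's contig from [call_snps()].
#' @param counts allele-count matrix of the contig.
#' @param ref reference sequence of the contig.
#' @param min_cov minimum depth for a position to count.
#' @return one-row data.frame: `gene_id`, `n_obs`, `s_obs`, `n_sites`,
#'   `s_sites`, `pn`, `ps`, `pnps`, `class`
#'   (`positive`/`purifying`/`no-variation`/`excluded`), `pseudocount`.
#' @export
pnps <- function(gene, snps, counts, ref, min_cov = 10L) {
  ref_chars <- strsplit(ref, "")[[1]]
  out <- data.frame(gene_id = gene$gene_id, n_obs = NA_real_, s_obs = NA_real_,
                    n_sites = NA_real_, s_sites = NA_real_, pn = NA_real_,
                    ps = NA_real_, pnps = NA_real_, class = "excluded",
                    pseudocount = FALSE, stringsAsFactors = FALSE)
  gc <- gene_codons(gene, ref_chars)
  if (is.null(gc)) return(out)
  if (any(gc$codons %in% STOP_CODONS)) {
    warning("gene ", gene$gene_id, " has an internal stop codon; excluded")
    return(out)
  }
  if (any(grepl("[^ACGT]", gc$codons))) {
    keep <- !grepl("[^ACGT]", gc$codons)
    gc$pos <- gc$pos[keep, , drop = FALSE]
    gc$codons <- gc$codons[keep]
    if (!length(gc$codons)) return(out)
  }
  depth <- rowSums(counts)
  cov_ok <- matrix(depth[gc$pos + 1L] >= min_cov, ncol = 3L)
  elig <- rowSums(cov_ok) == 3L
  if (!any(elig)) return(out)
  sites <- vapply(gc$codons[elig], ng_sites, numeric(2))
  n_sites <- sum(sites["n_sites", ])
  s_sites <- sum(sites["s_sites", ])

  ## effects of observed SNPs within eligible codons
  n_obs <- 0; s_obs <- 0
  if (nrow(snps)) {
    pos_elig <- gc$pos[elig, , drop = FALSE]
    codons_elig <- gc$codons[elig]
    for (i in seq_len(nrow(snps))) {
      hit <- which(pos_elig == snps$pos[i], arr.ind = TRUE)
      if (!nrow(hit)) next
      ci <- hit[1, "row"]; cp <- hit[1, "col"]
      ## the segregating change relative to the reference: when the
      ## reference allele is itself the reported minor variant, the
      ## mutation is the consensus allele
      alt_base <- snps$alt[i]
      if (alt_base == ref_chars[snps$pos[i] + 1L])
        alt_base <- snps$consensus[i]
      if (alt_base == ref_chars[snps$pos[i] + 1L]) next
      alt_cds <- if (gene$strand == "+") alt_base
                 else comp_base[[alt_base]]
      eff <- codon_effect(codons_elig[ci], cp, alt_cds)
      if (eff == "synonymous") s_obs <- s_obs + 1 else n_obs <- n_obs + 1
    }
  }
  out$n_obs <- n_obs; out$s_obs <- s_obs
  out$n_sites <- n_sites; out$s_sites <- s_sites
  out$pn <- n_obs / n_sites; out$ps <- s_obs / s_sites
  if (n_obs + s_obs == 0) {
    out$class <- "no-variation"
  } else if (s_obs == 0) {
    out$pnps <- ((n_obs + 1) / n_sites) / ((s_obs + 1) / s_sites)
    out$pseudocount <- TRUE
    out$class <- if (out$pnps > 1) "positive" else "purifying"
  } else {
    out$pnps <- out$pn / out$ps
    out$class <- if (out$pnps > 1) "positive" else "purifying"
  }
  out
}

#' Gene-level microdiversity table for one contig
#'
#' Applies [region_pi()], [snp_density()] and [pnps()] to every gene of a
#' contig.
#'
#' @param genes gene data.frame rows for this contig.
#' @param snps SNP table from [call_snps()].
#' @param counts allele-count matrix.
#' @param ref reference sequence.
#' @param min_cov minimum site depth.
#' @return data.frame, one row per gene, with `pi`, `eligible_sites`,
#'   `snp_sites`, `snp_density` and the [pnps()] columns.
#' @export
gene_microdiversity <- function(genes, snps, counts, ref, min_cov = 10L) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    p <- region_pi(counts, snps, min_cov = min_cov,
                   region = c(g$start, g$end))
    sel <- pnps(g, snps, counts, ref, min_cov = min_cov)
    cbind(data.frame(contig_id = g$contig_id, pi = p$pi,
                     eligible_sites = p$eligible_sites,
                     snp_sites = p$snp_sites,
                     snp_density = snp_density(p$snp_sites, p$eligible_sites),
                     stringsAsFactors = FALSE),
          sel)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("gene_id", setdiff(names(out), "gene_id"))]
}

#' Contig-level microdiversity summary
#'
#' @param counts allele-count matrix of one contig.
#' @param snps SNP table from [call_snps()].
#' @param min_cov minimum site depth.
#' @return one-row data.frame: `pi`, `eligible_sites`, `snp_sites`,
#'   `snp_density`.
#' @export
contig_microdiversity <- function(counts, snps, min_cov = 10L) {
  p <- region_pi(counts, snps, min_cov = min_cov)
  data.frame(pi = p$pi, eligible_sites = p$eligible_sites,
             snp_sites = p$snp_sites,
             snp_density = snp_density(p$snp_sites, p$eligible_sites))
}

#' Compare a statistic between two sample groups
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test on per-contig or
#' per-gene statistics, the standard nonparametric contrast for habitat
#' comparisons of microdiversity.
#'
#' @param values_by_group named list of (at least two) numeric vectors;
#'   `NA`s are dropped.
#' @param groups which two groups to compare (default: the first two).
#' @return list with `medians`, `statistic`, `p_value`, `groups`.
#' @export
compare_groups <- function(values_by_group, groups = names(values_by_group)[1:2]) {
  if (length(values_by_group) < 2) stop("need at least two groups")
  x <- values_by_group[[groups[1]]]; x <- x[!is.na(x)]
  y <- values_by_group[[groups[2]]]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("empty group in comparison")
  wt <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  list(groups = groups,
       medians = c(stats::median(x), stats::median(y)),
       statistic = unname(wt$statistic),
       p_value = wt$p.value)
}
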