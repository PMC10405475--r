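#' Specify the strain structure of one viral population
#'
#' @param n_strains number of strains (>= 1).
#' @param strain_freqs strain frequency vector summing to 1; default equal.
#' @param target_pi target genome-wide nucleotide diversity (expected mean
#'   per-site heterozygosity over the whole genome), in `[0, 0.75)`.
#' @param frac_nonsyn fraction of injected *coding* mutations that are
#'   nonsynonymous; realized exactly up to rounding.
#' @param hvr optional hypervariable-region injection: a list with `start`,
#'   `end` (0-based half-open) and `replaced_fraction` — the strain mass in
#'   which that interval is replaced by unrelated same-length sequence.
#' @param end_margin terminal bases excluded from mutation placement. With
#'   uniform read starts on a linearized genome the first and last
#'   read-length of positions never reach nominal depth (the coverage
#'   ramp), so sites there cannot carry the controlled diversity the spec
#'   promises; the default keeps injected sites where the stated depth
#'   holds.
#' @return a `strain_spec` list.
#' @export
strain_spec <- function(n_strains = 2L, strain_freqs = NULL,
                        target_pi = 0.005, frac_nonsyn = 0.5, hvr = NULL,
                        end_margin = 100L) {
  n_strains <- as.integer(n_strains)
  if (n_strains < 1L) stop("n_strains must be >= 1")
  if (is.null(strain_freqs)) strain_freqs <- rep(1 / n_strains, n_strains)
  if (length(strain_freqs) != n_strains || abs(sum(strain_freqs) - 1) > 1e-8)
    stop("strain_freqs must have length n_strains and sum to 1")
  if (target_pi < 0 || target_pi >= 0.75)
    stop("target_pi must be in [0, 0.75)")
  if (frac_nonsyn < 0 || frac_nonsyn > 1)
    stop("frac_nonsyn must be in [0, 1]")
  structure(list(n_strains = n_strains, strain_freqs = strain_freqs,
                 target_pi = target_pi, frac_nonsyn = frac_nonsyn,
                 hvr = hvr, end_margin = as.integer(end_margin)),
            class = "strain_spec")
}

## Effect of substituting `alt` at codon position `cpos` (1..3) of `codon`.
codon_effect <- function(codon, cpos, alt) {
  mutant <- codon
  substr(mutant, cpos, cpos) <- alt
  aa_ref <- Biostrings::GENETIC_CODE[[codon]]
  aa_alt <- Biostrings::GENETIC_CODE[[mutant]]
  if (aa_ref == aa_alt) "synonymous" else "nonsynonymous"
}

creates_stop <- function(codon, cpos, alt) {
  mutant <- codon
  substr(mutant, cpos, cpos) <- alt
  Biostrings::GENETIC_CODE[[mutant]] == "*"
}

## Map a genome position (0-based) to its gene, codon, codon position and the
## strand-oriented alt for a genome-strand substitution. `gene_map`, if
## supplied, is a precomputed pos -> gene-row lookup (0 = intergenic).
locate_in_gene <- function(pos, genes, genome_chars, gene_map = NULL) {
  if (is.null(genes) || !nrow(genes)) return(NULL)
  hit <- if (!is.null(gene_map)) {
    h <- gene_map[pos + 1L]
    if (h == 0L) integer(0) else h
  } else which(genes$start <= pos & pos < genes$end)
  if (!length(hit)) return(NULL)
  g <- genes[hit[1], ]
  if (g$strand == "+") {
    off <- pos - g$start
    cpos <- off %% 3L + 1L
    cstart <- g$start + off - (off %% 3L)
    codon <- paste(genome_chars[(cstart + 1L):(cstart + 3L)], collapse = "")
    list(gene_id = g$gene_id, codon = codon, cpos = cpos, strand = "+",
         is_stop_codon = off >= (g$end - g$start - 3L))
  } else {
    off <- g$end - 1L - pos              # offset along the CDS
    cpos <- off %% 3L + 1L
    cend <- g$end - (off - off %% 3L)    # genome coord just past codon
    codon <- revcomp(paste(genome_chars[(cend - 2L):cend], collapse = ""))
    list(gene_id = g$gene_id, codon = codon, cpos = cpos, strand = "-",
         is_stop_codon = off >= (g$end - g$start - 3L))
  }
}

comp_base <- c(A = "T", C = "G", G = "C", T = "A")

#' Inject strain-level diversity into one genome
#'
#' Builds `n_strains` haplotypes of a reference genome whose pooled per-site
#' diversity matches `target_pi`: mutated sites are accumulated until the
#' summed site heterozygosity `2f(1-f)` (with `f` the pooled frequency of
#' the strains carrying the alternative allele) reaches `target_pi * L`.
#' Coding mutations are classified synonymous/nonsynonymous against the
#' standard genetic code at injection time, with the nonsynonymous fraction
#' realized exactly (running-quota allocation); mutations that would create
#' a stop codon are re-drawn. An optional HVR replaces an interval in a
#' subset of strains with unrelated same-length random sequence, so reads
#' from those strains fail identity filters there and coverage collapses.
#'
#' @param genome reference sequence (single character string).
#' @param genes gene data.frame for this genome (may be `NULL`).
#' @param spec a [strain_spec()].
#' @param seed integer seed.
#' @return list with `strains` (character vector of haplotypes), `freqs`,
#'   `truth_snps` (data.frame: `pos`, `ref`, `alt`, `expected_freq`,
#'   `effect`, `gene_id`), and `truth_hvr` (1-row data.frame or `NULL` with
#'   `start`, `end`, `replaced_fraction`).
#' @export
inject_strains <- function(genome, genes, spec, seed = 1L) {
  stopifnot(inherits(spec, "strain_spec"))
  set.seed(seed)
  L <- nchar(genome)
  chars <- strsplit(genome, "")[[1]]
  n <- spec$n_strains
  freqs <- spec$strain_freqs

  hvr <- spec$hvr
  if (!is.null(hvr)) {
    if (hvr$start < 0 || hvr$end > L || hvr$start >= hvr$end)
      stop("HVR interval [", hvr$start, ",", hvr$end,
           ") outside contig bounds")
  }
  in_hvr <- function(p) !is.null(hvr) && p >= hvr$start && p < hvr$end

  target_total <- spec$target_pi * L
  gene_map <- integer(L)
  if (!is.null(genes) && nrow(genes) > 0)
    for (gi in seq_len(nrow(genes)))
      gene_map[(genes$start[gi] + 1L):genes$end[gi]] <- gi
  bases <- c("A", "C", "G", "T")
  snps <- list()
  used <- logical(L)
  cum <- 0
  n_coding <- 0L
  n_nonsyn <- 0L
  guard <- 0L
  while (cum < target_total && spec$target_pi > 0) {
    guard <- guard + 1L
    if (guard > 50L * L) stop("target_pi unachievable for this genome")
    pos <- sample.int(L, 1L) - 1L
    if (pos < spec$end_margin || pos >= L - spec$end_margin) next
    if (used[pos + 1L] || chars[pos + 1L] == "N" || in_hvr(pos)) next
    ## carriers: proper non-empty strain subset
    k <- if (n == 1L) 1L else sample.int(n - 1L, 1L)
    carriers <- sample.int(n, k)
    f <- sum(freqs[carriers])
    if (f <= 0 || f >= 1) next
    ref <- chars[pos + 1L]
    loc <- locate_in_gene(pos, genes, chars, gene_map)
    if (!is.null(loc) && loc$is_stop_codon) next
    if (is.null(loc)) {
      alt <- sample(setdiff(bases, ref), 1L)
      effect <- "noncoding"
      gene_id <- NA_character_
    } else {
      want_nonsyn <- n_nonsyn < round(spec$frac_nonsyn * (n_coding + 1L))
      cds_ref <- if (loc$strand == "+") ref else comp_base[[ref]]
      cand <- setdiff(bases, cds_ref)
      eff <- vapply(cand, function(a) codon_effect(loc$codon, loc$cpos, a),
                    character(1))
      ok <- !vapply(cand, function(a) creates_stop(loc$codon, loc$cpos, a),
                    logical(1))
      pick <- cand[ok & eff == (if (want_nonsyn) "nonsynonymous"
                                else "synonymous")]
      if (!length(pick)) next                  # no alt of the wanted class
      cds_alt <- if (length(pick) == 1L) pick else sample(pick, 1L)
      alt <- if (loc$strand == "+") cds_alt else comp_base[[cds_alt]]
      effect <- if (want_nonsyn) "nonsynonymous" else "synonymous"
      gene_id <- loc$gene_id
      n_coding <- n_coding + 1L
      if (want_nonsyn) n_nonsyn <- n_nonsyn + 1L
    }
    used[pos + 1L] <- TRUE
    cum <- cum + 2 * f * (1 - f)
    snps[[length(snps) + 1L]] <- list(pos = pos, ref = ref, alt = alt,
                                      expected_freq = f, effect = effect,
                                      gene_id = gene_id,
                                      carriers = list(carriers))
  }
  truth <- if (length(snps)) {
    data.frame(pos = vapply(snps, `[[`, numeric(1), "pos"),
               ref = vapply(snps, `[[`, character(1), "ref"),
               alt = vapply(snps, `[[`, character(1), "alt"),
               expected_freq = vapply(snps, `[[`, numeric(1), "expected_freq"),
               effect = vapply(snps, `[[`, character(1), "effect"),
               gene_id = vapply(snps, `[[`, character(1), "gene_id"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(pos = numeric(0), ref = character(0), alt = character(0),
               expected_freq = numeric(0), effect = character(0),
               gene_id = character(0), stringsAsFactors = FALSE)
  }

  ## build haplotypes
  strains <- vector("list", n)
  for (i in seq_len(n)) strains[[i]] <- chars
  for (s in snps) {
    for (i in s$carriers[[1]]) strains[[i]][s$pos + 1L] <- s$alt
  }
  truth_hvr <- NULL
  if (!is.null(hvr)) {
    n_rep <- max(1L, round(hvr$replaced_fraction * n))
    replaced <- order(freqs, decreasing = TRUE)[seq_len(n_rep)]
    seg <- sample(bases, hvr$end - hvr$start, replace = TRUE)
    for (i in replaced) strains[[i]][(hvr$start + 1L):hvr$end] <- seg
    truth_hvr <- data.frame(start = hvr$start, end = hvr$end,
                            replaced_fraction = sum(freqs[replaced]))
  }
  list(strains = vapply(strains, paste, character(1), collapse = ""),
       freqs = freqs,
       truth_snps = truth,
       truth_hvr = truth_hvr)
}

#' Genome-wide nucleotide diversity implied by a truth SNP table
#'
#' The expectation the injected strain pool commits to: the sum over mutated
#' sites of `2 f (1 - f)` divided by the genome length.
#'
#' @param truth_snps truth SNP data.frame from [inject_strains()].
#' @param genome_len genome length in bp.
#' @return expected genome-wide pi.
#' @export
truth_pi <- function(truth_snps, genome_len) {
  if (!nrow(truth_snps)) return(0)
  sum(2 * truth_snps$expected_freq * (1 - truth_snps$expected_freq)) /
    genome_len
}
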