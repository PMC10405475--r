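## Shared fixture builders. Everything is generated in code under fixed
## seeds; no stored data.

mk_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## substitute a fraction of positions (returns list with seq and positions)
mutate_seq <- function(s, rate = NULL, positions = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ch <- strsplit(s, "")[[1]]
  if (is.null(positions))
    positions <- sort(sample(length(ch), round(rate * length(ch))))
  ch[positions] <- vapply(ch[positions], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  list(seq = paste(ch, collapse = ""), positions = positions)
}

## independent pairwise-difference oracle for genome-wide pi:
## sum_{i,j} w_i w_j d_ij / L over strain haplotypes
oracle_pi_strains <- function(strains, freqs) {
  L <- nchar(strains[1])
  codes <- lapply(strains, utf8ToInt)
  n <- length(strains)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    tot <- tot + freqs[i] * freqs[j] * sum(codes[[i]] != codes[[j]])
  }
  tot / L
}

## dynamic-programming ANI oracle built on Biostrings' Smith-Waterman local
## aligner; same return shape as pairwise_ani()
dp_ani <- function(a, b, ...) {
  if (nchar(a) > nchar(b) || (nchar(a) == nchar(b) && a > b)) {
    tmp <- a; a <- b; b <- tmp
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = TRUE),
    gapOpening = 4, gapExtension = 2)
  cols <- nchar(as.character(Biostrings::alignedPattern(al)))
  if (cols == 0)
    return(list(ani = NA_real_, af_shorter = 0, aligned_bases = 0L))
  ani <- Biostrings::pid(al, type = "PID1")
  qa <- nchar(gsub("-", "", as.character(Biostrings::alignedPattern(al))))
  list(ani = ani, af_shorter = 100 * qa / nchar(a),
       aligned_bases = as.integer(qa))
}

## small two-sample pipeline demo configuration
demo_config <- function(out_dir = NULL, seed = 42L) {
  list(
    seed = seed, out_dir = out_dir,
    samples = list(
      list(sample_id = "stable", group = "stable",
           sim = list(n_genomes = 2, genome_len = 15000, depth_mean = 40,
                      error_rate = 0.001, n_strains = 2,
                      target_pi = 0.001, frac_nonsyn = 0.2),
           active = list("stable_g_01")),
      list(sample_id = "fluct", group = "fluct",
           sim = list(n_genomes = 2, genome_len = 15000, depth_mean = 40,
                      error_rate = 0.001, n_strains = 3,
                      target_pi = 0.01, frac_nonsyn = 0.5))))
}
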