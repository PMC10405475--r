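#' Specify a synthetic viral community
#'
#' Bundles the parameters of the community generator: how many genomes, how
#' long, how gene-dense, how abundances are distributed (log-normal, the
#' usual shape of metagenomic abundance profiles), and how reads are drawn.
#'
#' @param n_genomes number of genomes (>= 1).
#' @param genome_len_range length-2 integer vector, genome length bounds (bp).
#' @param gene_density coding genes per kb.
#' @param abundance_meanlog,abundance_sdlog log-normal abundance parameters.
#' @param read_len read length (bp).
#' @param error_rate per-base substitution error rate in reads.
#' @param depth_mean community-mean fold coverage; per-genome depth scales
#'   with its relative abundance.
#' @param seed integer seed; the whole community is a deterministic function
#'   of the spec including this seed.
#' @param id_prefix prefix for genome ids (lets several samples' genomes
#'   coexist in one namespace).
#' @return a `community_spec` list.
#' @export
community_spec <- function(n_genomes = 5L,
                           genome_len_range = c(30000L, 60000L),
                           gene_density = 1,
                           abundance_meanlog = 0,
                           abundance_sdlog = 0.5,
                           read_len = 100L,
                           error_rate = 0.001,
                           depth_mean = 30,
                           seed = 1L,
                           id_prefix = "genome") {
  if (n_genomes < 1L) stop("n_genomes must be >= 1")
  if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0, 1]")
  if (read_len > min(genome_len_range))
    stop("read_len exceeds the minimum genome length")
  structure(list(n_genomes = as.integer(n_genomes),
                 genome_len_range = as.integer(genome_len_range),
                 gene_density = gene_density,
                 abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog,
                 read_len = as.integer(read_len),
                 error_rate = error_rate,
                 depth_mean = depth_mean,
                 seed = as.integer(seed),
                 id_prefix = id_prefix),
            class = "community_spec")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

SENSE_CODONS <- local({
  all <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                           c("A", "C", "G", "T"), stringsAsFactors = FALSE),
               1, paste0, collapse = "")
  setdiff(all, c("TAA", "TAG", "TGA"))
})

sense_codons <- function() SENSE_CODONS

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  vapply(x, function(s)
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(s, "")[[1]]), collapse = "")),
    character(1), USE.NAMES = FALSE)
}

## One coding sequence: ATG, sense codons, stop. Length divisible by 3, no
## internal stop by construction.
random_cds <- function(len) {
  stopifnot(len %% 3 == 0, len >= 9)
  body <- sample(sense_codons(), len / 3 - 2, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), sample(STOP_CODONS, 1))
}

#' Generate reference genomes with annotated genes
#'
#' Each genome is random DNA carrying non-overlapping coding genes
#' (ATG...stop, length divisible by 3, no internal stop; strands mixed).
#' Deterministic under the spec's seed.
#'
#' @param spec a [community_spec()].
#' @return list with `contigs` (named character vector), `genes` (gene
#'   data.frame as in [read_gff()]), and `abundances` (named relative
#'   abundance vector drawn from the spec's log-normal).
#' @export
generate_genomes <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  set.seed(spec$seed)
  n <- spec$n_genomes
  lens <- if (spec$genome_len_range[1] == spec$genome_len_range[2])
    rep(spec$genome_len_range[1], n)
  else
    sample(spec$genome_len_range[1]:spec$genome_len_range[2], n, replace = TRUE)
  ids <- sprintf("%s_%02d", spec$id_prefix, seq_len(n))
  contigs <- character(n)
  gene_rows <- vector("list", n)
  for (i in seq_len(n)) {
    g <- generate_one_genome(lens[i], spec$gene_density, ids[i])
    contigs[i] <- g$seq
    gene_rows[[i]] <- g$genes
  }
  names(contigs) <- ids
  ab <- stats::rlnorm(n, spec$abundance_meanlog, spec$abundance_sdlog)
  ab <- ab / sum(ab)
  names(ab) <- ids
  list(contigs = contigs,
       genes = do.call(rbind, gene_rows),
       abundances = ab)
}

generate_one_genome <- function(len, gene_density, id) {
  n_genes <- round(gene_density * len / 1000)
  gene_lens <- if (n_genes > 0)
    sample(seq(300L, 900L, by = 3L), n_genes, replace = TRUE) else integer(0)
  if (sum(gene_lens) + n_genes * 20L > len)
    stop("infeasible gene density: genes do not fit in a ", len, " bp genome")
  ## spread genes with random intergenic gaps
  slack <- len - sum(gene_lens)
  cuts <- if (n_genes > 0) sort(sample.int(slack, n_genes)) else integer(0)
  starts <- cuts + c(0L, cumsum(gene_lens))[seq_len(n_genes)]
  seq_chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  genes <- NULL
  if (n_genes > 0) {
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    for (j in seq_len(n_genes)) {
      cds <- random_cds(gene_lens[j])
      placed <- if (strand[j] == "+") cds else revcomp(cds)
      idx <- (starts[j] + 1L):(starts[j] + gene_lens[j])
      seq_chars[idx] <- strsplit(placed, "")[[1]]
    }
    genes <- data.frame(
      gene_id = sprintf("%s_g%03d", id, seq_len(n_genes)),
      contig_id = id,
      start = starts,
      end = starts + gene_lens,
      strand = strand,
      frame = 0L,
      stringsAsFactors = FALSE)
  }
  list(seq = paste(seq_chars, collapse = ""), genes = genes)
}
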