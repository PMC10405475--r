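## Fast vectorized helpers: sequences as integer codes 1..4 (A,C,G,T).
BASE4 <- c("A", "C", "G", "T")

chars_to_code <- function(x) {
  ## x: single string -> integer vector (A=1,C=2,G=3,T=4, N=NA)
  v <- utf8ToInt(x)
  out <- rep(NA_integer_, length(v))
  out[v == 65L] <- 1L; out[v == 67L] <- 2L
  out[v == 71L] <- 3L; out[v == 84L] <- 4L
  out
}

code_to_string <- function(code) {
  intToUtf8(c(65L, 67L, 71L, 84L)[code])
}

#' Simulate shotgun reads from a strain pool
#'
#' Reads are drawn from the strain haplotypes in proportion to their
#' frequencies, with uniform start positions and independent per-base
#' substitution errors. Alongside the reads, a truth alignment table is
#' produced recording each read's exact origin and its edit distance to the
#' *reference* (strain mismatches at covered positions plus injected
#' errors), so the downstream pipeline can run without an external mapper.
#'
#' @param strains character vector of same-length haplotypes.
#' @param freqs strain frequencies (sum to 1).
#' @param reference the reference sequence reads are reported against.
#' @param contig_id reference contig id used in the alignment table.
#' @param depth_mean target fold coverage; read count =
#'   `round(depth_mean * L / read_len)`.
#' @param read_len read length (bp).
#' @param error_rate per-base substitution error probability.
#' @param seed integer seed.
#' @param read_prefix prefix for read ids.
#' @return list with `reads` (named character vector) and `aln` (alignment
#'   data.frame as in [read_alignments()], all forward strand, CIGAR
#'   `<read_len>M`).
#' @export
simulate_reads <- function(strains, freqs, reference, contig_id,
                           depth_mean, read_len = 100L, error_rate = 0,
                           seed = 1L, read_prefix = contig_id) {
  L <- nchar(reference)
  if (read_len > L) stop("read_len exceeds genome length")
  if (depth_mean <= 0) stop("depth_mean must be > 0")
  stopifnot(all(nchar(strains) == L))
  set.seed(seed)
  n_reads <- as.integer(round(depth_mean * L / read_len))
  if (n_reads == 0L)
    return(list(reads = character(0), aln = empty_alignments()))
  origin <- sample.int(length(strains), n_reads, replace = TRUE, prob = freqs)
  start <- sample.int(L - read_len + 1L, n_reads, replace = TRUE) - 1L

  strain_codes <- lapply(strains, chars_to_code)
  ref_code <- chars_to_code(reference)
  offs <- seq_len(read_len) - 1L
  idx <- rep(start, each = read_len) + offs + 1L      # 1-based genome index
  read_code <- unlist(strain_codes, use.names = FALSE)[
    idx + (rep(origin, each = read_len) - 1L) * L]
  ## substitution errors: shift by 1..3 mod 4
  if (error_rate > 0) {
    err <- which(stats::runif(length(read_code)) < error_rate)
    if (length(err)) {
      shift <- sample.int(3L, length(err), replace = TRUE)
      read_code[err] <- (read_code[err] - 1L + shift) %% 4L + 1L
    }
  }
  nm <- as.integer(rowsum(as.integer(read_code != ref_code[idx]),
                          rep(seq_len(n_reads), each = read_len)))
  big <- code_to_string(read_code)
  seqs <- substring(big, (seq_len(n_reads) - 1L) * read_len + 1L,
                    seq_len(n_reads) * read_len)
  ids <- sprintf("%s_r%07d", read_prefix, seq_len(n_reads))
  aln <- data.frame(read_id = ids, contig_id = contig_id, start = start,
                    cigar = paste0(read_len, "M"), nm = nm,
                    read_len = read_len, mapped = TRUE, strand = "+",
                    seq = seqs, stringsAsFactors = FALSE)
  list(reads = stats::setNames(seqs, ids), aln = aln)
}

empty_alignments <- function() {
  data.frame(read_id = character(0), contig_id = character(0),
             start = integer(0), cigar = character(0), nm = integer(0),
             read_len = integer(0), mapped = logical(0),
             strand = character(0), seq = character(0),
             stringsAsFactors = FALSE)
}

#' Simulate metatranscriptomic reads from active genomes
#'
#' Transcript reads are drawn only from the gene intervals of the genomes in
#' `active_ids`; inactive genomes receive zero reads. Genes shorter than the
#' read length are not sampled. Reads come from the reference haplotype with
#' no errors (transcript identity filtering is exercised by the genomic
#' simulator).
#'
#' @param contigs named character vector of reference genomes.
#' @param genes gene data.frame.
#' @param active_ids character vector of active genome ids.
#' @param depth fold coverage of the gene space of each active genome.
#' @param read_len read length (bp).
#' @param seed integer seed.
#' @return list with `reads`, `aln`, and `active` (the recorded truth set).
#' @export
simulate_transcriptome <- function(contigs, genes, active_ids, depth = 20,
                                   read_len = 100L, seed = 1L) {
  stopifnot(all(active_ids %in% names(contigs)))
  set.seed(seed)
  reads <- list(); alns <- list()
  for (id in active_ids) {
    g <- genes[genes$contig_id == id & (genes$end - genes$start) >= read_len, ,
               drop = FALSE]
    if (!nrow(g)) {
      warning("active genome ", id, " has no usable genes; skipped")
      next
    }
    glen <- g$end - g$start
    n_reads <- as.integer(round(depth * sum(glen) / read_len))
    if (n_reads == 0L) next
    pick <- sample.int(nrow(g), n_reads, replace = TRUE, prob = glen)
    start <- g$start[pick] +
      floor(stats::runif(n_reads) * (glen[pick] - read_len + 1L))
    seqs <- substring(contigs[[id]], start + 1L, start + read_len)
    ids <- sprintf("%s_t%07d", id, seq_len(n_reads))
    reads[[id]] <- stats::setNames(seqs, ids)
    alns[[id]] <- data.frame(read_id = ids, contig_id = id,
                             start = as.integer(start),
                             cigar = paste0(read_len, "M"), nm = 0L,
                             read_len = read_len, mapped = TRUE,
                             strand = "+", seq = seqs,
                             stringsAsFactors = FALSE)
  }
  list(reads = unlist(unname(reads)),
       aln = if (length(alns)) do.call(rbind, alns) else empty_alignments(),
       active = active_ids)
}

#' Simulate a full community with ground truth
#'
#' Convenience wrapper tying the generator together: reference genomes and
#' genes, per-genome strain pools, shotgun reads at abundance-scaled depth,
#' and a truth bundle (abundances, SNPs with coding effects, HVR intervals,
#' expected per-genome pi) that downstream tests use as oracle.
#'
#' @param spec a [community_spec()].
#' @param strain_specs single [strain_spec()] applied to every genome, or a
#'   list of one per genome.
#' @param active_ids genomes to mark transcriptionally active (may be empty;
#'   transcriptome reads are simulated only if non-empty).
#' @param transcript_depth fold coverage for transcriptome simulation.
#' @return list with `contigs`, `genes`, `abundances`, `strains` (per-genome
#'   [inject_strains()] results), `aln` (pooled genomic truth alignments),
#'   `reads`, `transcriptome` (or `NULL`), `truth` (per-genome expected pi,
#'   SNPs, HVRs, active set), and `library_bases`.
#' @export
simulate_community <- function(spec, strain_specs = strain_spec(),
                               active_ids = character(0),
                               transcript_depth = 20) {
  stopifnot(inherits(spec, "community_spec"))
  gen <- generate_genomes(spec)
  n <- spec$n_genomes
  if (inherits(strain_specs, "strain_spec"))
    strain_specs <- rep(list(strain_specs), n)
  stopifnot(length(strain_specs) == n)
  ids <- names(gen$contigs)
  depth <- spec$depth_mean * gen$abundances / mean(gen$abundances)
  strains <- list(); alns <- list(); reads <- list()
  for (i in seq_len(n)) {
    id <- ids[i]
    gg <- gen$genes[gen$genes$contig_id == id, , drop = FALSE]
    st <- inject_strains(gen$contigs[[id]], gg, strain_specs[[i]],
                         seed = spec$seed + 1000L + i)
    sim <- simulate_reads(st$strains, st$freqs, gen$contigs[[id]], id,
                          depth_mean = depth[i], read_len = spec$read_len,
                          error_rate = spec$error_rate,
                          seed = spec$seed + 2000L + i)
    strains[[id]] <- st
    alns[[id]] <- sim$aln
    reads[[id]] <- sim$reads
  }
  txn <- NULL
  if (length(active_ids))
    txn <- simulate_transcriptome(gen$contigs, gen$genes, active_ids,
                                  depth = transcript_depth,
                                  read_len = spec$read_len,
                                  seed = spec$seed + 3000L)
  aln <- do.call(rbind, unname(alns))
  truth <- list(
    abundances = gen$abundances,
    expected_pi = vapply(ids, function(id)
      truth_pi(strains[[id]]$truth_snps, nchar(gen$contigs[[id]])),
      numeric(1)),
    snps = do.call(rbind, lapply(ids, function(id) {
      t <- strains[[id]]$truth_snps
      if (nrow(t)) cbind(contig_id = id, t, stringsAsFactors = FALSE)
      else NULL
    })),
    hvrs = do.call(rbind, lapply(ids, function(id) {
      t <- strains[[id]]$truth_hvr
      if (!is.null(t)) cbind(contig_id = id, t, stringsAsFactors = FALSE)
      else NULL
    })),
    active = active_ids)
  list(contigs = gen$contigs, genes = gen$genes,
       abundances = gen$abundances, strains = strains,
       aln = aln, reads = unlist(unname(reads)),
       transcriptome = txn, truth = truth,
       library_bases = sum(nchar(unlist(unname(reads)))))
}
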