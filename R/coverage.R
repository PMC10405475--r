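#' Filter alignments by read identity and aligned fraction
#'
#' The standard viromic read-recruitment filter: a mapped record is kept iff
#' its edit-distance identity, `1 - NM / aligned columns` (aligned columns =
#' matched + mismatched + inserted + deleted bases), is at least
#' `min_identity`, and the fraction of the read aligned (query-consumed
#' non-clipped bases / read length) is at least `min_read_frac`. Defaults
#' are the strict viromic pair (95% identity, 90% read coverage);
#' metatranscriptomic recruitment conventionally relaxes identity to 90%.
#'
#' @param aln alignment data.frame (see [read_alignments()]).
#' @param min_identity minimum read identity in `[0, 1]`.
#' @param min_read_frac minimum aligned fraction of the read in `[0, 1]`.
#' @return the retained subset of `aln`.
#' @export
filter_alignments <- function(aln, min_identity = 0.95, min_read_frac = 0.90) {
  aln <- aln[aln$mapped, , drop = FALSE]
  if (!nrow(aln)) return(aln)
  if (any(aln$nm < 0)) stop("negative NM value")
  cols <- cigar_aligned_columns(aln$cigar)
  identity <- 1 - aln$nm / cols
  frac <- cigar_query_length(aln$cigar, aligned_only = TRUE) / aln$read_len
  aln[identity >= min_identity & frac >= min_read_frac, , drop = FALSE]
}

## Reference intervals covered by the records: matrix of (start, end) 0-based
## half-open rows, one per cigar segment that consumes reference (M/D/=/X/N).
## The single-M fast path is vectorized; general cigars take the slow loop.
ref_segments <- function(start, cigar) {
  simple <- grepl("^[0-9]+M$", cigar)
  segs <- NULL
  if (any(simple)) {
    w <- as.integer(sub("M$", "", cigar[simple]))
    segs <- cbind(start[simple], start[simple] + w)
  }
  extra <- lapply(which(!simple), function(i) {
    ops <- cigar_ops(cigar[i])
    p <- start[i]
    out <- NULL
    for (j in seq_along(ops$op)) {
      if (ops$op[j] %in% c("M", "D", "=", "X", "N")) {
        out <- rbind(out, c(p, p + ops$len[j]))
        p <- p + ops$len[j]
      } else if (ops$op[j] %in% c("I", "S")) p <- p
    }
    out
  })
  if (length(extra)) segs <- rbind(segs, do.call(rbind, extra))
  segs
}

#' Per-base depth profile of one contig
#'
#' Each reference-consuming position of each retained record contributes one
#' unit of depth; deletions inside a read still consume reference and count
#' as covered by that read (the genomecov convention).
#'
#' @param aln retained alignment records of a single contig.
#' @param contig_len contig length (bp).
#' @return integer vector of per-position depth, length `contig_len`.
#' @export
depth_profile <- function(aln, contig_len) {
  depth_delta <- numeric(contig_len + 1L)
  if (nrow(aln)) {
    segs <- ref_segments(aln$start, aln$cigar)
    if (any(segs[, 2] > contig_len) || any(segs[, 1] < 0))
      stop("alignment exceeds contig bounds")
    add <- tabulate(segs[, 1] + 1L, nbins = contig_len + 1L)
    sub <- tabulate(segs[, 2] + 1L, nbins = contig_len + 1L)
    depth_delta <- add - sub
  }
  as.integer(cumsum(depth_delta))[seq_len(contig_len)]
}

#' Depth profiles for every contig
#'
#' @param aln retained alignment data.frame (any number of contigs).
#' @param refs named character vector of reference sequences.
#' @return named list of per-position depth vectors, one per reference.
#' @export
depth_profiles <- function(aln, refs) {
  out <- lapply(names(refs), function(id)
    depth_profile(aln[aln$contig_id == id, , drop = FALSE], nchar(refs[[id]])))
  stats::setNames(out, names(refs))
}

#' Breadth of coverage
#'
#' Fraction of contig positions covered at depth `>= min_depth`.
#'
#' @param depth per-position depth vector.
#' @param min_depth depth threshold.
#' @return fraction in `[0, 1]`.
#' @export
breadth <- function(depth, min_depth = 1L) {
  if (!length(depth)) stop("empty depth profile")
  mean(depth >= min_depth)
}

#' Normalized abundance table (coverage per gigabase)
#'
#' Per vOTU and sample: mean depth over all positions (zeros included) of
#' the representative, scaled by `1e9 / library_bases` — "coverage per
#' gigabase of virome". Relative abundances are column-normalized entries.
#'
#' @param profiles_by_sample named list (sample -> named list of depth
#'   vectors per vOTU representative).
#' @param library_bases named numeric vector of per-sample library sizes in
#'   bases.
#' @return list with `abundance` (vOTU x sample matrix, per Gb),
#'   `relative` (column-normalized; zero columns stay zero), and `breadth`
#'   (vOTU x sample matrix at `min_depth = 1`).
#' @export
abundance_table <- function(profiles_by_sample, library_bases) {
  samples <- names(profiles_by_sample)
  stopifnot(!is.null(samples), all(samples %in% names(library_bases)))
  if (any(library_bases[samples] <= 0)) stop("library size must be positive")
  votus <- names(profiles_by_sample[[1]])
  ab <- sapply(samples, function(s)
    vapply(profiles_by_sample[[s]][votus], mean, numeric(1)) *
      (1e9 / library_bases[[s]]))
  br <- sapply(samples, function(s)
    vapply(profiles_by_sample[[s]][votus], breadth, numeric(1)))
  ab <- matrix(ab, nrow = length(votus),
               dimnames = list(votus, samples))
  br <- matrix(br, nrow = length(votus),
               dimnames = list(votus, samples))
  rel <- sweep(ab, 2, colSums(ab), "/")
  rel[, colSums(ab) == 0] <- 0
  list(abundance = ab, relative = rel, breadth = br)
}

#' Per-site allele counts from aligned reads
#'
#' For every aligned column that consumes both reference and query, the read
#' base increments the corresponding A/C/G/T counter at that reference
#' position. Deletions contribute nothing; read `N`s (and any non-ACGT
#' base) are dropped. Reference positions that are `N` are masked to zero
#' counts (no defined reference allele).
#'
#' @param aln retained alignment records of one contig.
#' @param ref reference sequence of the contig.
#' @return integer matrix `contig_len x 4`, columns `A,C,G,T`.
#' @export
allele_counts <- function(aln, ref) {
  L <- nchar(ref)
  counts <- matrix(0L, nrow = L, ncol = 4L,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  if (nrow(aln)) {
    simple <- grepl("^[0-9]+M$", aln$cigar)
    pos_all <- integer(0); base_all <- integer(0)
    if (any(simple)) {
      sub_aln <- aln[simple, , drop = FALSE]
      lens <- nchar(sub_aln$seq)
      pos_all <- rep(sub_aln$start, times = lens) + sequence(lens)
      base_all <- chars_to_code(paste(sub_aln$seq, collapse = ""))
    }
    for (i in which(!simple)) {
      ops <- cigar_ops(aln$cigar[i])
      rp <- aln$start[i]; qp <- 0L
      code <- chars_to_code(aln$seq[i])
      for (j in seq_along(ops$op)) {
        op <- ops$op[j]; len <- ops$len[j]
        if (op %in% c("M", "=", "X")) {
          pos_all <- c(pos_all, rp + seq_len(len))
          base_all <- c(base_all, code[qp + seq_len(len)])
          rp <- rp + len; qp <- qp + len
        } else if (op %in% c("D", "N")) rp <- rp + len
        else if (op %in% c("I", "S")) qp <- qp + len
      }
    }
    keep <- !is.na(base_all)
    pos_all <- pos_all[keep]; base_all <- base_all[keep]
    if (any(pos_all < 1L) || any(pos_all > L))
      stop("alignment exceeds contig bounds")
    tab <- tabulate((pos_all - 1L) * 4L + base_all, nbins = 4L * L)
    counts <- matrix(tab, ncol = 4L, byrow = TRUE,
                     dimnames = list(NULL, c("A", "C", "G", "T")))
  }
  ref_n <- is.na(chars_to_code(ref))
  if (any(ref_n)) counts[ref_n, ] <- 0L
  counts
}
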