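#' Shannon diversity of a community
#'
#' `H = -sum(p_i log p_i)` over positive abundances after normalization.
#' Natural log by default (the convention under which species-rich virome
#' communities land near `ln(richness)`).
#'
#' @param abundances non-negative abundance vector, at least one positive.
#' @param base logarithm base.
#' @return Shannon index H.
#' @export
shannon <- function(abundances, base = exp(1)) {
  if (any(abundances < 0)) stop("negative abundance")
  tot <- sum(abundances)
  if (tot <= 0) stop("all-zero abundance vector")
  p <- abundances[abundances > 0] / tot
  -sum(p * log(p, base = base))
}

#' Shared and unique vOTUs across samples
#'
#' Counts every region of the 2- or 3-set Venn diagram of vOTU presence and
#' sums, per sample, the relative abundance carried by each region's vOTUs.
#'
#' @param presence logical vOTU x sample matrix.
#' @param relative numeric vOTU x sample matrix of relative abundances
#'   (optional).
#' @param samples which samples (2 or 3 column names) to compare.
#' @return data.frame with one row per Venn region: `region` (e.g. `"A&B"`),
#'   `n_votus`, and per-sample abundance share columns when `relative` is
#'   given.
#' @export
shared_unique <- function(presence, relative = NULL,
                          samples = colnames(presence)) {
  if (!all(samples %in% colnames(presence)))
    stop("unknown sample id: ",
         paste(setdiff(samples, colnames(presence)), collapse = ", "))
  k <- length(samples)
  if (!k %in% 2:3) stop("shared_unique compares 2 or 3 samples")
  pm <- presence[, samples, drop = FALSE]
  in_any <- rowSums(pm) > 0
  pattern <- apply(pm, 1, function(r) paste(samples[r], collapse = "&"))
  regions <- unlist(lapply(seq_len(k), function(m)
    utils::combn(samples, m, paste, collapse = "&")))
  out <- data.frame(region = regions,
                    n_votus = vapply(regions, function(r)
                      sum(pattern == r & in_any), integer(1)),
                    stringsAsFactors = FALSE)
  if (!is.null(relative)) {
    for (s in samples) {
      out[[paste0("abund_", s)]] <- vapply(regions, function(r)
        sum(relative[pattern == r & in_any, s]), numeric(1))
    }
  }
  rownames(out) <- NULL
  out
}

#' Rank-abundance ordering across two samples
#'
#' vOTUs are ordered by their abundance in the reference sample
#' (descending, ties by id); vOTUs absent from the reference sample but
#' present in the other are appended, ordered by their own abundance.
#'
#' @param relative vOTU x sample relative-abundance matrix.
#' @param order_by reference sample (column name).
#' @param other the second sample.
#' @return data.frame `votu`, `rank`, plus the two samples' abundances and
#'   an `exclusive` flag for the appended vOTUs.
#' @export
rank_abundance <- function(relative, order_by, other) {
  stopifnot(all(c(order_by, other) %in% colnames(relative)))
  a <- relative[, order_by]; b <- relative[, other]
  ids <- rownames(relative)
  main <- ids[a > 0][order(-a[a > 0], ids[a > 0])]
  excl <- ids[a == 0 & b > 0]
  excl <- excl[order(-b[match(excl, ids)], excl)]
  votu <- c(main, excl)
  data.frame(votu = votu, rank = seq_along(votu),
             ref_abundance = a[match(votu, ids)],
             other_abundance = b[match(votu, ids)],
             exclusive = votu %in% excl,
             stringsAsFactors = FALSE)
}

#' Least-squares slope of a rarefaction tail
#'
#' Fits vOTUs-vs-reads by ordinary least squares over the last four points
#' of a rarefaction curve and converts the slope to predicted additional
#' vOTUs per million further reads.
#'
#' @param reads subsample sizes (ascending).
#' @param votus detected vOTU counts at those sizes.
#' @return list with `slope` (vOTUs per read) and `pred_per_million`.
#' @export
rarefaction_slope <- function(reads, votus) {
  if (length(reads) < 4 || length(votus) != length(reads))
    stop("need at least 4 rarefaction points")
  n <- length(reads)
  tail_idx <- (n - 3):n
  fit <- stats::lm(v ~ r, data = data.frame(r = reads[tail_idx],
                                            v = votus[tail_idx]))
  slope <- unname(stats::coef(fit)[2])
  list(slope = slope, pred_per_million = slope * 1e6)
}

#' Rarefaction curve by read subsampling
#'
#' At each requested depth, reads are subsampled without replacement
#' (seeded), per-vOTU breadth is recomputed from the retained alignments,
#' and a vOTU counts as detected when its breadth reaches
#' `presence_breadth`. The tail slope and the predicted vOTU gain per
#' million additional reads come from [rarefaction_slope()].
#'
#' @param aln filtered alignment data.frame (all reads of one sample).
#' @param refs named character vector of vOTU representative sequences.
#' @param depths integer vector (>= 4 values) of subsample sizes, in reads.
#' @param presence_breadth breadth threshold for detection (default 0.70).
#' @param min_depth per-position depth threshold inside [breadth()].
#' @param seed integer seed for the subsampling.
#' @return list with `curve` (data.frame `reads`, `votus`), `slope`,
#'   `pred_per_million`.
#' @export
rarefy <- function(aln, refs, depths, presence_breadth = 0.70,
                   min_depth = 1L, seed = 1L) {
  if (length(depths) < 4) stop("need at least 4 subsample depths")
  reads <- unique(aln$read_id)
  if (any(depths > length(reads)))
    stop("subsample depth exceeds library size (", length(reads), " reads)")
  set.seed(seed)
  depths <- sort(depths)
  votus <- vapply(depths, function(d) {
    keep <- sample(reads, d)
    sub <- aln[aln$read_id %in% keep, , drop = FALSE]
    profs <- depth_profiles(sub, refs)
    sum(vapply(profs, function(p) breadth(p, min_depth), numeric(1)) >=
          presence_breadth)
  }, numeric(1))
  sl <- rarefaction_slope(depths, votus)
  list(curve = data.frame(reads = depths, votus = votus),
       slope = sl$slope, pred_per_million = sl$pred_per_million)
}

#' Call transcriptionally active vOTUs
#'
#' Metatranscriptomic alignments are filtered by read identity and aligned
#' fraction, breadth is computed per vOTU representative, and a vOTU is
#' called active when at least `min_breadth` of its genome is covered by
#' recruited transcript reads (the 90/90/50 recruitment rule).
#'
#' @param aln transcript alignment data.frame.
#' @param refs named character vector of vOTU representatives.
#' @param min_identity transcript read identity threshold (default 0.90).
#' @param min_read_frac aligned-fraction threshold (default 0.90).
#' @param min_breadth genome breadth required to call activity
#'   (default 0.50).
#' @param genes optional gene table; per-gene mean transcript depth is
#'   reported for active vOTUs.
#' @return list with `active` (character vector), `table` (per-vOTU breadth
#'   and mean transcript depth), and `gene_activity` (per-gene mean depth
#'   on active vOTUs, or `NULL`).
#' @export
call_active <- function(aln, refs, min_identity = 0.90, min_read_frac = 0.90,
                        min_breadth = 0.50, genes = NULL) {
  kept <- filter_alignments(aln, min_identity, min_read_frac)
  profs <- depth_profiles(kept, refs)
  br <- vapply(profs, breadth, numeric(1))
  tab <- data.frame(votu = names(refs), breadth = unname(br),
                    mean_depth = vapply(profs, mean, numeric(1)),
                    active = unname(br) >= min_breadth,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  gene_activity <- NULL
  if (!is.null(genes) && any(tab$active)) {
    act <- tab$votu[tab$active]
    gg <- genes[genes$contig_id %in% act, , drop = FALSE]
    if (nrow(gg)) {
      gene_activity <- data.frame(
        gene_id = gg$gene_id, contig_id = gg$contig_id,
        mean_depth = vapply(seq_len(nrow(gg)), function(i)
          mean(profs[[gg$contig_id[i]]][(gg$start[i] + 1L):gg$end[i]]),
          numeric(1)),
        stringsAsFactors = FALSE)
    }
  }
  list(active = tab$votu[tab$active], table = tab,
       gene_activity = gene_activity)
}
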