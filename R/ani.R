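#' Pairwise average nucleotide identity and aligned fraction
#'
#' Anchor-based local comparison of two sequences: shared k-mers are grouped
#' by diagonal, chained into blocks (gaps up to `max_gap` between anchors
#' are bridged and their mismatches counted), blocks shorter than
#' `min_block` are discarded, and non-conflicting blocks (non-overlapping on
#' both sequences) are merged greedily by descending matched length. ANI is
#' the length-weighted mean identity over the merged blocks; the aligned
#' fraction is the merged aligned length relative to the shorter sequence.
#' The comparison is gap-free within blocks, which is exact for the
#' substitution-structured divergence this rule is used on; a
#' dynamic-programming aligner serves as its oracle in the test suite.
#'
#' Arguments are canonicalized (shorter sequence first, ties by sequence
#' order) so the result is exactly symmetric.
#'
#' @param a,b DNA sequences (character strings).
#' @param k anchor k-mer size.
#' @param min_block minimum merged-block length (bp).
#' @param max_gap largest anchor gap bridged within a block (bp).
#' @return list with `ani` (percent identity over aligned blocks; `NA` if
#'   nothing aligns), `af_shorter` (percent of the shorter sequence
#'   aligned), and `aligned_bases`.
#' @export
pairwise_ani <- function(a, b, k = 15L, min_block = 100L, max_gap = 200L) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  if (nchar(a) > nchar(b) || (nchar(a) == nchar(b) && a > b)) {
    tmp <- a; a <- b; b <- tmp
  }
  la <- nchar(a); lb <- nchar(b)
  if (la < k)
    return(list(ani = NA_real_, af_shorter = 0, aligned_bases = 0L))
  ka <- substring(a, seq_len(la - k + 1L), seq_len(la - k + 1L) + k - 1L)
  kb <- substring(b, seq_len(lb - k + 1L), seq_len(lb - k + 1L) + k - 1L)
  pos_a <- split(seq_along(ka), ka)
  hit_b <- which(kb %in% names(pos_a))
  if (!length(hit_b))
    return(list(ani = NA_real_, af_shorter = 0, aligned_bases = 0L))
  pa <- pos_a[kb[hit_b]]
  reps <- lengths(pa)
  anchor_a <- unlist(pa, use.names = FALSE)          # 1-based starts in a
  anchor_b <- rep(hit_b, reps)
  diag <- anchor_b - anchor_a
  ac <- chars_to_code(a); bc <- chars_to_code(b)

  blocks <- list()
  for (d in unique(diag)) {
    sa <- sort(anchor_a[diag == d])
    ## chain anchors with gaps <= max_gap
    brk <- c(0L, which(diff(sa) > max_gap + k), length(sa))
    for (j in seq_len(length(brk) - 1L)) {
      run <- sa[(brk[j] + 1L):brk[j + 1L]]
      s <- min(run); e <- max(run) + k - 1L          # inclusive, in a
      ## extend to nearby sequence/overlap ends so end mismatches count in
      lo <- max(1L, 1L - d); hi <- min(la, lb - d)
      s2 <- if (s - lo <= max_gap) lo else s
      e2 <- if (hi - e <= max_gap) hi else e
      len <- e2 - s2 + 1L
      if (len < min_block) next
      xa <- ac[s2:e2]; xb <- bc[(s2:e2) + d]
      mism <- sum(xa != xb | is.na(xa) | is.na(xb), na.rm = TRUE)
      blocks[[length(blocks) + 1L]] <-
        c(s2, e2, s2 + d, e2 + d, len, len - mism)
    }
  }
  if (!length(blocks))
    return(list(ani = NA_real_, af_shorter = 0, aligned_bases = 0L))
  bl <- do.call(rbind, blocks)
  colnames(bl) <- c("sa", "ea", "sb", "eb", "len", "match")
  bl <- bl[order(-bl[, "match"]), , drop = FALSE]
  taken_a <- logical(la); taken_b <- logical(lb)
  tot_len <- 0; tot_match <- 0
  for (r in seq_len(nrow(bl))) {
    ia <- bl[r, "sa"]:bl[r, "ea"]; ib <- bl[r, "sb"]:bl[r, "eb"]
    if (any(taken_a[ia]) || any(taken_b[ib])) next
    taken_a[ia] <- TRUE; taken_b[ib] <- TRUE
    tot_len <- tot_len + bl[r, "len"]
    tot_match <- tot_match + bl[r, "match"]
  }
  list(ani = unname(100 * tot_match / tot_len),
       af_shorter = unname(100 * tot_len / la),
       aligned_bases = as.integer(unname(tot_len)))
}

#' Greedy species-level vOTU clustering
#'
#' Contigs are sorted by length (descending; length ties broken by
#' lexicographic id) and each joins the first existing cluster whose
#' representative it matches at `>= min_ani` percent identity across
#' `>= min_af` percent of the shorter sequence, else founds a new cluster.
#' Because contigs are processed longest-first, every representative is the
#' longest member of its cluster.
#'
#' @param contigs named character vector of viral contig sequences.
#' @param min_ani minimum percent nucleotide identity (default 95).
#' @param min_af minimum percent of the shorter sequence aligned
#'   (default 80).
#' @param ani_fun comparison function with the signature and return shape of
#'   [pairwise_ani()]; swap in an exhaustive aligner to use it as oracle.
#' @param exclude optional named character vector of contaminant sequences;
#'   contigs matching any at the same thresholds are dropped before
#'   clustering.
#' @return list with `clusters` (data.frame: `votu_id`,
#'   `representative_id`, `rep_length`, `n_members`, `members`
#'   comma-joined), `assignment` (named vector contig -> votu), and
#'   `excluded` (ids removed by the contaminant screen).
#' @export
cluster_votus <- function(contigs, min_ani = 95, min_af = 80,
                          ani_fun = pairwise_ani, exclude = NULL) {
  stopifnot(length(contigs) >= 1, !is.null(names(contigs)))
  excluded <- character(0)
  if (!is.null(exclude) && length(exclude)) {
    hit <- vapply(names(contigs), function(id) {
      any(vapply(exclude, function(ex) {
        r <- ani_fun(contigs[[id]], ex)
        !is.na(r$ani) && r$ani >= min_ani && r$af_shorter >= min_af
      }, logical(1)))
    }, logical(1))
    excluded <- names(contigs)[hit]
    contigs <- contigs[!hit]
    if (!length(contigs)) stop("all contigs removed by contaminant screen")
  }
  ord <- order(-nchar(contigs), names(contigs))
  contigs <- contigs[ord]
  reps <- character(0)
  members <- list()
  assignment <- character(length(contigs))
  names(assignment) <- names(contigs)
  for (id in names(contigs)) {
    joined <- FALSE
    for (ri in seq_along(reps)) {
      r <- ani_fun(contigs[[id]], contigs[[reps[ri]]])
      if (!is.na(r$ani) && r$ani >= min_ani && r$af_shorter >= min_af) {
        members[[ri]] <- c(members[[ri]], id)
        assignment[[id]] <- reps[ri]
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      reps <- c(reps, id)
      members[[length(reps)]] <- id
      assignment[[id]] <- id
    }
  }
  clusters <- data.frame(
    votu_id = sprintf("vOTU_%04d", seq_along(reps)),
    representative_id = reps,
    rep_length = nchar(contigs[reps]),
    n_members = lengths(members),
    members = vapply(members, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
  list(clusters = clusters, assignment = assignment, excluded = excluded)
}
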