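#' Detect hypervariable regions (genomic islands) from depth
#'
#' A contig is eligible if its median per-base depth (over all positions,
#' zeros included) is at least `min_median`. Within an eligible contig a
#' position is "low" if its depth is at most `frac` of the median
#' (inclusive), and HVRs are maximal runs of consecutive low positions of
#' length at least `min_len`; runs separated by up to `max_gap` non-low
#' positions can optionally be bridged.
#'
#' @param depth per-position depth vector of one contig.
#' @param contig_id contig id carried into the output.
#' @param frac low-coverage threshold as a fraction of the median
#'   (default 0.20).
#' @param min_len minimum island length in bp (default 500).
#' @param min_median minimum contig median depth for eligibility
#'   (default 5).
#' @param max_gap bridge non-low gaps up to this many bp (default 0,
#'   strict runs).
#' @return data.frame of intervals (`contig_id`, `start`, `end` 0-based
#'   half-open, `length`, `island_mean_depth`, `contig_median_depth`); zero
#'   rows if none. Attribute `eligible` records whether the contig passed
#'   the median-depth gate.
#' @export
detect_hvrs <- function(depth, contig_id = "contig", frac = 0.20,
                        min_len = 500L, min_median = 5, max_gap = 0L) {
  stopifnot(length(depth) > 0)
  med <- stats::median(depth)
  empty <- data.frame(contig_id = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      island_mean_depth = numeric(0),
                      contig_median_depth = numeric(0),
                      stringsAsFactors = FALSE)
  if (med < min_median) {
    attr(empty, "eligible") <- FALSE
    return(empty)
  }
  low <- depth <= frac * med
  if (max_gap > 0L) {
    ## bridge short non-low gaps flanked by low runs
    r <- rle(low)
    ends <- cumsum(r$lengths)
    inner <- which(!r$values & r$lengths <= max_gap &
                     seq_along(r$values) > 1 &
                     seq_along(r$values) < length(r$values))
    for (i in inner) low[(ends[i] - r$lengths[i] + 1L):ends[i]] <- TRUE
  }
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  if (!any(keep)) {
    attr(empty, "eligible") <- TRUE
    return(empty)
  }
  out <- data.frame(
    contig_id = contig_id,
    start = starts[keep] - 1L,
    end = ends[keep],
    length = r$lengths[keep],
    island_mean_depth = vapply(which(keep), function(i)
      mean(depth[starts[i]:ends[i]]), numeric(1)),
    contig_median_depth = med,
    stringsAsFactors = FALSE)
  attr(out, "eligible") <- TRUE
  out
}

#' Summarize HVR collections by label
#'
#' @param hvrs_by_label named list of HVR data.frames (e.g. one per
#'   assembly strategy), as returned by [detect_hvrs()].
#' @param contig_bp named numeric vector: total contig bp per label (for
#'   densities); optional.
#' @return data.frame with per-label HVR count, summed HVR length, and
#'   density (HVR bp per contig bp) when `contig_bp` is given.
#' @export
hvr_summary <- function(hvrs_by_label, contig_bp = NULL) {
  labels <- names(hvrs_by_label)
  n <- vapply(hvrs_by_label, nrow, integer(1))
  bp <- vapply(hvrs_by_label, function(h)
    if (nrow(h)) sum(h$length) else 0L, numeric(1))
  out <- data.frame(label = labels, n_hvrs = n, hvr_bp = bp,
                    stringsAsFactors = FALSE)
  if (!is.null(contig_bp))
    out$density <- bp / contig_bp[labels]
  rownames(out) <- NULL
  out
}
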