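## CIGAR arithmetic for the minimal SAM dialect used throughout the package.
## Reference-consuming ops: M, D, =, X, N. Query-consuming ops: M, I, =, X, S.

cigar_ops <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(lens) != length(ops) || length(ops) == 0L)
    stop("malformed CIGAR string: ", cigar)
  list(len = lens, op = ops)
}

#' Reference-consumed length of a CIGAR string
#'
#' Number of reference bases spanned by an alignment: M/D/=/X/N operations
#' consume the reference; I/S/H/P do not.
#'
#' @param cigar character vector of CIGAR strings.
#' @return integer vector of reference spans.
#' @export
cigar_ref_length <- function(cigar) {
  cigar_sum(cigar, c("M", "D", "=", "X", "N"))
}

## vectorized sum of op lengths for a consumption class; single-M cigars
## (the overwhelming majority in substitution-only data) skip the parser
cigar_sum <- function(cigar, ops_keep) {
  out <- integer(length(cigar))
  simple <- grepl("^[0-9]+M$", cigar)
  if ("M" %in% ops_keep)
    out[simple] <- as.integer(sub("M$", "", cigar[simple]))
  for (i in which(!simple)) {
    ops <- cigar_ops(cigar[i])
    out[i] <- sum(ops$len[ops$op %in% ops_keep])
  }
  out
}

#' Query-consumed length of a CIGAR string
#'
#' Number of read bases used by an alignment. With `aligned_only = TRUE`
#' soft-clipped bases are excluded (M/I/=/X only), which is the numerator of
#' the read aligned-fraction filter; with `aligned_only = FALSE` soft clips
#' count too and the result must equal the read length for a mapped record.
#'
#' @param cigar character vector of CIGAR strings.
#' @param aligned_only drop soft-clipped bases from the count.
#' @return integer vector of query-consumed lengths.
#' @export
cigar_query_length <- function(cigar, aligned_only = FALSE) {
  keep <- if (aligned_only) c("M", "I", "=", "X") else c("M", "I", "=", "X", "S")
  cigar_sum(cigar, keep)
}

## Aligned columns (M/I/D/=/X) — the denominator of edit-distance identity.
cigar_aligned_columns <- function(cigar) {
  cigar_sum(cigar, c("M", "I", "D", "=", "X"))
}
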