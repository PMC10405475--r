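#' Classify contigs as viral from detector score tables
#'
#' Combines VirSorter, DeepVirFinder and MARVEL scores with the standard
#' four-criterion rule: a contig is viral if it meets any of
#' (i) VirSorter category 1, 2, 4 or 5;
#' (ii) DeepVirFinder score >= 0.9 and p < 0.05;
#' (iii) MARVEL probability >= 90;
#' (iv) DeepVirFinder score >= 0.7 and p < 0.05 and MARVEL >= 70.
#' Absent detector fields (`NA`) fail their criteria.
#'
#' @param scores data.frame with columns `contig_id`, `vs_category`,
#'   `dvf_score`, `dvf_p`, `marvel_prob` (missing values as `NA`).
#' @return the input with logical columns `crit1`..`crit4`, `viral`, and a
#'   comma-separated `criteria` listing which rules fired.
#' @export
classify_viral <- function(scores) {
  need <- c("contig_id", "vs_category", "dvf_score", "dvf_p", "marvel_prob")
  miss <- setdiff(need, names(scores))
  if (length(miss)) stop("missing score columns: ", paste(miss, collapse = ", "))
  isT <- function(x) !is.na(x) & x
  c1 <- scores$vs_category %in% c(1, 2, 4, 5)   # %in% is FALSE on NA
  c2 <- isT(scores$dvf_score >= 0.9 & scores$dvf_p < 0.05)
  c3 <- isT(scores$marvel_prob >= 90)
  c4 <- isT(scores$dvf_score >= 0.7 & scores$dvf_p < 0.05 &
              scores$marvel_prob >= 70)
  out <- scores
  out$crit1 <- c1; out$crit2 <- c2; out$crit3 <- c3; out$crit4 <- c4
  out$viral <- c1 | c2 | c3 | c4
  out$criteria <- apply(cbind(c1, c2, c3, c4), 1, function(r)
    paste(which(r), collapse = ","))
  out
}

#' Read a detector-score TSV
#'
#' Columns `contig_id`, `vs_category`, `dvf_score`, `dvf_p`, `marvel_prob`;
#' empty cells mean the detector did not score that contig.
#'
#' @param path path to the TSV.
#' @return data.frame suitable for [classify_viral()].
#' @export
read_detector_scores <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  df
}

#' Assembly N50
#'
#' Smallest length among the largest contigs whose cumulative length first
#' reaches half the assembly total.
#'
#' @param lengths numeric vector of contig lengths.
#' @return the N50 in bp.
#' @export
n50 <- function(lengths) {
  if (!length(lengths)) stop("empty length vector")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}
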