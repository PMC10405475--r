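#' Read alignments from a SAM/BAM file
#'
#' Parses a SAM (or BAM) file through Rsamtools and returns the alignment
#' table used by all coverage and pileup code. SAM's 1-based `POS` is
#' converted to the package-wide 0-based half-open convention here, at the
#' file boundary, and nowhere else. Unmapped records are kept but flagged
#' `mapped = FALSE` so coverage code can exclude them.
#'
#' Edit distance is taken from the `NM` tag; when `NM` is absent it is
#' reconstructed from the `MD` tag (mismatches in `MD` plus inserted bases
#' from the CIGAR). Records with neither tag are an error.
#'
#' @param path path to a SAM or BAM file.
#' @param refs named character vector of reference sequences (used to check
#'   that every record maps to a known contig and stays in bounds).
#' @return a data.frame with columns `read_id`, `contig_id`, `start`
#'   (0-based), `cigar`, `nm`, `read_len`, `mapped`, `strand`, `seq`.
#' @export
read_alignments <- function(path, refs) {
  if (!file.exists(path)) stop("no such file: ", path)
  bam <- if (grepl("\\.bam$", path, ignore.case = TRUE)) path else {
    dest <- tempfile(fileext = "")
    Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                     indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    tag = c("NM", "MD")))[[1]]
  mapped <- !bitwAnd(res$flag, 4L)
  strand <- ifelse(bitwAnd(res$flag, 16L), "-", "+")
  seq <- as.character(res$seq)
  nm <- res$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, length(res$qname))
  md <- res$tag$MD
  need <- mapped & is.na(nm)
  if (any(need)) {
    if (is.null(md) || any(is.na(md[need])))
      stop("mapped records without NM or MD tag; recompute edit distances ",
           "(e.g. samtools calmd) before importing")
    nm[need] <- nm_from_md(md[need], res$cigar[need])
  }
  aln <- data.frame(
    read_id = res$qname,
    contig_id = as.character(res$rname),
    start = ifelse(mapped, res$pos - 1L, NA_integer_),
    cigar = ifelse(mapped, res$cigar, NA_character_),
    nm = ifelse(mapped, nm, NA_integer_),
    read_len = nchar(seq),
    mapped = mapped,
    strand = strand,
    seq = seq,
    stringsAsFactors = FALSE)
  validate_alignments(aln[aln$mapped, , drop = FALSE], refs)
  aln
}

## NM = MD mismatch letters + inserted bases (deletions appear in both MD and
## NM, and MD's ^-runs count them once).
nm_from_md <- function(md, cigar) {
  mism <- vapply(md, function(x) {
    x <- gsub("\\^[A-Z]+", "", x)      # drop deletion runs, count below
    sum(nchar(regmatches(x, gregexpr("[A-Z]", x))[[1]]))
  }, numeric(1), USE.NAMES = FALSE)
  dels <- vapply(md, function(x) {
    runs <- regmatches(x, gregexpr("\\^[A-Z]+", x))[[1]]
    sum(nchar(runs)) - length(runs)
  }, numeric(1), USE.NAMES = FALSE)
  ins <- vapply(cigar, function(cg) {
    ops <- cigar_ops(cg)
    sum(ops$len[ops$op == "I"])
  }, numeric(1), USE.NAMES = FALSE)
  as.integer(mism + dels + ins)
}

validate_alignments <- function(aln, refs) {
  if (!nrow(aln)) return(invisible(TRUE))
  unknown <- setdiff(unique(aln$contig_id), names(refs))
  if (length(unknown))
    stop("alignment references unknown contig(s): ",
         paste(unknown, collapse = ", "))
  span <- cigar_ref_length(aln$cigar)
  lens <- nchar(refs)[aln$contig_id]
  if (any(aln$start + span > lens))
    stop("alignment extends beyond contig end for read(s): ",
         paste(utils::head(aln$read_id[aln$start + span > lens], 5),
               collapse = ", "))
  qlen <- cigar_query_length(aln$cigar)
  if (any(qlen != aln$read_len))
    stop("CIGAR query length disagrees with sequence length for read(s): ",
         paste(utils::head(aln$read_id[qlen != aln$read_len], 5),
               collapse = ", "))
  invisible(TRUE)
}

#' Write alignments to a SAM file
#'
#' Emits the minimal SAM dialect the package consumes: `@HD`/`@SQ` header,
#' mandatory fields, and the `NM` tag. Internal 0-based starts become
#' 1-based `POS` at this boundary.
#'
#' @param aln alignment data.frame (see [read_alignments()]).
#' @param refs named character vector of reference sequences (for `@SQ`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(aln, refs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(refs), nchar(refs)), con)
  if (nrow(aln)) {
    flag <- ifelse(aln$mapped, ifelse(aln$strand == "-", 16L, 0L), 4L)
    lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*\tNM:i:%d",
                     aln$read_id, flag,
                     ifelse(aln$mapped, aln$contig_id, "*"),
                     ifelse(aln$mapped, aln$start + 1L, 0L),
                     ifelse(aln$mapped, 60L, 0L),
                     ifelse(aln$mapped, aln$cigar, "*"),
                     aln$seq,
                     ifelse(aln$mapped, aln$nm, 0L))
    writeLines(lines, con)
  }
  invisible(path)
}
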