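#' Read contigs from a FASTA file
#'
#' Sequences are uppercased and validated against the DNA alphabet
#' \{A, C, G, T, N\}. Duplicate headers and empty records are errors.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences; names are contig ids
#'   (first whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate contig id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L))
    stop("empty sequence record: ", paste(ids[nchar(seqs) == 0L], collapse = ", "))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-ACGTN characters in sequence(s): ", paste(ids[bad], collapse = ", "))
  stats::setNames(seqs, ids)
}

#' Write contigs to a FASTA file
#'
#' @param contigs named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(contigs, path, width = 70L) {
  stopifnot(is.character(contigs), !is.null(names(contigs)))
  if (anyDuplicated(names(contigs)))
    stop("duplicate contig id: ",
         paste(unique(names(contigs)[duplicated(names(contigs))]), collapse = ", "))
  set <- Biostrings::DNAStringSet(contigs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Write reads to a FASTQ file
#'
#' Qualities are constant placeholders (the downstream statistics are not
#' quality-aware); they are carried for format compliance only.
#'
#' @param reads named character vector of read sequences.
#' @param path output path.
#' @param qual_char quality character to fill with.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, qual_char = "I") {
  stopifnot(is.character(reads))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(reads)) {
    quals <- vapply(nchar(reads), function(n) strrep(qual_char, n), character(1))
    writeLines(paste0("@", names(reads), "\n", reads, "\n+\n", quals), con)
  }
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path path to a FASTQ file.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(set), sub("\\s.*$", "", names(set)))
}
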