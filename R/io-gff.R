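#' Read gene models from a GFF3 file
#'
#' Only `CDS` and `gene` rows are consumed. GFF's 1-based closed intervals
#' become the package-wide 0-based half-open convention at this boundary.
#' Coding genes whose length is not divisible by 3 are excluded with a
#' warning (they cannot enter codon-aware statistics).
#'
#' @param path path to a GFF3 file.
#' @param refs optional named character vector of reference sequences; if
#'   given, intervals are checked against contig bounds.
#' @return data.frame with columns `gene_id`, `contig_id`, `start`, `end`
#'   (0-based half-open), `strand`, `frame`.
#' @export
read_gff <- function(path, refs = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% c("CDS", "gene")]
  ids <- gr$ID
  if (is.null(ids)) ids <- rep(NA_character_, length(gr))
  ids[is.na(ids)] <- paste0("gene_", seq_len(sum(is.na(ids))))
  genes <- data.frame(
    gene_id = ids,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    frame = 0L,
    stringsAsFactors = FALSE)
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  if (any(genes$end < genes$start))
    stop("gene with end < start: ",
         paste(genes$gene_id[genes$end < genes$start], collapse = ", "))
  if (!is.null(refs)) {
    lens <- nchar(refs)[genes$contig_id]
    if (any(is.na(lens)))
      stop("gene on unknown contig: ",
           paste(genes$gene_id[is.na(lens)], collapse = ", "))
    if (any(genes$end > lens))
      stop("gene interval out of contig bounds: ",
           paste(genes$gene_id[genes$end > lens], collapse = ", "))
  }
  bad <- (genes$end - genes$start) %% 3L != 0L
  if (any(bad)) {
    warning("excluding gene(s) with length not divisible by 3: ",
            paste(genes$gene_id[bad], collapse = ", "))
    genes <- genes[!bad, , drop = FALSE]
  }
  rownames(genes) <- NULL
  genes
}

#' Write gene models to a GFF3 file
#'
#' Inverse of [read_gff()]: internal 0-based half-open intervals become
#' 1-based closed GFF coordinates.
#'
#' @param genes gene data.frame (see [read_gff()]).
#' @param path output path.
#' @param type feature type to emit (default `"CDS"`).
#' @return `path`, invisibly.
#' @export
write_gff <- function(genes, path, type = "CDS") {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig_id,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand)
  gr$type <- type
  gr$ID <- genes$gene_id
  gr$phase <- genes$frame
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
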