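#' Write sequences to FASTA
#'
#' 60-column wrapped FASTA. Sequences may be a named character vector or a
#' `DNAStringSet`/`AAStringSet`; optional descriptions are appended to the
#' header line after the identifier.
#'
#' @param seqs named character vector (or XStringSet) of sequences.
#' @param path output file.
#' @param desc optional character vector of header descriptions, recycled
#'   against `seqs`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, desc = NULL) {
  if (is(seqs, "XStringSet")) seqs <- setNames(as.character(seqs), names(seqs))
  nm <- names(seqs)
  if (!is.null(desc)) nm <- paste(nm, desc)
  x <- Biostrings::BStringSet(unname(seqs))
  names(x) <- nm
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}

#' Read FASTA as a named character vector
#'
#' Names are the full header lines (identifier plus description).
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), names(x))
}

fasta_ids <- function(headers) sub("\\s.*$", "", headers)

## build a GRanges from a 0-based half-open interval data.frame and export
## as GFF3 via rtracklayer; extra columns become GFF3 attributes
write_gff3 <- function(df, path, type, source = "beanTE",
                       seqlengths = NULL) {
  if (nrow(df) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = df$seq_id,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
  meta <- df[, setdiff(names(df), c("seq_id", "start", "end", "strand")),
             drop = FALSE]
  S4Vectors::mcols(gr) <- cbind(
    S4Vectors::DataFrame(source = source, type = type),
    S4Vectors::DataFrame(meta)
  )
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlengths(gr) <- seqlengths[GenomeInfoDb::seqlevels(gr)]
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a data frame as TSV
#'
#' @param df data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
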