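# File-format interfaces.  Sequence IO goes through Biostrings, BED IO
# through rtracklayer; tables are plain TSV.

#' Read / write FASTA
#'
#' @param path File path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read / write FASTQ reads
#'
#' @param path File path.
#' @return `read_fastq`: read data.frame (id, seq, qual).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x), seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}

#' @rdname read_fastq
#' @param reads Read data.frame with id, seq and qual columns.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  qual <- if ("qual" %in% names(reads)) reads$qual else
    strrep("I", nchar(reads$seq))
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
  invisible(path)
}

#' Read / write BED intervals
#'
#' BED files are 0-based half-open, matching the internal convention; the
#' name column carries the feature class for gene-model files.
#'
#' @param path File path.
#' @return `read_bed`: data.frame chrom, start, end, name, strand.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             name = if (!is.null(gr$name)) gr$name else NA_character_,
             strand = as.character(BiocGenerics::strand(gr)),
             stringsAsFactors = FALSE)
}

#' @rdname read_bed
#' @param df data.frame with chrom, start, end and optionally name, strand.
#' @export
write_bed <- function(df, path) {
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end),
                               strand = strand)
  if ("name" %in% names(df)) gr$name <- df$name
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read / write a repeat catalog as TSV
#'
#' The written table carries both coordinate conventions: `start`/`end`
#' (0-based half-open) and `start1`/`end1` (1-based inclusive, the
#' convention of printed locus tables).
#'
#' @param catalog Repeat catalog data.frame.
#' @param path File path.
#' @export
write_catalog <- function(catalog, path) {
  out <- catalog
  one <- coords_zero_to_one(out$start, out$end)
  out$start1 <- one$start; out$end1 <- one$end
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$start1 <- NULL; df$end1 <- NULL
  df
}

#' Read / write plain TSV tables
#'
#' @param path File path.
#' @param df data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_tsv
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
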