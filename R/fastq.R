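# Thin FASTQ I/O layer over Biostrings. Reads are handled in memory as
# plain data frames (id, seq, qual) throughout the package; these helpers
# are the only place file formats are touched.

#' Read a FASTQ file into a data frame
#'
#' @param path FASTQ file (Phred+33), optionally gzipped.
#' @return data.frame with columns `id` (full header line), `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x),
             seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}

#' Write a data frame of reads to FASTQ
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param path output path (`.gz` suffix gzips).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual),
    compress = grepl("\\.gz$", path))
  invisible(path)
}
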