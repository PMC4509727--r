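# Dual-index demultiplexing: assign each read pair to a sample by matching
# its two 8-nt index reads against a sample sheet. The default policy is
# perfect matching (max_mismatch = 0), as applied by the instrument
# software; relaxed matching resolves any ambiguity conservatively to
# "undetermined".

#' Validate a sample sheet
#'
#' @param x data.frame with columns `sample_id`, `fwd_index`, `rev_index`
#'   (8-nt ACGT strings). Sample ids and index pairs must be unique.
#' @return the validated sheet with class `SampleSheet`.
#' @export
samplesheet <- function(x) {
  need <- c("sample_id", "fwd_index", "rev_index")
  if (!all(need %in% names(x)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  x <- as.data.frame(x, stringsAsFactors = FALSE)[need]
  x$sample_id <- as.character(x$sample_id)
  if (nrow(x) == 0L) stop("sample sheet has no rows")
  bad <- which(!grepl("^[ACGT]{8}$", x$fwd_index) |
               !grepl("^[ACGT]{8}$", x$rev_index))
  if (length(bad))
    stop("malformed 8-nt index in sample sheet row(s): ",
         paste(bad, collapse = ", "))
  dup <- which(duplicated(x$sample_id))
  if (length(dup))
    stop("duplicate sample_id in sample sheet row(s): ",
         paste(dup, collapse = ", "))
  key <- paste(x$fwd_index, x$rev_index)
  dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
  if (any(duplicated(key)))
    stop("duplicate index pair in sample sheet row(s): ",
         paste(dup, collapse = ", "))
  rownames(x) <- NULL
  class(x) <- c("SampleSheet", "data.frame")
  x
}

#' Read a sample sheet from CSV
#'
#' @param path CSV file with header `sample_id,fwd_index,rev_index`.
#' @return a `SampleSheet`.
#' @export
parse_samplesheet <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) stop("sample sheet file is empty: ", path)
  samplesheet(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Demultiplex indexed read pairs against a sample sheet
#'
#' A pair is assigned to a sample iff the Hamming distances of both index
#' reads to that sample's indices are at most `max_mismatch` and the
#' assignment is unique; unmatched or ambiguous pairs go to
#' `"undetermined"`. Ambiguous bases (N) in index reads count as
#' mismatches.
#'
#' @param reads data.frame with (at least) columns `i1_seq` and `i2_seq`
#'   holding the 8-nt index reads; typically also `id`, `r1_seq`, `r1_qual`,
#'   `r2_seq`, `r2_qual`.
#' @param sheet a `SampleSheet`.
#' @param max_mismatch maximum Hamming distance per index (default 0:
#'   perfect matches only).
#' @return object of class `DemuxResult`: list with `assignments` (character
#'   vector, sample id or `"undetermined"` per read), `counts` (named
#'   integer, sheet order), `undetermined` and `total`. The counts always
#'   satisfy `sum(counts) + undetermined == total`.
#' @export
demultiplex <- function(reads, sheet, max_mismatch = 0L) {
  stopifnot(is.data.frame(reads), max_mismatch >= 0L)
  if (!inherits(sheet, "SampleSheet")) sheet <- samplesheet(sheet)
  i1 <- toupper(reads$i1_seq)
  i2 <- toupper(reads$i2_seq)
  n <- length(i1)
  if (n && (any(nchar(i1) != 8L) || any(nchar(i2) != 8L)))
    stop("index read length does not match the 8-nt sheet indices")
  if (n == 0L) {
    assign <- character(0)
  } else if (max_mismatch == 0L) {
    hit <- match(paste(i1, i2), paste(sheet$fwd_index, sheet$rev_index))
    assign <- ifelse(is.na(hit), "undetermined", sheet$sample_id[hit])
  } else {
    m1 <- matrix(unlist(strsplit(i1, ""), use.names = FALSE), ncol = 8L,
                 byrow = TRUE)
    m2 <- matrix(unlist(strsplit(i2, ""), use.names = FALSE), ncol = 8L,
                 byrow = TRUE)
    n_hits <- integer(n)
    last_hit <- integer(n)
    for (s in seq_len(nrow(sheet))) {
      f <- strsplit(sheet$fwd_index[s], "")[[1]]
      r <- strsplit(sheet$rev_index[s], "")[[1]]
      d1 <- rowSums(m1 != matrix(f, n, 8L, byrow = TRUE))
      d2 <- rowSums(m2 != matrix(r, n, 8L, byrow = TRUE))
      ok <- d1 <= max_mismatch & d2 <= max_mismatch
      n_hits <- n_hits + ok
      last_hit[ok] <- s
    }
    assign <- ifelse(n_hits == 1L, sheet$sample_id[pmax(last_hit, 1L)],
                     "undetermined")
  }
  counts <- table(factor(assign, levels = sheet$sample_id))
  counts <- stats::setNames(as.integer(counts), sheet$sample_id)
  structure(
    list(assignments = assign,
         counts = counts,
         undetermined = sum(assign == "undetermined"),
         total = n),
    class = "DemuxResult")
}

#' @export
print.DemuxResult <- function(x, ...) {
  cat(sprintf("Demultiplexed %d read pairs into %d samples (%d undetermined, %.1f%%)\n",
              x$total, length(x$counts), x$undetermined,
              if (x$total) 100 * x$undetermined / x$total else 0))
  invisible(x)
}

# pull "<i1>+<i2>" tokens out of Casava-style header comments
.index_from_headers <- function(ids) {
  m <- regmatches(ids, regexpr("[ACGTN]+\\+[ACGTN]+$", ids))
  if (length(m) != length(ids))
    stop("could not find an '<i1>+<i2>' index token in every read header")
  parts <- strsplit(m, "+", fixed = TRUE)
  list(i1 = vapply(parts, `[`, character(1), 1L),
       i2 = vapply(parts, `[`, character(1), 2L))
}

#' Demultiplex FASTQ files into per-sample files
#'
#' Index sources are either separate I1/I2 FASTQ files or, when `i1`/`i2`
#' are `NULL`, a Casava-style `<i1>+<i2>` token at the end of the R1 header
#' comment (auto-detected).
#'
#' @param r1,r2 paths to the paired read FASTQ files.
#' @param i1,i2 paths to the index read FASTQ files, or `NULL`.
#' @param sheet a `SampleSheet` or path to a sample-sheet CSV.
#' @param outdir output directory; per-sample files are named
#'   `<sample_id>_R1.fastq` / `<sample_id>_R2.fastq`, with a
#'   `demux_stats.tsv` summary.
#' @param max_mismatch see [demultiplex()].
#' @return the `DemuxResult`, invisibly.
#' @export
demux_fastq <- function(r1, r2, i1 = NULL, i2 = NULL, sheet, outdir,
                        max_mismatch = 0L) {
  if (is.character(sheet) && length(sheet) == 1L && file.exists(sheet))
    sheet <- parse_samplesheet(sheet)
  fq1 <- read_fastq(r1)
  fq2 <- read_fastq(r2)
  if (nrow(fq1) != nrow(fq2)) stop("R1 and R2 differ in read count")
  if (is.null(i1) != is.null(i2))
    stop("provide both index files or neither")
  if (is.null(i1)) {
    idx <- .index_from_headers(fq1$id)
  } else {
    idx <- list(i1 = read_fastq(i1)$seq, i2 = read_fastq(i2)$seq)
  }
  reads <- data.frame(id = fq1$id,
                      r1_seq = fq1$seq, r1_qual = fq1$qual,
                      r2_seq = fq2$seq, r2_qual = fq2$qual,
                      i1_seq = idx$i1, i2_seq = idx$i2,
                      stringsAsFactors = FALSE)
  res <- demultiplex(reads, sheet, max_mismatch)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (s in sheet$sample_id) {
    sel <- res$assignments == s
    write_fastq(data.frame(id = reads$id[sel], seq = reads$r1_seq[sel],
                           qual = reads$r1_qual[sel]),
                file.path(outdir, paste0(s, "_R1.fastq")))
    write_fastq(data.frame(id = reads$id[sel], seq = reads$r2_seq[sel],
                           qual = reads$r2_qual[sel]),
                file.path(outdir, paste0(s, "_R2.fastq")))
  }
  stats <- data.frame(sample_id = c(names(res$counts), "undetermined"),
                      reads = c(res$counts, res$undetermined))
  utils::write.table(stats, file.path(outdir, "demux_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(res)
}
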