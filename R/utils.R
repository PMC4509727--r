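# Shared low-level helpers: rank ladder, DNA string utilities, Phred
# conversion, k-mer integer encoding.

#' The seven canonical taxonomic ranks
#'
#' Rank ladder used throughout the package, from kingdom down to species.
#' All lineages, reference databases and classifier outputs use exactly
#' these seven levels.
#'
#' @export
SEVEN_RANKS <- c("kingdom", "phylum", "class", "order", "family",
                 "genus", "species")

DNA_BASES <- c("A", "C", "G", "T")

# placeholder prefix for ranks that could not be named
UNCLASSIFIED_PREFIX <- "unclassified_"

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (IUPAC letters accepted).
#' @return character vector of base-wise reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# reverse plain strings (quality strings accompany reverse-complemented reads)
str_reverse <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverse(Biostrings::BStringSet(x)))
}

qual_to_phred <- function(qual) utf8ToInt(qual) - 33L

phred_to_qual <- function(phred) {
  intToUtf8(pmin(pmax(as.integer(round(phred)), 0L), 41L) + 33L)
}

assert_dna <- function(x, what, len = NULL, allow_empty = FALSE) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(sprintf("%s must be a single DNA string", what), call. = FALSE)
  if (!allow_empty && nchar(x) == 0L)
    stop(sprintf("%s must be non-empty", what), call. = FALSE)
  if (!grepl("^[ACGT]*$", x))
    stop(sprintf("%s contains non-ACGT characters", what), call. = FALSE)
  if (!is.null(len) && nchar(x) != len)
    stop(sprintf("%s must be exactly %d nt (got %d)", what, len, nchar(x)),
         call. = FALSE)
  invisible(x)
}

# A -> 0, C -> 1, G -> 2, T -> 3; anything else NA
.BASE_CODE <- local({
  v <- rep(NA_integer_, 256L)
  v[utf8ToInt("A") + 1L] <- 0L
  v[utf8ToInt("C") + 1L] <- 1L
  v[utf8ToInt("G") + 1L] <- 2L
  v[utf8ToInt("T") + 1L] <- 3L
  v
})

# Distinct k-mers of a sequence as base-4 integer codes (numeric; exact for
# k <= 26). Windows containing an ambiguous base are dropped.
kmer_codes <- function(seq, k) {
  code <- .BASE_CODE[utf8ToInt(seq) + 1L]
  n <- length(code)
  if (n < k) return(numeric(0))
  nw <- n - k + 1L
  w <- numeric(nw)
  ok <- rep(TRUE, nw)
  for (j in seq_len(k)) {
    cj <- code[j:(nw + j - 1L)]
    bad <- is.na(cj)
    if (any(bad)) {
      ok <- ok & !bad
      cj[bad] <- 0L
    }
    w <- w * 4 + cj
  }
  unique(w[ok])
}

# Deterministic 31-bit polynomial string hash, used to derive independent
# per-read RNG streams so results do not depend on read order.
str_hash <- function(x) {
  vapply(x, function(s) {
    h <- 0
    for (ci in utf8ToInt(s)) h <- (h * 31 + ci) %% 2147483629
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}
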