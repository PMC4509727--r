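# Paired-end merging and quality filtering. Reads are merged by scanning
# all candidate overlap lengths between the forward read and the
# reverse-complemented reverse read; amplicons then pass a three-rule
# quality filter (length >= 150 nt, mean Phred >= Q20, no ambiguous bases).

#' Merge parameters
#'
#' Defaults follow the conventional defaults of overlap-joining tools:
#' a minimum overlap of 6 nt and at most 8% mismatching positions within
#' the overlap.
#'
#' @param min_overlap smallest overlap length considered (nt, >= 1).
#' @param max_mismatch_frac maximum fraction of mismatching positions in
#'   the chosen overlap.
#' @return a `MergeParams` list.
#' @export
merge_params <- function(min_overlap = 6L, max_mismatch_frac = 0.08) {
  stopifnot(min_overlap >= 1L, max_mismatch_frac >= 0,
            max_mismatch_frac <= 1)
  structure(list(min_overlap = as.integer(min_overlap),
                 max_mismatch_frac = max_mismatch_frac),
            class = "MergeParams")
}

#' Quality-filter parameters
#'
#' Defaults implement the standard post-merge amplicon filter: discard
#' reads shorter than 150 nt, with mean Phred below Q20, or containing any
#' ambiguous base.
#'
#' @param min_len minimum merged length (nt).
#' @param min_mean_q minimum mean Phred quality.
#' @param max_ambiguous maximum number of non-ACGT bases.
#' @return a `FilterParams` list.
#' @export
filter_params <- function(min_len = 150L, min_mean_q = 20, max_ambiguous = 0L) {
  stopifnot(min_len >= 1L, min_mean_q >= 0, max_ambiguous >= 0L)
  structure(list(min_len = as.integer(min_len), min_mean_q = min_mean_q,
                 max_ambiguous = as.integer(max_ambiguous)),
            class = "FilterParams")
}

# core merge on the forward read and the already reverse-complemented
# reverse read (qualities reversed accordingly)
.merge_core <- function(s1, q1, s2, q2, params, id = NA_character_) {
  a <- charToRaw(s1)
  b <- charToRaw(s2)
  qa <- utf8ToInt(q1) - 33L
  qb <- utf8ToInt(q2) - 33L
  n1 <- length(a)
  n2 <- length(b)
  l_max <- min(n1, n2)
  if (params$min_overlap > l_max)
    return(list(status = "failed", id = id, reason = "no_overlap"))
  ls <- params$min_overlap:l_max
  mm <- integer(length(ls))
  for (i in seq_along(ls)) {
    l <- ls[i]
    mm[i] <- sum(a[(n1 - l + 1L):n1] != b[1:l])
  }
  frac <- mm / ls
  best <- order(frac, -ls)[1L]  # min mismatch fraction, ties -> longest
  if (frac[best] > params$max_mismatch_frac)
    return(list(status = "failed", id = id, reason = "too_many_mismatches"))
  l <- ls[best]
  ia <- (n1 - l + 1L):n1
  ov_a <- a[ia]; ov_b <- b[1:l]
  oq_a <- qa[ia]; oq_b <- qb[1:l]
  cons <- ov_a
  consq <- pmax(oq_a, oq_b)         # agreement keeps the better quality
  dis <- ov_a != ov_b
  if (any(dis)) {
    take_b <- dis & (oq_b > oq_a)   # disagreement keeps the better base
    cons[take_b] <- ov_b[take_b]
    consq[dis] <- pmax(abs(oq_a[dis] - oq_b[dis]), 2L)
  }
  consq <- pmin(consq, 41L)
  tail_b <- if (l < n2) b[(l + 1L):n2] else raw(0)
  tail_q <- if (l < n2) qb[(l + 1L):n2] else integer(0)
  list(status = "merged",
       id = id,
       seq = rawToChar(c(a[seq_len(n1 - l)], cons, tail_b)),
       qual = phred_to_qual(c(qa[seq_len(n1 - l)], consq, tail_q)),
       overlap_len = l,
       overlap_mismatches = mm[best])
}

#' Merge one read pair by overlap
#'
#' The reverse read is reverse-complemented (qualities reversed); among all
#' overlap lengths `L >= min_overlap` the candidate with the smallest
#' mismatch fraction is chosen (ties resolved towards the longer overlap)
#' and accepted iff that fraction is at most `max_mismatch_frac`. The
#' merged length is `len(r1) + len(r2) - L`. In the overlap, agreeing
#' positions keep the higher of the two qualities; disagreeing positions
#' keep the higher-quality base with quality `|q1 - q2|` (floored at 2);
#' merged qualities are capped at Q41.
#'
#' @param r1_seq,r1_qual forward read sequence and Phred+33 quality string.
#' @param r2_seq,r2_qual reverse read (as sequenced, i.e. not yet
#'   reverse-complemented).
#' @param params a `MergeParams` object.
#' @param id optional read id carried through.
#' @return list with `status = "merged"` and fields `seq`, `qual`,
#'   `overlap_len`, `overlap_mismatches`; or `status = "failed"` with
#'   `reason` `"no_overlap"` (no candidate overlap of at least
#'   `min_overlap`) or `"too_many_mismatches"`.
#' @export
merge_pair <- function(r1_seq, r1_qual, r2_seq, r2_qual,
                       params = merge_params(), id = NA_character_) {
  stopifnot(nchar(r1_seq) > 0L, nchar(r2_seq) > 0L,
            nchar(r1_seq) == nchar(r1_qual),
            nchar(r2_seq) == nchar(r2_qual))
  .merge_core(r1_seq, r1_qual, revcomp(r2_seq), str_reverse(r2_qual),
              params, id)
}

#' Merge a table of read pairs
#'
#' @param reads data.frame with columns `id`, `r1_seq`, `r1_qual`,
#'   `r2_seq`, `r2_qual`.
#' @param params a `MergeParams` object.
#' @return list with `merged` (data.frame `id`, `seq`, `qual`,
#'   `overlap_len`, `overlap_mismatches`) and `failed` (data.frame `id`,
#'   `reason`).
#' @export
merge_pairs <- function(reads, params = merge_params()) {
  n <- nrow(reads)
  if (n == 0L)
    return(list(merged = data.frame(id = character(0), seq = character(0),
                                    qual = character(0),
                                    overlap_len = integer(0),
                                    overlap_mismatches = integer(0)),
                failed = data.frame(id = character(0),
                                    reason = character(0))))
  rc2 <- revcomp(reads$r2_seq)
  q2r <- str_reverse(reads$r2_qual)
  out <- vector("list", n)
  for (i in seq_len(n))
    out[[i]] <- .merge_core(reads$r1_seq[i], reads$r1_qual[i], rc2[i],
                            q2r[i], params, reads$id[i])
  ok <- vapply(out, function(x) x$status == "merged", logical(1))
  merged <- data.frame(
    id = vapply(out[ok], `[[`, character(1), "id"),
    seq = vapply(out[ok], `[[`, character(1), "seq"),
    qual = vapply(out[ok], `[[`, character(1), "qual"),
    overlap_len = vapply(out[ok], `[[`, integer(1), "overlap_len"),
    overlap_mismatches = vapply(out[ok], `[[`, integer(1),
                                "overlap_mismatches"),
    stringsAsFactors = FALSE)
  failed <- data.frame(
    id = vapply(out[!ok], `[[`, character(1), "id"),
    reason = vapply(out[!ok], `[[`, character(1), "reason"),
    stringsAsFactors = FALSE)
  list(merged = merged, failed = failed)
}

#' Quality-filter a single read
#'
#' Rules are checked in order; the first failing rule is the reported
#' reason: `"short"` (length < `min_len`), `"low_quality"` (mean Phred
#' < `min_mean_q`), `"ambiguous"` (more than `max_ambiguous` non-ACGT
#' bases).
#'
#' @param seq,qual sequence and Phred+33 quality string.
#' @param params a `FilterParams` object.
#' @return list with `keep` (logical) and `reason` (`NA` if kept).
#' @export
quality_filter <- function(seq, qual, params = filter_params()) {
  if (nchar(seq) < params$min_len)
    return(list(keep = FALSE, reason = "short"))
  if (mean(qual_to_phred(qual)) < params$min_mean_q)
    return(list(keep = FALSE, reason = "low_quality"))
  if (nchar(gsub("[ACGT]", "", seq)) > params$max_ambiguous)
    return(list(keep = FALSE, reason = "ambiguous"))
  list(keep = TRUE, reason = NA_character_)
}

#' Quality-filter a table of reads
#'
#' Vectorised [quality_filter()].
#'
#' @param reads data.frame with columns `seq` and `qual`.
#' @param params a `FilterParams` object.
#' @return `reads` with added logical column `keep` and character column
#'   `reason`.
#' @export
filter_reads <- function(reads, params = filter_params()) {
  n <- nrow(reads)
  if (n == 0L) {
    reads$keep <- logical(0)
    reads$reason <- character(0)
    return(reads)
  }
  len <- nchar(reads$seq)
  meanq <- vapply(reads$qual, function(q) mean(utf8ToInt(q)), numeric(1),
                  USE.NAMES = FALSE) - 33
  amb <- nchar(gsub("[ACGT]", "", reads$seq))
  reason <- rep(NA_character_, n)
  reason[amb > params$max_ambiguous] <- "ambiguous"
  reason[meanq < params$min_mean_q] <- "low_quality"
  reason[len < params$min_len] <- "short"   # first rule wins
  reads$keep <- is.na(reason)
  reads$reason <- reason
  reads
}

#' Per-sample read-preparation report
#'
#' @param raw_count,merged_count,kept_count read counts after each stage;
#'   must satisfy `kept <= merged <= raw`.
#' @param sample_id optional label.
#' @return one-row data.frame with the counts plus `merge_rate`
#'   (merged/raw) and `keep_rate` (kept/merged); degenerate zero
#'   denominators give rate 0 with a warning.
#' @export
prep_report <- function(raw_count, merged_count, kept_count,
                        sample_id = NA_character_) {
  stopifnot(raw_count >= 0L, merged_count >= 0L, kept_count >= 0L)
  if (kept_count > merged_count)
    stop("kept_count exceeds merged_count")
  if (merged_count > raw_count)
    stop("merged_count exceeds raw_count")
  rate <- function(num, den) {
    if (den == 0L) {
      warning("zero-count denominator; rate reported as 0")
      0
    } else num / den
  }
  data.frame(sample_id = sample_id,
             raw = raw_count, merged = merged_count, kept = kept_count,
             merge_rate = rate(merged_count, raw_count),
             keep_rate = rate(kept_count, merged_count),
             stringsAsFactors = FALSE)
}
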