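# Community-matrix aggregation: per-read assignments become a taxa x
# samples count table plus a lineage side-table, with the standard filters
# (rare taxa below 0.1% of sample reads; samples below 2,000 reads).

#' Aggregation and filtering parameters
#'
#' @param rare_frac per-sample relative-abundance threshold below which a
#'   taxon's count is zeroed (strict inequality; default 0.001, i.e. 0.1%).
#' @param min_sample_reads samples with fewer assigned reads are dropped
#'   (default 2000, the minimum saturation depth).
#' @return an `AggregateParams` list.
#' @export
aggregate_params <- function(rare_frac = 0.001, min_sample_reads = 2000L) {
  stopifnot(rare_frac >= 0, rare_frac < 1, min_sample_reads >= 0L)
  structure(list(rare_frac = rare_frac,
                 min_sample_reads = as.integer(min_sample_reads)),
            class = "AggregateParams")
}

# deepest non-placeholder name of each lineage row
.deepest_named <- function(lin) {
  lab <- lin[, 1L]
  for (i in 2:7) {
    real <- !startsWith(lin[, i], UNCLASSIFIED_PREFIX)
    lab[real] <- lin[real, i]
  }
  lab
}

#' Aggregate per-sample assignment tables into a community matrix
#'
#' Taxa are identified by their full seven-rank lineage (avoiding homonym
#' collisions) and labelled by the deepest named rank; two distinct
#' lineages sharing a label is an error. Cell (t, s) counts the reads of
#' sample s assigned to taxon t; column sums equal the per-sample assigned
#' read counts.
#'
#' @param tables named list (sample id -> data.frame with the seven rank
#'   columns, one row per assigned read), e.g. from [apply_cutoff()].
#' @return object of class `CommunityMatrix`: list with `counts` (integer
#'   matrix, taxa x samples) and `lineage` (data.frame `taxon` + seven
#'   ranks).
#' @export
aggregate_assignments <- function(tables) {
  stopifnot(is.list(tables), !is.null(names(tables)),
            all(nzchar(names(tables))))
  samples <- names(tables)
  lin_all <- do.call(rbind, lapply(tables, function(t)
    as.data.frame(t, stringsAsFactors = FALSE)[SEVEN_RANKS]))
  key <- do.call(paste, c(lin_all, sep = "\r"))
  sample_of <- rep(samples, vapply(tables, nrow, integer(1)))
  ukey <- sort(unique(key), method = "radix")
  lineage <- as.matrix(lin_all[match(ukey, key), , drop = FALSE])
  label <- .deepest_named(lineage)
  dup <- duplicated(label)
  if (any(dup)) {
    i <- which(label == label[which(dup)[1L]])
    stop("conflicting lineages for taxon name '", label[i[1L]], "': ",
         paste(gsub("\r", ";", ukey[i]), collapse = " vs "))
  }
  counts <- table(factor(key, levels = ukey),
                  factor(sample_of, levels = samples))
  counts <- matrix(as.integer(counts), nrow = length(ukey),
                   dimnames = list(label, samples))
  lineage <- cbind(data.frame(taxon = label, stringsAsFactors = FALSE),
                   as.data.frame(lineage, stringsAsFactors = FALSE))
  rownames(lineage) <- NULL
  structure(list(counts = counts, lineage = lineage),
            class = "CommunityMatrix")
}

#' @export
print.CommunityMatrix <- function(x, ...) {
  cat(sprintf("CommunityMatrix: %d taxa x %d samples, %d reads\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Zero out rare taxa per sample
#'
#' In each sample, entries whose share of the sample's total is strictly
#' below `rare_frac` are set to zero (a taxon at exactly the threshold is
#' kept); rows that become all-zero are dropped. The rule is evaluated in
#' a single pass against the original column totals. Zero-count columns
#' are left unchanged with a warning.
#'
#' @param cm a `CommunityMatrix`.
#' @param params an `AggregateParams` object.
#' @return the filtered `CommunityMatrix`.
#' @export
filter_rare <- function(cm, params = aggregate_params()) {
  m <- cm$counts
  cs <- colSums(m)
  if (any(cs == 0))
    warning("zero-count column(s) left unchanged: ",
            paste(colnames(m)[cs == 0], collapse = ", "))
  ok <- cs > 0
  if (any(ok)) {
    frac <- sweep(m[, ok, drop = FALSE], 2L, cs[ok], "/")
    sub <- m[, ok, drop = FALSE]
    sub[frac < params$rare_frac] <- 0L
    m[, ok] <- sub
  }
  keep <- rowSums(m) > 0
  structure(list(counts = m[keep, , drop = FALSE],
                 lineage = cm$lineage[keep, , drop = FALSE]),
            class = "CommunityMatrix")
}

#' Drop samples below the minimum sequencing depth
#'
#' @param cm a `CommunityMatrix`.
#' @param params an `AggregateParams` object; columns with fewer than
#'   `min_sample_reads` reads are removed.
#' @return list with `community` (the reduced `CommunityMatrix`) and
#'   `dropped` (character vector of removed sample ids).
#' @export
drop_low_depth_samples <- function(cm, params = aggregate_params()) {
  cs <- colSums(cm$counts)
  keep <- cs >= params$min_sample_reads
  list(community = structure(list(counts = cm$counts[, keep, drop = FALSE],
                                  lineage = cm$lineage),
                             class = "CommunityMatrix"),
       dropped = colnames(cm$counts)[!keep])
}

#' Relative abundances
#'
#' @param cm a `CommunityMatrix` (or a plain count matrix); every column
#'   sum must be positive.
#' @return numeric matrix whose columns each sum to 1.
#' @export
relative_abundance <- function(cm) {
  m <- if (inherits(cm, "CommunityMatrix")) cm$counts else cm
  cs <- colSums(m)
  if (any(cs == 0))
    stop("zero-count column(s): ", paste(colnames(m)[cs == 0],
                                         collapse = ", "))
  sweep(m, 2L, cs, "/")
}

#' Most abundant taxa at a rank
#'
#' Counts are summed at the requested rank over a group of samples and
#' converted to shares of the group total; the list is sorted by
#' descending share (ties alphabetical) and entries beyond `top_n` are
#' folded into `"other"`. Shares including `"other"` sum to 1.
#'
#' @param cm a `CommunityMatrix`.
#' @param rank one of [SEVEN_RANKS].
#' @param samples sample ids forming the group (default: all).
#' @param top_n number of named entries to keep.
#' @return data.frame with columns `name` and `share`.
#' @export
rank_summary <- function(cm, rank, samples = NULL, top_n = 10L) {
  rank <- match.arg(rank, SEVEN_RANKS)
  if (is.null(samples)) samples <- colnames(cm$counts)
  if (length(samples) == 0L) stop("empty sample group")
  missing <- setdiff(samples, colnames(cm$counts))
  if (length(missing))
    stop("unknown sample(s): ", paste(missing, collapse = ", "))
  sub <- cm$counts[, samples, drop = FALSE]
  tot <- rowSums(sub)
  by_rank <- tapply(tot, cm$lineage[[rank]], sum)
  grand <- sum(by_rank)
  if (grand == 0) stop("sample group has no reads")
  share <- as.numeric(by_rank) / grand
  name <- names(by_rank)
  ord <- order(-share, name, method = "radix")
  name <- name[ord]
  share <- share[ord]
  if (length(name) > top_n) {
    other <- sum(share[-seq_len(top_n)])
    name <- c(name[seq_len(top_n)], "other")
    share <- c(share[seq_len(top_n)], other)
  }
  data.frame(name = name, share = share, stringsAsFactors = FALSE)
}

#' Write a community matrix and its lineage table to TSV
#'
#' Emits `community_matrix.tsv` (rows = taxa, header = sample ids) and
#' `lineage.tsv` (taxon + the seven ranks), a format directly importable
#' into community-ecology software.
#'
#' @param cm a `CommunityMatrix`.
#' @param dir output directory.
#' @return invisibly, the two paths.
#' @export
write_community_matrix <- function(cm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mp <- file.path(dir, "community_matrix.tsv")
  lp <- file.path(dir, "lineage.tsv")
  df <- data.frame(taxon = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cm$lineage, lp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix = mp, lineage = lp))
}

#' Convert a community matrix to a phyloseq object
#'
#' @param cm a `CommunityMatrix`.
#' @return a `phyloseq` object (requires the phyloseq package).
#' @export
as_phyloseq <- function(cm) {
  if (!requireNamespace("phyloseq", quietly = TRUE))
    stop("the phyloseq package is required for as_phyloseq()")
  tax <- as.matrix(cm$lineage[SEVEN_RANKS])
  rownames(tax) <- cm$lineage$taxon
  phyloseq::phyloseq(
    phyloseq::otu_table(cm$counts, taxa_are_rows = TRUE),
    phyloseq::tax_table(tax))
}
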