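# Naive Bayes k-mer taxonomic classifier with bootstrap confidence, in the
# style of the RDP classifier: reads are scored against each reference leaf
# by the sum of log conditional probabilities of their distinct k-length
# words, and per-rank confidence is the fraction of word-subsampled
# bootstrap trials agreeing with the full-word winner at that rank.

#' Classifier parameters
#'
#' @param k word length (k-mer size); 1 <= k <= 12, default 8.
#' @param n_bootstrap number of bootstrap trials.
#' @param word_subsample_divisor each trial draws `floor(W / divisor)`
#'   words with replacement from the read's `W` distinct words (at least
#'   one); the canonical divisor is 8.
#' @param min_confidence ranks with bootstrap confidence below this are
#'   replaced by unclassified placeholders in [apply_cutoff()].
#' @param min_raw_score floor on the mean per-word log-likelihood of the
#'   winning leaf; reads scoring below it are truncated to kingdom. This is
#'   a score floor in the spirit of raw-score cutoffs used by other
#'   classifiers, but on the natural-log mean-likelihood scale of this
#'   model, and is therefore not numerically interchangeable with cutoffs
#'   of other tools. The default (-4) is far below the typical score of a
#'   read with a close reference and rejects only reads scoring no better
#'   than noise.
#' @param rng_seed seed for the bootstrap RNG used by [classify_sample()].
#' @return a `ClassifierParams` list.
#' @export
classifier_params <- function(k = 8L, n_bootstrap = 100L,
                              word_subsample_divisor = 8L,
                              min_confidence = 0.80,
                              min_raw_score = -4,
                              rng_seed = 1L) {
  stopifnot(k >= 1L, k <= 12L, n_bootstrap >= 1L,
            word_subsample_divisor >= 1L,
            min_confidence >= 0, min_confidence <= 1)
  structure(list(k = as.integer(k), n_bootstrap = as.integer(n_bootstrap),
                 word_subsample_divisor = as.integer(word_subsample_divisor),
                 min_confidence = min_confidence,
                 min_raw_score = min_raw_score,
                 rng_seed = as.integer(rng_seed)),
            class = "ClassifierParams")
}

#' Train the naive Bayes k-mer model
#'
#' Leaves are the species-level labels of the training lineages. With `N`
#' training sequences in total, `n(w)` of which contain word `w`, the word
#' prior is `P(w) = (n(w) + 0.5) / (N + 1)`; with `M` sequences in a leaf,
#' `m(w)` of which contain `w`, the leaf conditional is
#' `P(w|leaf) = (m(w) + P(w)) / (M + 1)`. Words are scored by presence,
#' not multiplicity. The model is independent of record order.
#'
#' @param db a `ReferenceDB`; every record must be at least `k` nt
#'   (shorter records are dropped with a warning).
#' @param params a `ClassifierParams` object.
#' @return object of class `KmerModel`.
#' @export
train_classifier <- function(db, params = classifier_params()) {
  if (!is.data.frame(db) || nrow(db) == 0L)
    stop("reference database is empty")
  k <- params$k
  codes <- lapply(db$sequence, kmer_codes, k = k)
  keep <- lengths(codes) > 0L
  if (any(!keep))
    warning(sprintf("%d record(s) shorter than k = %d dropped", sum(!keep),
                    k))
  if (!any(keep)) stop("no training record of length >= k")
  codes <- codes[keep]
  leaf <- db$species[keep]
  lin_all <- db[keep, SEVEN_RANKS, drop = FALSE]
  lin_key <- do.call(paste, c(lin_all, sep = ";"))
  if (any(tapply(lin_key, leaf, function(x) length(unique(x))) > 1L))
    stop("conflicting lineages for a single species leaf")
  leaves <- sort(unique(leaf), method = "radix")
  lidx <- match(leaf, leaves)
  lineage <- lin_all[match(leaves, leaf), , drop = FALSE]
  rownames(lineage) <- NULL
  n_leaf <- length(leaves)
  n_seq <- length(codes)
  words <- sort(unique(unlist(codes, use.names = FALSE)))
  n_word <- length(words)
  widx <- match(unlist(codes, use.names = FALSE), words)
  seq_of <- rep(seq_len(n_seq), lengths(codes))
  nw <- tabulate(widx, n_word)
  pw <- (nw + 0.5) / (n_seq + 1)
  m_leaf <- tabulate(lidx, n_leaf)
  mwl <- matrix(tabulate((lidx[seq_of] - 1L) * n_word + widx,
                         n_word * n_leaf),
                nrow = n_word, ncol = n_leaf)
  logp <- log(sweep(mwl + pw, 2L, m_leaf + 1, "/"))
  p0 <- 0.5 / (n_seq + 1)
  logp <- rbind(log(p0 / (m_leaf + 1)), logp)  # row 1: unseen words
  lookup <- NULL
  if (4^k <= 4^10) {
    lookup <- integer(4^k)
    lookup[words + 1] <- seq_len(n_word)
  }
  structure(list(k = k, leaves = leaves, lineage = lineage, logp = logp,
                 words = words, word_prior = pw, lookup = lookup,
                 M = m_leaf, N = n_seq, n_dropped = sum(!keep)),
            class = "KmerModel")
}

#' @export
print.KmerModel <- function(x, ...) {
  cat(sprintf("KmerModel: k = %d, %d leaves, %d words, %d training sequences\n",
              x$k, length(x$leaves), length(x$words), x$N))
  invisible(x)
}

# map a read's word codes to rows of model$logp (row 1 = unseen)
.word_rows <- function(codes, model) {
  if (!is.null(model$lookup)) {
    rows <- model$lookup[codes + 1]
  } else {
    rows <- match(codes, model$words, nomatch = 0L)
  }
  rows + 1L
}

#' Classify one sequence
#'
#' The winning leaf maximizes the summed log conditional probability of the
#' read's distinct k-mers (ties broken towards the lexicographically
#' smallest leaf id). Words not seen in training contribute their prior
#' mass. Bootstrap: `n_bootstrap` trials each draw `floor(W / divisor)`
#' words with replacement and record the winner; confidence at a rank is
#' the fraction of trials whose winner agrees with the full-word winner at
#' that rank, smoothed to be non-increasing from kingdom to species by a
#' cumulative minimum.
#'
#' @param seq sequence of length >= k.
#' @param model a `KmerModel`.
#' @param params a `ClassifierParams` object.
#' @return object of class `ClassificationResult`: list with `ranks` (named
#'   character over [SEVEN_RANKS]), `confidence` (named numeric), `leaf`,
#'   `raw_score` (mean per-word log-likelihood of the winner) and
#'   `n_words`.
#' @export
classify <- function(seq, model, params = classifier_params()) {
  if (nchar(seq) < model$k)
    stop(sprintf("sequence shorter than k = %d", model$k))
  codes <- kmer_codes(seq, model$k)
  n_w <- length(codes)
  if (n_w == 0L) stop("sequence contains no unambiguous k-mer")
  rows <- .word_rows(codes, model)
  sub <- model$logp[rows, , drop = FALSE]
  full <- colSums(sub)
  win <- which.max(full)
  raw <- full[[win]] / n_w
  s <- max(1L, n_w %/% params$word_subsample_divisor)
  nb <- params$n_bootstrap
  samp <- sample.int(n_w, s * nb, replace = TRUE)
  trials <- rowsum(sub[samp, , drop = FALSE],
                   group = rep.int(seq_len(nb), rep.int(s, nb)),
                   reorder = FALSE)
  bwin <- max.col(trials, ties.method = "first")
  winlin <- as.character(model$lineage[win, ])
  conf <- vapply(seq_along(SEVEN_RANKS), function(r)
    mean(model$lineage[[r]][bwin] == winlin[r]), numeric(1))
  conf <- cummin(conf)
  structure(list(ranks = stats::setNames(winlin, SEVEN_RANKS),
                 confidence = stats::setNames(conf, SEVEN_RANKS),
                 leaf = model$leaves[win],
                 raw_score = raw,
                 n_words = n_w),
            class = "ClassificationResult")
}

#' Truncate an assignment at its confidence cutoff
#'
#' Ranks whose confidence falls below `min_confidence` are replaced by
#' `unclassified_<deepest surviving named rank>`; if the raw score is below
#' `min_raw_score` everything below kingdom is truncated.
#'
#' @param x a `ClassificationResult`, or the per-read table produced by
#'   [classify_sample()].
#' @param params a `ClassifierParams` object.
#' @return for a single result, a named character vector over
#'   [SEVEN_RANKS]; for a table, a data.frame of `read_id` plus the seven
#'   truncated rank columns.
#' @export
apply_cutoff <- function(x, params = classifier_params()) {
  UseMethod("apply_cutoff")
}

#' @export
apply_cutoff.ClassificationResult <- function(x, params = classifier_params()) {
  depth <- sum(x$confidence >= params$min_confidence)
  if (x$raw_score < params$min_raw_score) depth <- 1L
  depth <- max(depth, 1L)
  out <- x$ranks
  last_named <- out[[1L]]
  for (i in 2:7) {
    if (i <= depth) {
      if (!startsWith(out[[i]], UNCLASSIFIED_PREFIX)) last_named <- out[[i]]
    } else {
      out[[i]] <- paste0(UNCLASSIFIED_PREFIX, last_named)
    }
  }
  out
}

#' @export
apply_cutoff.data.frame <- function(x, params = classifier_params()) {
  n <- nrow(x)
  ranks <- as.matrix(x[SEVEN_RANKS])
  if (n == 0L)
    return(cbind(data.frame(read_id = character(0)),
                 as.data.frame(ranks, stringsAsFactors = FALSE)))
  conf <- as.matrix(x[paste0("conf_", SEVEN_RANKS)])
  depth <- rowSums(conf >= params$min_confidence)  # monotone by smoothing
  depth[x$raw_score < params$min_raw_score] <- 1L
  depth <- pmax(depth, 1L)
  last_named <- ranks[, 1L]
  for (i in 2:7) {
    kept <- depth >= i
    real <- kept & !startsWith(ranks[, i], UNCLASSIFIED_PREFIX)
    ranks[!kept, i] <- paste0(UNCLASSIFIED_PREFIX, last_named[!kept])
    last_named[real] <- ranks[real, i]
  }
  out <- data.frame(read_id = x$read_id, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(ranks, stringsAsFactors = FALSE))
}

#' Classify all reads of a sample
#'
#' Each read is classified with its own RNG stream derived from
#' `params$rng_seed` and the read id, so the output is deterministic for a
#' given seed and independent of read order.
#'
#' @param reads data.frame with columns `read_id` and `seq` (or a named
#'   character vector of sequences).
#' @param model a `KmerModel`.
#' @param params a `ClassifierParams` object.
#' @return data.frame with one row per read: `read_id`, the seven rank
#'   columns, `conf_<rank>` columns, `leaf` and `raw_score`.
#' @export
classify_sample <- function(reads, model, params = classifier_params()) {
  if (is.character(reads))
    reads <- data.frame(read_id = names(reads), seq = unname(reads),
                        stringsAsFactors = FALSE)
  n <- nrow(reads)
  ranks <- matrix(character(0), 0L, 7L)
  conf <- matrix(numeric(0), 0L, 7L)
  if (n > 0L) {
    ranks <- matrix(NA_character_, n, 7L)
    conf <- matrix(NA_real_, n, 7L)
    leaf <- character(n)
    raw <- numeric(n)
    seeds <- (as.numeric(params$rng_seed) * 48271 +
                str_hash(reads$read_id)) %% 2147483647
    for (i in seq_len(n)) {
      set.seed(as.integer(seeds[i]))
      r <- classify(reads$seq[i], model, params)
      ranks[i, ] <- r$ranks
      conf[i, ] <- r$confidence
      leaf[i] <- r$leaf
      raw[i] <- r$raw_score
    }
  } else {
    leaf <- character(0)
    raw <- numeric(0)
  }
  colnames(ranks) <- SEVEN_RANKS
  colnames(conf) <- paste0("conf_", SEVEN_RANKS)
  cbind(data.frame(read_id = if (n) reads$read_id else character(0),
                   stringsAsFactors = FALSE),
        as.data.frame(ranks, stringsAsFactors = FALSE),
        as.data.frame(conf),
        data.frame(leaf = leaf, raw_score = raw, stringsAsFactors = FALSE))
}
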