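# Species-accumulation (rarefaction) curves per sample: the analytic
# hypergeometric expectation and a Monte-Carlo subsampling alternative,
# plus saturation-depth detection.

#' Construct an accumulation curve
#'
#' @param depths increasing integer subsample depths.
#' @param expected_taxa expected distinct-taxon counts, non-decreasing.
#' @param mode `"analytic"` or `"montecarlo"`.
#' @param reps,seed Monte-Carlo bookkeeping (NA for analytic curves).
#' @return object of class `AccumulationCurve`: a data.frame with columns
#'   `depth` and `expected_taxa` plus attributes `mode`, `reps`, `seed`.
#' @export
accumulation_curve <- function(depths, expected_taxa,
                               mode = c("analytic", "montecarlo"),
                               reps = NA_integer_, seed = NA_integer_) {
  mode <- match.arg(mode)
  stopifnot(length(depths) == length(expected_taxa))
  if (is.unsorted(depths, strictly = TRUE))
    stop("depths must be strictly increasing")
  if (any(diff(expected_taxa) < -1e-9))
    stop("expected_taxa must be non-decreasing")
  out <- data.frame(depth = as.integer(depths),
                    expected_taxa = as.numeric(expected_taxa))
  attr(out, "mode") <- mode
  attr(out, "reps") <- reps
  attr(out, "seed") <- seed
  class(out) <- c("AccumulationCurve", "data.frame")
  out
}

#' Default rarefaction depth grid
#'
#' Log-spaced depths from 1 up to the sample total, capped for plotting.
#'
#' @param total total read count of the sample.
#' @param n number of grid points.
#' @param cap upper depth bound (default 5000).
#' @return increasing integer vector of depths.
#' @export
depth_grid <- function(total, n = 50L, cap = 5000L) {
  top <- min(total, cap)
  unique(as.integer(round(exp(seq(0, log(top), length.out = n)))))
}

#' Analytic rarefaction
#'
#' The expected number of distinct taxa in a uniform subsample of `d`
#' reads without replacement from a sample of `N` reads with per-taxon
#' counts `N_i` is `E[S(d)] = sum_i (1 - C(N - N_i, d) / C(N, d))`, with
#' `C(a, b) = 0` for `a < b`. Computed with log-gamma arithmetic
#' (`lchoose`) to avoid overflow.
#'
#' @param counts non-negative taxon counts (named vector).
#' @param depths subsample depths, each at most `sum(counts)`.
#' @return an `AccumulationCurve`.
#' @export
rarefy_analytic <- function(counts, depths) {
  counts <- counts[counts > 0]
  n_tot <- sum(counts)
  depths <- sort(unique(as.integer(depths)))
  if (length(depths) == 0L) stop("no depths given")
  if (any(depths < 1L)) stop("depths must be >= 1")
  if (any(depths > n_tot))
    stop("depth exceeds the sample total of ", n_tot, " reads")
  es <- vapply(depths, function(d)
    sum(1 - exp(lchoose(n_tot - counts, d) - lchoose(n_tot, d))),
    numeric(1))
  accumulation_curve(depths, es, "analytic")
}

#' Monte-Carlo rarefaction
#'
#' Mean distinct-taxon count over `reps` random subsamples without
#' replacement; seeded and deterministic. Each replicate draws one random
#' permutation of the reads, so its curve is exactly monotone in depth.
#'
#' @param counts non-negative taxon counts.
#' @param depths subsample depths, each at most `sum(counts)`.
#' @param reps number of replicates (>= 1).
#' @param seed RNG seed.
#' @return an `AccumulationCurve`.
#' @export
rarefy_montecarlo <- function(counts, depths, reps = 100L, seed = 1L) {
  stopifnot(reps >= 1L)
  counts <- counts[counts > 0]
  n_tot <- sum(counts)
  depths <- sort(unique(as.integer(depths)))
  if (length(depths) == 0L) stop("no depths given")
  if (any(depths < 1L)) stop("depths must be >= 1")
  if (any(depths > n_tot))
    stop("depth exceeds the sample total of ", n_tot, " reads")
  pool <- rep(seq_along(counts), counts)
  set.seed(seed)
  acc <- numeric(length(depths))
  for (r in seq_len(reps)) {
    cum_distinct <- cumsum(!duplicated(sample(pool)))
    acc <- acc + cum_distinct[depths]
  }
  accumulation_curve(depths, acc / reps, "montecarlo", reps = reps,
                     seed = seed)
}

#' Saturation depth of an accumulation curve
#'
#' @param curve an `AccumulationCurve`.
#' @param fraction saturation is reached at the smallest depth whose
#'   expected richness is at least `fraction` times the curve's final
#'   value.
#' @return the saturation depth, or `NA` if never reached on the grid.
#' @export
saturation_depth <- function(curve, fraction = 0.99) {
  if (nrow(curve) == 0L) stop("empty accumulation curve")
  final <- curve$expected_taxa[nrow(curve)]
  i <- which(curve$expected_taxa >= fraction * final)[1L]
  if (is.na(i)) NA_integer_ else curve$depth[i]
}

#' Accumulation curves for every sample of a community matrix
#'
#' By default the per-sample rare-taxon filter is applied first (taxa
#' below `rare_frac` of the sample total are excluded), matching how
#' saturation is usually assessed; set `rare_filter = FALSE` for raw
#' counts.
#'
#' @param cm a `CommunityMatrix`.
#' @param mode `"analytic"` or `"montecarlo"`.
#' @param depths depth grid; default [depth_grid()] per sample.
#' @param rare_filter apply the rare-taxon rule before rarefying.
#' @param params an `AggregateParams` object (for `rare_frac`).
#' @param reps,seed Monte-Carlo settings.
#' @return named list of `AccumulationCurve` objects (samples with zero
#'   reads are skipped).
#' @export
accumulation_curves <- function(cm, mode = c("analytic", "montecarlo"),
                                depths = NULL, rare_filter = TRUE,
                                params = aggregate_params(), reps = 100L,
                                seed = 1L) {
  mode <- match.arg(mode)
  out <- list()
  for (s in colnames(cm$counts)) {
    cnt <- cm$counts[, s]
    tot <- sum(cnt)
    if (tot == 0L) next
    if (rare_filter) cnt[cnt / tot < params$rare_frac] <- 0L
    cnt <- cnt[cnt > 0]
    d <- if (is.null(depths)) depth_grid(sum(cnt)) else
      depths[depths <= sum(cnt)]
    out[[s]] <- if (mode == "analytic") rarefy_analytic(cnt, d)
                else rarefy_montecarlo(cnt, d, reps = reps, seed = seed)
  }
  out
}
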