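# Mock-community run simulator: hierarchically structured reference
# databases, log-normally skewed per-sample communities, and dual-indexed
# paired-read MiSeq-like runs with known per-read ground truth. All
# randomness flows from a single seed; reruns are bit-identical.

#' Simulation parameters
#'
#' Defaults describe the standard test run used throughout the package: a
#' reference set of 2 orders x 2 families x 5 genera x 2 species (40
#' species, 20 genera) over amplicons of 350-480 nt, 8 samples of 5,000
#' read pairs each drawn from 20-species communities with log-normal
#' abundance skew (sigma = 1), 2 x 250 nt reads with 1% substitution
#' error and linearly decaying quality, and error-free index reads.
#'
#' @param n_orders,families_per_order,genera_per_family,species_per_genus
#'   reference-tree shape (all >= 1).
#' @param seq_len_range amplicon length range in nt.
#' @param divergence named substitution fractions applied when descending
#'   each rank (`order`, `family`, `genus`, `species`), each in (0, 0.5).
#' @param read_len read length in nt.
#' @param error_rate per-base substitution probability in `[0, 0.2]`.
#' @param index_error_rate per-base substitution probability on index
#'   reads.
#' @param quality_range Phred quality at the first and last cycle (linear
#'   decay in between).
#' @param sigma log-normal abundance skew (sd of log abundance).
#' @param n_taxa_per_sample species per mock community.
#' @param reads_per_sample read pairs per sample.
#' @param n_samples number of samples in a run.
#' @param rng_seed master seed.
#' @return a `SimParams` list.
#' @export
sim_params <- function(n_orders = 2L, families_per_order = 2L,
                       genera_per_family = 5L, species_per_genus = 2L,
                       seq_len_range = c(350L, 480L),
                       divergence = c(order = 0.20, family = 0.10,
                                      genus = 0.05, species = 0.02),
                       read_len = 250L, error_rate = 0.01,
                       index_error_rate = 0,
                       quality_range = c(38L, 25L), sigma = 1,
                       n_taxa_per_sample = 20L,
                       reads_per_sample = 5000L, n_samples = 8L,
                       rng_seed = 1L) {
  stopifnot(n_orders >= 1L, families_per_order >= 1L,
            genera_per_family >= 1L, species_per_genus >= 1L,
            all(c("order", "family", "genus", "species") %in%
                  names(divergence)),
            all(divergence > 0), all(divergence < 0.5),
            error_rate >= 0, error_rate <= 0.2,
            index_error_rate >= 0, index_error_rate <= 1,
            read_len >= 1L, sigma >= 0)
  structure(list(n_orders = as.integer(n_orders),
                 families_per_order = as.integer(families_per_order),
                 genera_per_family = as.integer(genera_per_family),
                 species_per_genus = as.integer(species_per_genus),
                 seq_len_range = as.integer(seq_len_range),
                 divergence = divergence,
                 read_len = as.integer(read_len),
                 error_rate = error_rate,
                 index_error_rate = index_error_rate,
                 quality_range = as.integer(quality_range),
                 sigma = sigma,
                 n_taxa_per_sample = as.integer(n_taxa_per_sample),
                 reads_per_sample = as.integer(reads_per_sample),
                 n_samples = as.integer(n_samples),
                 rng_seed = as.integer(rng_seed)),
            class = "SimParams")
}

# substitute a fixed fraction of positions with a different base
.mutate_seq <- function(seq, frac) {
  n <- nchar(seq)
  k <- round(frac * n)
  if (k == 0L) return(seq)
  v <- strsplit(seq, "")[[1]]
  pos <- sample.int(n, k)
  v[pos] <- vapply(v[pos], function(b)
    sample(setdiff(DNA_BASES, b), 1L), character(1), USE.NAMES = FALSE)
  paste(v, collapse = "")
}

# per-base random substitutions at a given rate
.inject_errors <- function(seqs, rate) {
  if (rate == 0 || length(seqs) == 0L) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    ne <- stats::rbinom(1L, n, rate)
    if (ne == 0L) return(s)
    v <- strsplit(s, "")[[1]]
    pos <- sample.int(n, ne)
    v[pos] <- vapply(v[pos], function(b)
      sample(setdiff(DNA_BASES, b), 1L), character(1), USE.NAMES = FALSE)
    paste(v, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate a hierarchically structured reference database
#'
#' A single root amplicon is drawn uniformly over ACGT with length sampled
#' from `seq_len_range`; descending each rank applies that rank's
#' substitution fraction at random positions, so sequences within a genus
#' are more similar than sequences across orders. Lineage names are
#' systematic (`o1`, `o1_f2`, `o1_f2_g3`, `o1_f2_g3_s4`) under one
#' kingdom/phylum/class.
#'
#' @param params a `SimParams` object.
#' @param seed RNG seed (defaults to `params$rng_seed`).
#' @return a `ReferenceDB` with one sequence per species.
#' @export
simulate_refdb <- function(params = sim_params(), seed = params$rng_seed) {
  set.seed(seed)
  len <- sample(params$seq_len_range[1L]:params$seq_len_range[2L], 1L)
  root <- paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  dv <- params$divergence
  ids <- character(0)
  seqs <- character(0)
  lin <- list()
  for (o in seq_len(params$n_orders)) {
    o_name <- sprintf("o%d", o)
    o_seq <- .mutate_seq(root, dv[["order"]])
    for (f in seq_len(params$families_per_order)) {
      f_name <- sprintf("%s_f%d", o_name, f)
      f_seq <- .mutate_seq(o_seq, dv[["family"]])
      for (g in seq_len(params$genera_per_family)) {
        g_name <- sprintf("%s_g%d", f_name, g)
        g_seq <- .mutate_seq(f_seq, dv[["genus"]])
        for (s in seq_len(params$species_per_genus)) {
          s_name <- sprintf("%s_s%d", g_name, s)
          s_seq <- .mutate_seq(g_seq, dv[["species"]])
          ids <- c(ids, s_name)
          seqs <- c(seqs, s_seq)
          lin[[length(lin) + 1L]] <-
            c(kingdom = "k1", phylum = "p1", class = "c1",
              order = o_name, family = f_name, genus = g_name,
              species = s_name)
        }
      }
    }
  }
  reference_db(ids, seqs, do.call(rbind, lin))
}

#' Simulate a mock-community composition
#'
#' Samples `n_taxa` species without replacement and assigns them
#' log-normal abundances (`exp(N(0, sigma^2))`), normalized and converted
#' to integer read counts summing exactly to `reads_per_sample` by
#' largest-remainder rounding.
#'
#' @param db a `ReferenceDB`.
#' @param n_taxa number of species in the community.
#' @param sigma log-normal skew (0 gives near-uniform counts).
#' @param reads_per_sample total reads of the sample.
#' @param seed RNG seed.
#' @return named integer vector of true per-species read counts.
#' @export
simulate_community <- function(db, n_taxa, sigma = 1,
                               reads_per_sample = 5000L, seed = 1L) {
  species <- unique(db$species)
  if (n_taxa > length(species))
    stop(sprintf("n_taxa = %d exceeds the %d species available", n_taxa,
                 length(species)))
  set.seed(seed)
  pick <- sample(species, n_taxa)
  w <- exp(stats::rnorm(n_taxa, 0, sigma))
  p <- w / sum(w)
  base <- floor(p * reads_per_sample)
  rem <- reads_per_sample - sum(base)
  if (rem > 0L) {
    ord <- order(-(p * reads_per_sample - base), seq_along(base))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), pick)
}

#' Simulate a dual-indexed sequencing run
#'
#' For every sample, read pairs are drawn from the reference sequence of
#' their true species: the forward read is the first `read_len` nt, the
#' reverse read the reverse complement of the last `read_len` nt.
#' Substitution errors are injected per base at `error_rate`; qualities
#' decay linearly across the read between `quality_range[1]` and
#' `quality_range[2]`. Index reads carry the sample's index pair, perturbed
#' at `index_error_rate`. Ground truth is recorded per read and per
#' sample.
#'
#' @param db a `ReferenceDB`.
#' @param communities named list (sample id -> named true count vector,
#'   e.g. from [simulate_community()]).
#' @param sheet a `SampleSheet` with one row per community.
#' @param params a `SimParams` object.
#' @param seed RNG seed (defaults to `params$rng_seed`).
#' @return object of class `SimRun`: list with `reads` (data.frame `id`,
#'   `r1_seq`, `r1_qual`, `r2_seq`, `r2_qual`, `i1_seq`, `i2_seq`),
#'   `sheet`, `truth_counts` (the input communities), `truth_reads`
#'   (data.frame `id`, `sample_id`, `species`) and `params`.
#' @export
simulate_run <- function(db, communities, sheet, params = sim_params(),
                         seed = params$rng_seed) {
  if (!inherits(sheet, "SampleSheet")) sheet <- samplesheet(sheet)
  stopifnot(!is.null(names(communities)),
            all(names(communities) %in% sheet$sample_id))
  refseq <- stats::setNames(db$sequence, db$species)
  reflen <- stats::setNames(nchar(db$sequence), db$species)
  rl <- params$read_len
  if (any(reflen < rl))
    stop("reference sequence shorter than the read length")
  if (any(2L * rl - reflen < 1L))
    stop("reference sequence too long for the paired reads to overlap")
  qual1 <- phred_to_qual(round(seq(params$quality_range[1L],
                                   params$quality_range[2L],
                                   length.out = rl)))
  iqual <- phred_to_qual(rep(params$quality_range[1L], 8L))
  set.seed(seed)
  chunks <- list()
  truth <- list()
  for (s in names(communities)) {
    cnt <- communities[[s]]
    if (!all(names(cnt) %in% names(refseq)))
      stop("community of sample ", s, " names unknown species")
    taxa <- rep(names(cnt), cnt)
    n <- length(taxa)
    if (n == 0L) next
    row <- match(s, sheet$sample_id)
    fwd <- substr(refseq[taxa], 1L, rl)
    rev <- revcomp(substring(refseq[taxa], reflen[taxa] - rl + 1L,
                             reflen[taxa]))
    ids <- sprintf("%s_read%05d", s, seq_len(n))
    chunks[[s]] <- data.frame(
      id = ids,
      r1_seq = .inject_errors(unname(fwd), params$error_rate),
      r1_qual = qual1,
      r2_seq = .inject_errors(unname(rev), params$error_rate),
      r2_qual = qual1,
      i1_seq = .inject_errors(rep(sheet$fwd_index[row], n),
                              params$index_error_rate),
      i2_seq = .inject_errors(rep(sheet$rev_index[row], n),
                              params$index_error_rate),
      stringsAsFactors = FALSE)
    truth[[s]] <- data.frame(id = ids, sample_id = s, species = taxa,
                             stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, c(chunks, list(make.row.names = FALSE)))
  truth_reads <- do.call(rbind, c(truth, list(make.row.names = FALSE)))
  structure(list(reads = reads, sheet = sheet,
                 truth_counts = communities, truth_reads = truth_reads,
                 params = params),
            class = "SimRun")
}

#' Simulate a complete default run
#'
#' Convenience wrapper: builds the reference database, one mock community
#' per sample and the dual-indexed run from a single `SimParams` object,
#' deriving all seeds from `params$rng_seed`.
#'
#' @param params a `SimParams` object.
#' @return list with `db`, `sheet` and `run`.
#' @export
simulate_default_run <- function(params = sim_params()) {
  db <- simulate_refdb(params, seed = params$rng_seed)
  fwd <- random_index_set(params$n_samples, "forward",
                          seed = params$rng_seed + 101L)
  rev <- random_index_set(params$n_samples, "reverse",
                          seed = params$rng_seed + 202L)
  sheet <- samplesheet(data.frame(
    sample_id = sprintf("sample%02d", seq_len(params$n_samples)),
    fwd_index = unname(unclass(fwd)),
    rev_index = unname(unclass(rev)),
    stringsAsFactors = FALSE))
  communities <- lapply(seq_len(params$n_samples), function(i)
    simulate_community(db, params$n_taxa_per_sample, params$sigma,
                       params$reads_per_sample,
                       seed = params$rng_seed + 1000L + i))
  names(communities) <- sheet$sample_id
  run <- simulate_run(db, communities, sheet, params,
                      seed = params$rng_seed + 5000L)
  list(db = db, sheet = sheet, run = run)
}

#' Write a simulated run to disk
#'
#' Emits `R1.fastq`, `R2.fastq`, `I1.fastq`, `I2.fastq`,
#' `samplesheet.csv`, `truth_reads.tsv` and `truth_counts.tsv`.
#'
#' @param run a `SimRun`.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  r <- run$reads
  write_fastq(data.frame(id = r$id, seq = r$r1_seq, qual = r$r1_qual),
              file.path(dir, "R1.fastq"))
  write_fastq(data.frame(id = r$id, seq = r$r2_seq, qual = r$r2_qual),
              file.path(dir, "R2.fastq"))
  iq <- strrep(substr(r$r1_qual[1L], 1L, 1L), 8L)
  write_fastq(data.frame(id = r$id, seq = r$i1_seq, qual = iq),
              file.path(dir, "I1.fastq"))
  write_fastq(data.frame(id = r$id, seq = r$i2_seq, qual = iq),
              file.path(dir, "I2.fastq"))
  utils::write.csv(as.data.frame(run$sheet),
                   file.path(dir, "samplesheet.csv"), row.names = FALSE)
  utils::write.table(run$truth_reads, file.path(dir, "truth_reads.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tc <- do.call(rbind, lapply(names(run$truth_counts), function(s)
    data.frame(sample_id = s, species = names(run$truth_counts[[s]]),
               count = as.integer(run$truth_counts[[s]]),
               stringsAsFactors = FALSE)))
  utils::write.table(tc, file.path(dir, "truth_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
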