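# End-to-end workflow: demultiplex a run, merge and filter each sample's
# read pairs, classify, truncate at the confidence cutoff, and aggregate
# into the filtered community matrix.

#' Run the complete meta-barcoding pipeline on a set of indexed read pairs
#'
#' Stages: dual-index demultiplexing ([demultiplex()]), per-sample
#' paired-end merging ([merge_pairs()]), quality filtering
#' ([filter_reads()]), naive Bayes classification ([classify_sample()])
#' with confidence cutoff ([apply_cutoff()]), aggregation
#' ([aggregate_assignments()]), the rare-taxon filter ([filter_rare()])
#' and the sequencing-depth filter ([drop_low_depth_samples()]), in that
#' order.
#'
#' @param run a `SimRun`, or a list with elements `reads` (data.frame
#'   `id`, `r1_seq`, `r1_qual`, `r2_seq`, `r2_qual`, `i1_seq`, `i2_seq`)
#'   and `sheet` (a `SampleSheet`).
#' @param db a `ReferenceDB` used to train the classifier (ignored when
#'   `model` is given).
#' @param model optional pre-trained `KmerModel`.
#' @param cparams,mparams,fparams,aparams parameter objects for the
#'   classifier, merger, quality filter and aggregation stages.
#' @param max_mismatch index mismatches tolerated by the demultiplexer.
#' @return list with `model`, `demux` (`DemuxResult`), `prep` (per-sample
#'   read-count report), `assignments` (per-sample truncated lineage
#'   tables), `community_raw` (unfiltered `CommunityMatrix`), `community`
#'   (rare- and depth-filtered) and `dropped_samples`.
#' @export
pollen_pipeline <- function(run, db = NULL, model = NULL,
                            cparams = classifier_params(),
                            mparams = merge_params(),
                            fparams = filter_params(),
                            aparams = aggregate_params(),
                            max_mismatch = 0L) {
  if (is.null(model)) {
    if (is.null(db)) stop("provide a reference database or a model")
    model <- train_classifier(db, cparams)
  }
  dm <- demultiplex(run$reads, run$sheet, max_mismatch)
  tables <- list()
  prep <- list()
  for (s in run$sheet$sample_id) {
    sub <- run$reads[dm$assignments == s, , drop = FALSE]
    mg <- merge_pairs(sub, mparams)
    fl <- filter_reads(mg$merged, fparams)
    kept <- fl[fl$keep, , drop = FALSE]
    cl <- classify_sample(
      data.frame(read_id = kept$id, seq = kept$seq,
                 stringsAsFactors = FALSE),
      model, cparams)
    tables[[s]] <- apply_cutoff(cl, cparams)
    prep[[s]] <- prep_report(nrow(sub), nrow(mg$merged), nrow(kept), s)
  }
  cm_raw <- aggregate_assignments(tables)
  cm <- filter_rare(cm_raw, aparams)
  low <- drop_low_depth_samples(cm, aparams)
  list(model = model, demux = dm,
       prep = do.call(rbind, c(prep, list(make.row.names = FALSE))),
       assignments = tables, community_raw = cm_raw,
       community = low$community, dropped_samples = low$dropped)
}
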