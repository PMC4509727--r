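lin_row <- function(g, s) {
  data.frame(kingdom = "k1", phylum = "p1", class = "c1", order = "o1",
             family = "f1", genus = g, species = s,
             stringsAsFactors = FALSE)
}

assign_table <- function(species, genus = sub("_.*", "g", species)) {
  if (length(species) == 0L)
    return(lin_row("g", "s")[0, ])
  do.call(rbind, Map(lin_row, genus, species))
}

toy_cm <- function(counts, samples = paste0("s", seq_len(ncol(counts)))) {
  taxa <- sprintf("sp%d", seq_len(nrow(counts)))
  tables <- lapply(seq_along(samples), function(j) {
    reps <- rep(seq_len(nrow(counts)), counts[, j])
    assign_table(taxa[reps], genus = paste0("g", (reps + 1) %/% 2))
  })
  names(tables) <- samples
  aggregate_assignments(tables)
}

test_that("aggregation counts assignments per taxon and sample", {
  t1 <- assign_table(c("A", "A", "A", "B", "B"), c("gA", "gA", "gA", "gB", "gB"))
  t2 <- assign_table(c("C", "C"), c("gC", "gC"))
  cm <- aggregate_assignments(list(s1 = t1, s2 = t2))
  expect_identical(unname(cm$counts[, "s1"]),
                   unname(c(3L, 2L, 0L)[order(c("A", "B", "C"))]))
  expect_identical(cm$counts["A", "s1"], 3L)
  expect_identical(cm$counts["B", "s1"], 2L)
  expect_identical(cm$counts["C", "s1"], 0L)
  expect_identical(cm$counts["C", "s2"], 2L)
  expect_equal(unname(colSums(cm$counts)), c(5, 2))
  expect_identical(nrow(cm$lineage), 3L)

  # 3 samples x 4 taxa: column sums conserve the input read counts
  set.seed(13)
  counts <- matrix(sample(0:5, 12, replace = TRUE), 4, 3)
  cm2 <- toy_cm(counts)
  expect_identical(unname(colSums(cm2$counts)), unname(colSums(counts)))
  expect_identical(sum(cm2$counts), sum(counts))
})

test_that("homonymous taxon labels with different lineages are rejected", {
  t1 <- rbind(lin_row("gA", "X"), lin_row("gB", "X"))
  expect_error(aggregate_assignments(list(s1 = t1)), "conflicting")
})

test_that("rows are labelled by the deepest named rank", {
  t1 <- rbind(lin_row("gA", "unclassified_gA"),
              lin_row("gA", "spX"))
  cm <- aggregate_assignments(list(s1 = t1))
  expect_setequal(rownames(cm$counts), c("gA", "spX"))
})

test_that("rare-taxon filter uses a strict threshold on original totals", {
  # one sample of 10,000 reads; counts 9 (0.09%) and 10 (0.10%)
  t1 <- assign_table(c(rep("A", 9981), rep("B", 9), rep("C", 10)),
                     c(rep("gA", 9981), rep("gB", 9), rep("gC", 10)))
  cm <- aggregate_assignments(list(s1 = t1))
  f <- filter_rare(cm, aggregate_params(rare_frac = 0.001))
  expect_false("B" %in% rownames(f$counts))
  expect_identical(f$counts["C", "s1"], 10L)

  # all taxa below the threshold leaves an empty matrix
  u <- aggregate_assignments(list(s1 = assign_table(c("A", "B"),
                                                    c("gA", "gB"))))
  f2 <- filter_rare(u, aggregate_params(rare_frac = 0.9999))
  expect_identical(nrow(f2$counts), 0L)

  # never increases an entry, on random matrices
  set.seed(19)
  for (i in 1:5) {
    cm3 <- toy_cm(matrix(sample(0:50, 12, replace = TRUE), 4, 3))
    f3 <- filter_rare(cm3, aggregate_params(rare_frac = 0.05))
    common <- rownames(f3$counts)
    expect_true(all(f3$counts <= cm3$counts[common, , drop = FALSE]))
  }
})

test_that("low-depth samples are dropped at the exact boundary", {
  counts <- cbind(s_low = c(1000L, 999L), s_ok = c(1000L, 1000L))
  cm <- toy_cm(counts, samples = colnames(counts))
  r <- drop_low_depth_samples(cm, aggregate_params(min_sample_reads = 2000))
  expect_identical(r$dropped, "s_low")
  expect_identical(colnames(r$community$counts), "s_ok")
  r2 <- drop_low_depth_samples(cm, aggregate_params(min_sample_reads = 3000))
  expect_identical(ncol(r2$community$counts), 0L)
  expect_length(r2$dropped, 2L)
})

test_that("relative abundance normalizes each column to 1", {
  cm <- toy_cm(matrix(c(3L, 1L), 2, 1))
  ra <- relative_abundance(cm)
  expect_equal(unname(ra[, 1]), c(0.75, 0.25))
  expect_equal(unname(colSums(ra)), 1, tolerance = 1e-9)
  cm0 <- toy_cm(matrix(c(1L, 0L, 0L, 0L), 2, 2))
  expect_error(relative_abundance(cm0), "zero")
})

test_that("rank summaries rank by share and fold the tail into other", {
  t1 <- assign_table(c(rep("A", 6), rep("B", 4)), c(rep("gA", 6), rep("gB", 4)))
  cm <- aggregate_assignments(list(s1 = t1))
  rs <- rank_summary(cm, "genus")
  expect_identical(rs$name, c("gA", "gB"))
  expect_equal(rs$share, c(0.6, 0.4))
  rs1 <- rank_summary(cm, "genus", top_n = 1)
  expect_identical(rs1$name, c("gA", "other"))
  expect_equal(sum(rs1$share), 1)
  expect_error(rank_summary(cm, "genus", samples = character(0)), "empty")
})
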