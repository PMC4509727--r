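toy_tree <- function() {
  tax_tree(data.frame(
    taxon_id = 1:9,
    name = c("root", "k1", "p1", "c1", "o1", "f1", "g1", "s1", "f2"),
    parent_id = c(1L, 1L, 2L, 3L, 4L, 5L, 6L, 7L, 5L),
    rank = c("no rank", "kingdom", "phylum", "class", "order", "family",
             "genus", "species", "family")))
}

test_that("lineage normalization fills gaps from the nearest named ancestor", {
  full <- normalize_lineage(c("k1", "p1", "c1", "o1", "f1", "g1", "s1"))
  expect_identical(unname(full[7]), "s1")
  part <- normalize_lineage(c("k1", "p1", "c1", "o1", "f1", NA, NA))
  expect_identical(unname(part[6]), "unclassified_f1")
  expect_identical(unname(part[7]), "unclassified_f1")
  # idempotent
  expect_identical(normalize_lineage(part), part)
  # a named rank below a gap keeps its name; the gap refers upward
  mid <- normalize_lineage(c("k1", "p1", "c1", "o1", NA, "g1", NA))
  expect_identical(unname(mid[5]), "unclassified_o1")
  expect_identical(unname(mid[7]), "unclassified_g1")
  expect_error(normalize_lineage(c(NA, "p1", "c1", "o1", "f1", "g1", "s1")),
               "kingdom")
})

test_that("taxonomy trees validate structure and compute depths", {
  tr <- toy_tree()
  expect_identical(tr$depth, c(0L, 1L, 2L, 3L, 4L, 5L, 6L, 7L, 5L))
  bad <- data.frame(taxon_id = 1:2, name = c("a", "b"),
                    parent_id = c(2L, 1L), rank = c("kingdom", "phylum"))
  expect_error(tax_tree(bad), "root")
})

test_that("assign_lineages walks the tree and drops unmapped ids", {
  seqs <- c(q1 = "ACGTACGTAC", q2 = "TTTTGGGGCC", q3 = "ACACACACAC")
  id2tax <- c(q1 = 8L, q2 = 9L)  # q3 unmapped; q2 attached at family f2
  expect_warning(db <- assign_lineages(seqs, id2tax, toy_tree()),
                 "dropped")
  expect_identical(attr(db, "n_dropped"), 1L)
  expect_identical(nrow(db), 2L)
  expect_identical(db$species[db$seq_id == "q1"], "s1")
  r2 <- db[db$seq_id == "q2", ]
  expect_identical(r2$family, "f2")
  expect_identical(r2$genus, "unclassified_f2")
  expect_identical(r2$species, "unclassified_f2")
})

test_that("UTAX FASTA writing and reading are mutual inverses", {
  db <- toy_refdb()
  path <- tempfile(fileext = ".fasta")
  write_utax_fasta(db, path)
  back <- read_utax_fasta(path)
  expect_identical(as.data.frame(back), as.data.frame(db))

  # delimiter sanitation
  dirty <- reference_db("id;x", "ACGTACGT",
                        data.frame(kingdom = "k,1", phylum = "p1",
                                   class = "c1", order = "o1",
                                   family = "f1", genus = "g1",
                                   species = "s:1"))
  write_utax_fasta(dirty, path)
  line1 <- readLines(path, n = 1)
  expect_identical(line1, ">id_x;tax=d:k_1,p:p1,c:c1,o:o1,f:f1,g:g1,s:s_1;")
  back2 <- read_utax_fasta(path)
  expect_identical(back2$kingdom, "k_1")

  # empty database round-trips through an empty file
  empty <- reference_db(character(0), character(0), NULL)
  write_utax_fasta(empty, path)
  expect_identical(nrow(read_utax_fasta(path)), 0L)

  writeLines(c(">broken header", "ACGT"), path)
  expect_error(read_utax_fasta(path), "record 1")
})

test_that("RDP training files form a rooted tree with one node per prefix", {
  db <- toy_refdb()   # 4 species, 2 genera, shared upper ranks
  res <- write_rdp_training(db, tempfile())
  # Root + k,p,c,o,f (1 each) + 2 genera + 4 species
  expect_identical(nrow(res$nodes), 1L + 5L + 2L + 4L)
  two_sp <- reference_db(c("a", "b"), c("ACGTACGT", "ACGTACGA"),
                         rbind(c("k1", "p1", "c1", "o1", "f1", "g1", "s1"),
                               c("k1", "p1", "c1", "o1", "f1", "g1", "s2")))
  res2 <- write_rdp_training(two_sp, tempfile())
  expect_identical(sum(res2$nodes$rank == "genus"), 1L)
  expect_identical(sum(res2$nodes$rank == "species"), 2L)
  one <- reference_db("a", "ACGTACGT",
                      data.frame(kingdom = "k1", phylum = "p1",
                                 class = "c1", order = "o1", family = "f1",
                                 genus = "g1", species = "s1"))
  expect_identical(nrow(write_rdp_training(one, tempfile())$nodes), 8L)

  # the taxonomy file parses back into a valid TaxTree
  tr <- read_rdp_taxonomy(res$taxonomy)
  expect_s3_class(tr, "TaxTree")
  expect_identical(nrow(tr), nrow(res$nodes))

  # the training FASTA headers carry the full rooted lineage
  fa <- readLines(res$fasta)
  expect_true(startsWith(fa[1], ">r1\tRoot;k1;p1;c1;o1;f1;gA;sp1"))
})

test_that("RDP node count equals distinct lineage prefixes + Root", {
  set.seed(31)
  for (i in 1:5) {
    n <- sample(3:8, 1)
    lin <- t(replicate(n, c("k1", "p1", "c1",
                            sample(c("o1", "o2"), 1),
                            sample(c("f1", "f2"), 1),
                            sample(c("g1", "g2", "g3"), 1),
                            sprintf("s%d", sample(1:5, 1)))))
    db <- reference_db(sprintf("id%d", 1:n),
                       replicate(n, rand_dna(20)), lin)
    res <- write_rdp_training(db, tempfile())
    expected <- 1L + length(unique(unlist(lapply(1:7, function(d)
      apply(as.matrix(db[SEVEN_RANKS])[, 1:d, drop = FALSE], 1, paste,
            collapse = ";")))))
    expect_identical(nrow(res$nodes), expected)
  }
})

test_that("coverage reports the checklist fraction at the queried rank", {
  db <- toy_refdb()
  expect_equal(coverage_report(db, c("sp1", "sp3"))$fraction, 1.0)
  expect_equal(coverage_report(db, c("SP1", "sp2", "nope", "x"))$fraction,
               0.5)
  # a genus is covered if any of its species is present
  expect_equal(coverage_report(db, c("gA", "gC"), rank = "genus")$fraction,
               0.5)
  expect_error(coverage_report(db, character(0)), "empty")
})
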