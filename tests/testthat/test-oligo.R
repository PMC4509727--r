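test_that("sample oligos are pure concatenations of the scaffold parts", {
  sp <- its2_scaffold()
  o <- build_sample_oligos(sp, "AAAAAAAA", "CCCCCCCC")
  expect_identical(nchar(o[["forward"]]), 29L + 8L + 10L + 2L + 20L)
  expect_true(startsWith(o[["forward"]], "AATGATACGG"))
  expect_true(endsWith(o[["forward"]], "GTGTGAAT"))
  expect_identical(o[["reverse"]],
                   paste0("CAAGCAGAAGACGGCATACGAGAT", "CCCCCCCC",
                          "AGTCAGTCAG", "CC", "TCCTCCGCTTATTGATATGC"))

  # concatenation identity on a degenerate component list
  bare <- list(fwd_adapter = "", fwd_pad = "", fwd_linker = "",
               fwd_amp_primer = "A", rev_adapter = "", rev_pad = "",
               rev_linker = "", rev_amp_primer = "A")
  expect_identical(build_sample_oligos(bare, "ACGTACGT", "ACGTACGT")[["forward"]],
                   "ACGTACGTA")

  expect_error(build_sample_oligos(sp, "AAAAAAA", "CCCCCCCC"), "fwd_index")
  expect_error(build_sample_oligos(sp, "AAAAAAAA", "CCCCCCCN"), "rev_index")
})

test_that("scaffold validation enforces pad and linker lengths", {
  expect_error(scaffold_spec("ACGT", "AT", "GT", "ACGT",
                             "ACGT", "AGTCAGTCAG", "CC", "ACGT"),
               "fwd_pad")
  expect_error(scaffold_spec("ACGT", "CCTGGTGCTG", "G", "ACGT",
                             "ACGT", "AGTCAGTCAG", "CC", "ACGT"),
               "fwd_linker")
})

test_that("sequencing primers follow the scaffold and the printed set", {
  p <- derive_sequencing_primers(its2_scaffold())
  expect_identical(p$read1, "CCTGGTGCTGGTATGCGATACTTGGTGTGAAT")
  expect_identical(p$read2, "AGTCAGTCAGCCTCCTCCGCTTATTGATATGC")
  expect_identical(p$index_primer, "GCATATCAATAAGCGGAGGAGGCTGACTGACT")

  # revcomp(index_primer) == read2 for random valid scaffolds
  set.seed(42)
  for (i in 1:10) {
    sp <- scaffold_spec(rand_dna(29), rand_dna(10), rand_dna(2),
                        rand_dna(20), rand_dna(24), rand_dna(10),
                        rand_dna(2), rand_dna(20))
    pr <- derive_sequencing_primers(sp)
    expect_identical(revcomp(pr$index_primer), pr$read2)
  }

  # a reverse-complement-palindromic read2 region is its own index primer
  sp <- scaffold_spec("ACGT", "CCTGGTGCTG", "GT", "ACGT",
                      "ACGT", "ACGTACGTAC", "GG",
                      revcomp("ACGTACGTACGG"))
  pr <- derive_sequencing_primers(sp)
  expect_identical(pr$index_primer, pr$read2)
})

test_that("gc_fraction counts G+C over length and respects revcomp", {
  expect_equal(gc_fraction("CCTGGTGCTGGTATGCGATACTTGGTGTGAAT"), 0.5)
  expect_equal(gc_fraction("GGCC"), 1.0)
  expect_equal(gc_fraction("ATAT"), 0.0)
  expect_error(gc_fraction(""), "non-empty")
  set.seed(7)
  for (i in 1:20) {
    s <- rand_dna(sample(5:60, 1))
    expect_equal(gc_fraction(s), gc_fraction(revcomp(s)))
  }
})

test_that("melting temperature models behave as specified", {
  expect_equal(melting_temperature("ACGT", "wallace"), 12)
  expect_equal(melting_temperature("CCTGGTGCTGGTATGCGATACTTGGTGTGAAT",
                                   "marmur_doty"),
               64.9 + 41 * (16 - 16.4) / 32)
  expect_warning(melting_temperature(strrep("ACGT", 4), "wallace"),
                 "14 nt")
  expect_error(melting_temperature("ACGT", "boiling"))
  # duplex symmetry of the nearest-neighbor model
  set.seed(11)
  for (i in 1:10) {
    s <- rand_dna(sample(10:40, 1))
    expect_equal(melting_temperature(s, "nearest_neighbor"),
                 melting_temperature(revcomp(s), "nearest_neighbor"),
                 tolerance = 1e-10)
  }
})

test_that("longest_complementary_run matches brute force and is symmetric", {
  expect_identical(longest_complementary_run("AAAA", "TTTT"), 4L)
  expect_identical(longest_complementary_run("ACGT", "ACGT"), 4L)
  set.seed(3)
  for (i in 1:15) {
    a <- rand_dna(sample(4:25, 1))
    b <- rand_dna(sample(4:25, 1))
    expect_identical(longest_complementary_run(a, b),
                     as.integer(bf_longest_complementary_run(a, b)))
    expect_identical(longest_complementary_run(a, b),
                     longest_complementary_run(b, a))
  }
})

test_that("qc_report aggregates the region metrics deterministically", {
  r <- qc_report(its2_scaffold())
  expect_identical(r$read1$length, 32L)
  expect_identical(r$read2$length, 32L)
  expect_equal(r$read1$gc_fraction, 0.5)
  expect_identical(r$read1$max_self_dimer, 4L)
  expect_identical(r$max_cross_dimer, 4L)
  expect_identical(r, qc_report(its2_scaffold()))

  sp <- scaffold_spec("ACGT", "CCTGGTGCTG", "GT", "A",
                      "ACGT", "AGTCAGTCAG", "CC", "A")
  expect_identical(qc_report(sp)$read1$length, 13L)
})

test_that("index combinations form the full Cartesian product", {
  f1 <- index_set(c(a = "AAAAAAAA"), "forward")
  r1 <- index_set(c(b = "CCCCCCCC"), "reverse")
  expect_identical(nrow(enumerate_combinations(f1, r1)), 1L)

  f2 <- random_index_set(2, "forward", seed = 1)
  r3 <- random_index_set(3, "reverse", seed = 2)
  cmb <- enumerate_combinations(f2, r3)
  expect_identical(nrow(cmb), 6L)
  expect_false(anyDuplicated(paste(cmb$fwd_seq, cmb$rev_seq)) > 0)

  expect_error(index_set(c(x = "AAAAAAAA", y = "AAAAAAAA"), "forward"),
               "duplicate")
})
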