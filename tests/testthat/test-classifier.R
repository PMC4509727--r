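test_that("training statistics follow the prior and conditional formulas", {
  one <- reference_db("a", "ACGT",
                      data.frame(kingdom = "k1", phylum = "p1",
                                 class = "c1", order = "o1", family = "f1",
                                 genus = "g1", species = "s1"))
  m <- train_classifier(one, classifier_params(k = 2))
  # single record: n(w) = 1, N = 1 -> P(w) = 1.5/2 = 0.75 for each word
  expect_true(all(m$word_prior == 0.75))
  # P(w|leaf) = (1 + 0.75)/(1 + 1); stored as log, unseen row first
  expect_equal(unname(m$logp[2, 1]), log(1.75 / 2))

  dup <- reference_db(c("a", "b"), c("ACGTACGT", "ACGTACGT"),
                      rbind(c("k1", "p1", "c1", "o1", "f1", "g1", "s1"),
                            c("k1", "p1", "c1", "o1", "f1", "g1", "s1")))
  m2 <- train_classifier(dup, classifier_params(k = 4))
  expect_identical(m2$M, 2L)
  # both records contain each word: m(w) = 2, P(w) = 2.5/3
  expect_equal(unname(m2$logp[2, 1]), log((2 + 2.5 / 3) / 3))

  expect_error(train_classifier(toy_refdb()[0, ]), "empty")
  short <- reference_db(c("a", "b"), c("ACGTACGTACGT", "ACG"),
                        rbind(c("k1", "p1", "c1", "o1", "f1", "g1", "s1"),
                              c("k1", "p1", "c1", "o1", "f1", "g1", "s2")))
  expect_warning(m3 <- train_classifier(short, classifier_params(k = 8)),
                 "dropped")
  expect_identical(m3$N, 1L)
})

test_that("classifier scores equal brute-force naive Bayes enumeration", {
  set.seed(17)
  for (rep in 1:4) {
    n_leaf <- sample(2:5, 1)
    lin <- t(sapply(seq_len(n_leaf), function(i)
      c("k1", "p1", "c1", "o1", "f1", sprintf("g%d", (i + 1) %/% 2),
        sprintf("s%d", i))))
    db <- reference_db(sprintf("id%d", 1:n_leaf),
                       replicate(n_leaf, rand_dna(sample(30:50, 1))), lin)
    k <- sample(3:5, 1)
    model <- train_classifier(db, classifier_params(k = k))
    query <- rand_dna(40)
    expected <- bf_nb_scores(db, query, k)

    codes <- dualpollen:::kmer_codes(query, k)
    rows <- dualpollen:::.word_rows(codes, model)
    got <- colSums(model$logp[rows, , drop = FALSE])
    expect_equal(unname(got), unname(expected[model$leaves]),
                 tolerance = 1e-12)

    r <- classify(query, model, classifier_params(k = k))
    expect_identical(r$leaf, names(which.max(expected)))
    expect_equal(r$raw_score, max(expected) / length(codes),
                 tolerance = 1e-12)
  }
})

test_that("single-leaf models classify everything with full confidence", {
  one <- reference_db("a", rand_dna(60),
                      data.frame(kingdom = "k1", phylum = "p1",
                                 class = "c1", order = "o1", family = "f1",
                                 genus = "g1", species = "s1"))
  m <- train_classifier(one)
  r <- classify(rand_dna(40), m)
  expect_identical(r$leaf, "s1")
  expect_true(all(r$confidence == 1))
  expect_error(classify("ACGT", m), "shorter than k")
})

test_that("training sequences classify to their own leaf when leaves diverge", {
  p <- sim_params(genera_per_family = 3L, species_per_genus = 1L,
                  divergence = c(order = 0.3, family = 0.2, genus = 0.12,
                                 species = 0.05))
  db <- simulate_refdb(p, seed = 8)
  model <- train_classifier(db)
  set.seed(1)
  for (i in seq_len(nrow(db))) {
    r <- classify(db$sequence[i], model)
    expect_identical(r$leaf, db$species[i])
    expect_gte(r$confidence[["species"]], 0.95)
  }
})

test_that("confidence is non-increasing from kingdom to species", {
  db <- simulate_refdb(sim_params(), seed = 3)
  model <- train_classifier(db)
  set.seed(2)
  for (i in sample(nrow(db), 5)) {
    r <- classify(dualpollen:::.inject_errors(db$sequence[i], 0.02), model)
    expect_true(all(diff(r$confidence) <= 1e-12))
  }
})

test_that("the cutoff truncates low-confidence and low-score assignments", {
  res <- structure(list(
    ranks = setNames(c("k1", "p1", "c1", "o1", "f1", "g1", "s1"),
                     SEVEN_RANKS),
    confidence = setNames(c(1, 1, 1, 1, 1, 0.9, 0.4), SEVEN_RANKS),
    leaf = "s1", raw_score = -0.5, n_words = 100),
    class = "ClassificationResult")
  p <- classifier_params(min_confidence = 0.8)
  out <- apply_cutoff(res, p)
  expect_identical(unname(out[["genus"]]), "g1")
  expect_identical(unname(out[["species"]]), "unclassified_g1")

  res$confidence[] <- 1
  expect_identical(unname(apply_cutoff(res, p)), unname(res$ranks))

  res$raw_score <- -10
  out2 <- apply_cutoff(res, p)
  expect_identical(unname(out2[["phylum"]]), "unclassified_k1")
  expect_identical(unname(out2[["species"]]), "unclassified_k1")
})

test_that("classify_sample is seed-deterministic and order-invariant", {
  db <- toy_refdb()
  model <- train_classifier(db, classifier_params(k = 4))
  p <- classifier_params(k = 4, rng_seed = 7)
  reads <- data.frame(read_id = sprintf("r%d", 1:6),
                      seq = db$sequence[c(1, 2, 3, 4, 1, 3)],
                      stringsAsFactors = FALSE)
  a <- classify_sample(reads, model, p)
  b <- classify_sample(reads, model, p)
  expect_identical(a, b)
  perm <- c(4, 2, 6, 1, 5, 3)
  c_ <- classify_sample(reads[perm, ], model, p)
  rownames(c_) <- NULL
  expect_identical(c_, a[perm, ][, ] |> `rownames<-`(NULL))

  empty <- classify_sample(reads[0, ], model, p)
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("read_id", SEVEN_RANKS, "raw_score") %in%
                    names(empty)))
})
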