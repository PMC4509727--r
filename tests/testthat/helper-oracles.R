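# Independent brute-force oracles and small fixture builders. These are
# deliberately naive implementations, kept separate from the package's own
# algorithms so that the two routes cannot share a bug.

# longest common substring of a and revcomp(b) by enumeration of all
# substring pairs
bf_longest_complementary_run <- function(a, b) {
  rb <- dualpollen::revcomp(b)
  na <- nchar(a)
  nb <- nchar(rb)
  best <- 0L
  for (len in seq_len(min(na, nb))) {
    subs_a <- unique(substring(a, 1:(na - len + 1L), len:na))
    subs_b <- unique(substring(rb, 1:(nb - len + 1L), len:nb))
    if (any(subs_a %in% subs_b)) best <- len
  }
  best
}

# naive Bayes scores by direct enumeration over leaves and character
# k-mers, straight from the probability formulas
bf_nb_scores <- function(db, seq, k) {
  words_of <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1L), k:n))
  }
  train_words <- lapply(db$sequence, words_of)
  all_words <- unique(unlist(train_words))
  n_seq <- nrow(db)
  leaves <- sort(unique(db$species), method = "radix")
  q_words <- words_of(seq)
  scores <- sapply(leaves, function(lf) {
    in_leaf <- db$species == lf
    m_leaf <- sum(in_leaf)
    sum(sapply(q_words, function(w) {
      n_w <- sum(vapply(train_words, function(tw) w %in% tw, logical(1)))
      p_w <- (n_w + 0.5) / (n_seq + 1)
      m_w <- sum(vapply(train_words[in_leaf], function(tw) w %in% tw,
                        logical(1)))
      log((m_w + p_w) / (m_leaf + 1))
    }))
  })
  names(scores) <- leaves
  scores
}

# expected rarefied richness by exhaustive subset enumeration
bf_rarefy <- function(counts, depth) {
  pool <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(pool), depth)
  mean(apply(subs, 2L, function(i) length(unique(pool[i]))))
}

# tiny hand-built reference database: 4 species, 2 genera, one family
toy_refdb <- function() {
  lin <- function(g, s) c(kingdom = "k1", phylum = "p1", class = "c1",
                          order = "o1", family = "f1", genus = g,
                          species = s)
  reference_db(
    seq_id = c("r1", "r2", "r3", "r4"),
    sequence = c("ACGTACGTACGTACGTACGT",
                 "ACGTACGTACGTACGTATGT",
                 "TTTTCCCCGGGGAAAATTTT",
                 "TTTTCCCCGGGGAAAACTTT"),
    lineage = rbind(lin("gA", "sp1"), lin("gA", "sp2"),
                    lin("gB", "sp3"), lin("gB", "sp4")))
}

# random DNA string
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")
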