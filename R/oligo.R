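# Dual-indexed oligo scaffold: construction of amplification oligos and
# sequencing primers from component parts, plus the QC metrics reported for
# them (length, GC content, melting temperature, dimer complementarity).
#
# Scaffold layout (5' -> 3'):
#   adapter | 8-nt index | 10-nt pad | 2-nt linker | amplifying primer
# The pad and linker tune the melting temperature of the read-primer region
# (pad + linker + amplifying primer) to ~65 degrees C so that custom
# sequencing primers bind during the run.

#' Construct an oligo scaffold specification
#'
#' Validates and bundles the component parts of a dual-indexed amplification
#' oligo: MiSeq adapters, 10-nt pads, 2-nt linkers and the amplifying
#' primers for both the forward and the reverse scaffold.
#'
#' @param fwd_adapter,rev_adapter platform adapter sequences.
#' @param fwd_pad,rev_pad 10-nt pad sequences.
#' @param fwd_linker,rev_linker 2-nt linker sequences.
#' @param fwd_amp_primer,rev_amp_primer amplifying (marker) primers.
#' @return an object of class `ScaffoldSpec`.
#' @seealso [its2_scaffold()] for the ITS2 plant-barcoding default.
#' @export
scaffold_spec <- function(fwd_adapter, fwd_pad, fwd_linker, fwd_amp_primer,
                          rev_adapter, rev_pad, rev_linker, rev_amp_primer) {
  assert_dna(fwd_adapter, "fwd_adapter")
  assert_dna(rev_adapter, "rev_adapter")
  assert_dna(fwd_pad, "fwd_pad", len = 10L)
  assert_dna(rev_pad, "rev_pad", len = 10L)
  assert_dna(fwd_linker, "fwd_linker", len = 2L)
  assert_dna(rev_linker, "rev_linker", len = 2L)
  assert_dna(fwd_amp_primer, "fwd_amp_primer")
  assert_dna(rev_amp_primer, "rev_amp_primer")
  structure(
    list(fwd_adapter = fwd_adapter, fwd_pad = fwd_pad,
         fwd_linker = fwd_linker, fwd_amp_primer = fwd_amp_primer,
         rev_adapter = rev_adapter, rev_pad = rev_pad,
         rev_linker = rev_linker, rev_amp_primer = rev_amp_primer),
    class = "ScaffoldSpec")
}

#' The ITS2 dual-indexing scaffold
#'
#' The scaffold used for ITS2 plant meta-barcoding on the MiSeq: standard
#' Illumina adapters, a forward pad adjusted so that the combined
#' pad + linker + primer region melts near 65 degrees C, and the
#' ITS-S2F / ITS4R amplifying primer pair.
#'
#' @return a `ScaffoldSpec`.
#' @export
its2_scaffold <- function() {
  scaffold_spec(
    fwd_adapter    = "AATGATACGGCGACCACCGAGATCTACAC",
    fwd_pad        = "CCTGGTGCTG",
    fwd_linker     = "GT",
    fwd_amp_primer = "ATGCGATACTTGGTGTGAAT",
    rev_adapter    = "CAAGCAGAAGACGGCATACGAGAT",
    rev_pad        = "AGTCAGTCAG",
    rev_linker     = "CC",
    rev_amp_primer = "TCCTCCGCTTATTGATATGC")
}

#' @export
print.ScaffoldSpec <- function(x, ...) {
  cat("Oligo scaffold (adapter | index(8) | pad(10) | linker(2) | primer)\n")
  cat(sprintf("  forward: %s | XXXXXXXX | %s | %s | %s\n",
              x$fwd_adapter, x$fwd_pad, x$fwd_linker, x$fwd_amp_primer))
  cat(sprintf("  reverse: %s | XXXXXXXX | %s | %s | %s\n",
              x$rev_adapter, x$rev_pad, x$rev_linker, x$rev_amp_primer))
  invisible(x)
}

#' Build the full amplification oligos for one index pair
#'
#' Pure concatenation of the scaffold components around the given 8-nt
#' indices: `adapter | index | pad | linker | amplifying primer` for both
#' orientations. No other transformation is applied.
#'
#' @param spec a `ScaffoldSpec` (or a list with the same fields).
#' @param fwd_index,rev_index 8-nt index sequences.
#' @return named character vector with elements `forward` and `reverse`.
#' @export
build_sample_oligos <- function(spec, fwd_index, rev_index) {
  assert_dna(fwd_index, "fwd_index", len = 8L)
  assert_dna(rev_index, "rev_index", len = 8L)
  for (f in c("fwd_adapter", "fwd_pad", "fwd_linker", "fwd_amp_primer",
              "rev_adapter", "rev_pad", "rev_linker", "rev_amp_primer"))
    assert_dna(spec[[f]], f, allow_empty = TRUE)
  c(forward = paste0(spec$fwd_adapter, fwd_index, spec$fwd_pad,
                     spec$fwd_linker, spec$fwd_amp_primer),
    reverse = paste0(spec$rev_adapter, rev_index, spec$rev_pad,
                     spec$rev_linker, spec$rev_amp_primer))
}

#' Derive the custom sequencing primers from a scaffold
#'
#' Read1 is the forward pad + linker + amplifying primer, Read2 the reverse
#' equivalent, and the index sequencing primer is the base-wise reverse
#' complement of Read2.
#'
#' @param spec a `ScaffoldSpec`.
#' @return object of class `SequencingPrimerSet` with fields `read1`,
#'   `read2` and `index_primer`.
#' @export
derive_sequencing_primers <- function(spec) {
  if (!inherits(spec, "ScaffoldSpec"))
    spec <- do.call(scaffold_spec, spec[c(
      "fwd_adapter", "fwd_pad", "fwd_linker", "fwd_amp_primer",
      "rev_adapter", "rev_pad", "rev_linker", "rev_amp_primer")])
  read1 <- paste0(spec$fwd_pad, spec$fwd_linker, spec$fwd_amp_primer)
  read2 <- paste0(spec$rev_pad, spec$rev_linker, spec$rev_amp_primer)
  structure(list(read1 = read1, read2 = read2,
                 index_primer = revcomp(read2)),
            class = "SequencingPrimerSet")
}

#' GC fraction of a DNA sequence
#'
#' @param seq non-empty ACGT string.
#' @return (#G + #C) / length, in `[0, 1]`.
#' @export
gc_fraction <- function(seq) {
  assert_dna(seq, "seq")
  n <- nchar(seq)
  (n - nchar(gsub("[GC]", "", seq))) / n
}

# unified nearest-neighbor stacking parameters (SantaLucia 1998, unified
# oligonucleotide set): dH in kcal/mol, dS in cal/(mol K), keyed by the
# 5'->3' top-strand dinucleotide; complementary stacks share values.
.NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
            CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
            TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2,
            CC = -8.0)
.NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
            CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
            TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
            CC = -19.9)

#' Oligo melting temperature
#'
#' Three standard models:
#' \describe{
#'   \item{wallace}{`2(A+T) + 4(G+C)`; intended for oligos of at most
#'     14 nt, a warning is issued for longer input.}
#'   \item{marmur_doty}{`64.9 + 41 * (GC - 16.4) / length` (the GC-count
#'     form commonly used for primers around 14-70 nt). The default.}
#'   \item{nearest_neighbor}{unified nearest-neighbor thermodynamics
#'     (SantaLucia 1998 parameter set) with terminal initiation terms,
#'     `Tm = 1000 dH / (dS + R ln(C/4)) - 273.15 + 16.6 log10([Na+])`.}
#' }
#'
#' @param seq non-empty ACGT string.
#' @param model one of `"marmur_doty"`, `"wallace"`, `"nearest_neighbor"`.
#' @param salt_molar monovalent salt concentration (mol/L), nearest-neighbor
#'   model only.
#' @param oligo_molar total oligo concentration (mol/L), nearest-neighbor
#'   model only.
#' @return melting temperature in degrees Celsius.
#' @export
melting_temperature <- function(seq,
                                model = c("marmur_doty", "wallace",
                                          "nearest_neighbor"),
                                salt_molar = 0.05, oligo_molar = 2.5e-7) {
  assert_dna(seq, "seq")
  model <- match.arg(model)
  n <- nchar(seq)
  ngc <- n - nchar(gsub("[GC]", "", seq))
  switch(model,
    wallace = {
      if (n > 14L)
        warning("Wallace rule requested for an oligo longer than 14 nt")
      2 * (n - ngc) + 4 * ngc
    },
    marmur_doty = 64.9 + 41 * (ngc - 16.4) / n,
    nearest_neighbor = {
      stacks <- substring(seq, 1:(n - 1L), 2:n)
      dh <- sum(.NN_DH[stacks])
      ds <- sum(.NN_DS[stacks])
      for (term in c(substr(seq, 1L, 1L), substr(seq, n, n))) {
        if (term %in% c("G", "C")) {
          dh <- dh + 0.1; ds <- ds - 2.8
        } else {
          dh <- dh + 2.3; ds <- ds + 4.1
        }
      }
      1000 * dh / (ds + 1.987 * log(oligo_molar / 4)) - 273.15 +
        16.6 * log10(salt_molar)
    })
}

#' Longest antiparallel complementary stretch between two oligos
#'
#' Length of the longest contiguous Watson-Crick duplex two oligos can form
#' in antiparallel orientation, computed as the longest common substring
#' between `seq_a` and the reverse complement of `seq_b`. Call with
#' `seq_a == seq_b` for the self-dimer. G.T wobble pairs are not counted.
#'
#' @param seq_a,seq_b non-empty ACGT strings.
#' @return integer length in bp.
#' @export
longest_complementary_run <- function(seq_a, seq_b) {
  assert_dna(seq_a, "seq_a")
  assert_dna(seq_b, "seq_b")
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(revcomp(seq_b), "")[[1]]
  best <- 0L
  prev <- integer(length(a))
  for (j in seq_along(b)) {
    cur <- integer(length(a))
    hit <- a == b[j]
    cur[hit] <- c(0L, prev[-length(prev)])[hit] + 1L
    best <- max(best, cur)
    prev <- cur
  }
  as.integer(best)
}

#' QC report for the read-primer regions of a scaffold
#'
#' Computes, for each of the two read regions (Read1 = forward
#' pad + linker + primer, Read2 = reverse equivalent): length, GC fraction,
#' melting temperature and the longest self-complementary run; plus the
#' longest cross-complementary run between the two regions.
#'
#' @param spec a `ScaffoldSpec`.
#' @param tm_model melting-temperature model, see [melting_temperature()].
#' @param ... further arguments passed to [melting_temperature()].
#' @return object of class `OligoQCReport`: a list with elements `read1`,
#'   `read2` (each length/gc_fraction/tm_celsius/max_self_dimer) and
#'   `max_cross_dimer`.
#' @export
qc_report <- function(spec, tm_model = "marmur_doty", ...) {
  primers <- derive_sequencing_primers(spec)
  region <- function(s) {
    list(length = nchar(s),
         gc_fraction = gc_fraction(s),
         tm_celsius = melting_temperature(s, model = tm_model, ...),
         max_self_dimer = longest_complementary_run(s, s))
  }
  structure(
    list(read1 = region(primers$read1),
         read2 = region(primers$read2),
         max_cross_dimer = longest_complementary_run(primers$read1,
                                                     primers$read2)),
    class = "OligoQCReport")
}

#' @export
print.OligoQCReport <- function(x, ...) {
  fmt <- function(nm, r) {
    cat(sprintf("  %s: %d nt, GC %.1f%%, Tm %.2f C, self-dimer %d bp\n",
                nm, r$length, 100 * r$gc_fraction, r$tm_celsius,
                r$max_self_dimer))
  }
  cat("Read-primer region QC\n")
  fmt("read1", x$read1)
  fmt("read2", x$read2)
  cat(sprintf("  cross-dimer read1 x read2: %d bp\n", x$max_cross_dimer))
  invisible(x)
}

#' Construct a set of 8-nt sample indices
#'
#' @param seqs named character vector of 8-nt index sequences; unnamed input
#'   is auto-named from the orientation.
#' @param orientation `"forward"` or `"reverse"`.
#' @return an `IndexSet` (named character vector with an orientation
#'   attribute).
#' @export
index_set <- function(seqs, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  seqs <- unlist(seqs)
  if (length(seqs) == 0L) stop("index set is empty")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- sprintf("%s%03d",
                           if (orientation == "forward") "F" else "R",
                           500L + seq_along(seqs))
  for (i in seq_along(seqs))
    assert_dna(seqs[[i]], sprintf("index '%s'", names(seqs)[i]), len = 8L)
  if (anyDuplicated(names(seqs)))
    stop("duplicate index names in set")
  if (anyDuplicated(seqs))
    stop("duplicate index sequences in set")
  structure(seqs, orientation = orientation, class = "IndexSet")
}

#' Generate a synthetic index set
#'
#' Draws `n` distinct random 8-nt sequences; a stand-in for a plate of
#' ordered index oligos when exercising the workflow on simulated runs.
#'
#' @param n number of indices.
#' @param orientation `"forward"` or `"reverse"`.
#' @param seed RNG seed.
#' @return an `IndexSet`.
#' @export
random_index_set <- function(n, orientation = c("forward", "reverse"),
                             seed = 1L) {
  orientation <- match.arg(orientation)
  set.seed(seed)
  seqs <- character(0)
  while (length(seqs) < n) {
    more <- vapply(seq_len(n - length(seqs) + 4L), function(i)
      paste(sample(DNA_BASES, 8L, replace = TRUE), collapse = ""),
      character(1))
    seqs <- unique(c(seqs, more))
  }
  index_set(seqs[seq_len(n)], orientation)
}

#' Enumerate all forward x reverse index combinations
#'
#' The full Cartesian product of a forward and a reverse index set; one row
#' per sample-sheet entry. 16 forward and 24 reverse indices give the 384
#' combinations of a fully multiplexed run.
#'
#' @param fwd,rev `IndexSet` objects (or named character vectors of 8-nt
#'   sequences).
#' @return data.frame with columns `combo_id`, `fwd_name`, `fwd_seq`,
#'   `rev_name`, `rev_seq`; row count is `length(fwd) * length(rev)`.
#' @export
enumerate_combinations <- function(fwd, rev) {
  if (!inherits(fwd, "IndexSet")) fwd <- index_set(fwd, "forward")
  if (!inherits(rev, "IndexSet")) rev <- index_set(rev, "reverse")
  g <- expand.grid(r = seq_along(rev), f = seq_along(fwd))
  data.frame(
    combo_id = paste(names(fwd)[g$f], names(rev)[g$r], sep = "-"),
    fwd_name = names(fwd)[g$f],
    fwd_seq = unname(unclass(fwd)[g$f]),
    rev_name = names(rev)[g$r],
    rev_seq = unname(unclass(rev)[g$r]),
    stringsAsFactors = FALSE)
}

#' Turn enumerated index combinations into a sample sheet
#'
#' @param combos output of [enumerate_combinations()].
#' @param sample_ids sample names, one per combination row; defaults to the
#'   combination ids.
#' @return a `SampleSheet`, see [samplesheet()].
#' @export
combinations_to_samplesheet <- function(combos, sample_ids = combos$combo_id) {
  samplesheet(data.frame(sample_id = sample_ids,
                         fwd_index = combos$fwd_seq,
                         rev_index = combos$rev_seq,
                         stringsAsFactors = FALSE))
}
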