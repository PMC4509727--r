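# Seven-rank taxonomic reference databases: lineage normalization, taxonomy
# trees, attaching lineages to sequences, and serialization to the two
# classifier dialects (RDP training files and UTAX-annotated FASTA).

#' Normalize a seven-rank lineage
#'
#' Ensures every rank carries a value. Missing ranks (NA or empty) are
#' filled with `unclassified_<nearest named ancestor>`, where the nearest
#' named ancestor is the closest shallower rank holding a real (non
#' placeholder) name. The kingdom must always be named. Normalization is
#' idempotent.
#'
#' @param x character vector of length 7 (kingdom..species), or a
#'   data.frame/matrix with seven such columns (normalized row-wise).
#' @return named character vector (or data.frame) over [SEVEN_RANKS].
#' @export
normalize_lineage <- function(x) {
  if (is.data.frame(x) || is.matrix(x)) {
    m <- as.matrix(x)
    out <- t(apply(m, 1L, normalize_lineage))
    colnames(out) <- SEVEN_RANKS
    return(as.data.frame(out, stringsAsFactors = FALSE))
  }
  stopifnot(length(x) == 7L)
  x <- as.character(x)
  x[!is.na(x) & !nzchar(x)] <- NA_character_
  if (is.na(x[1L]) || startsWith(x[1L], UNCLASSIFIED_PREFIX))
    stop("kingdom rank must be named")
  last_named <- x[1L]
  for (i in 2:7) {
    if (is.na(x[i])) {
      x[i] <- paste0(UNCLASSIFIED_PREFIX, last_named)
    } else if (!startsWith(x[i], UNCLASSIFIED_PREFIX)) {
      last_named <- x[i]
    }
  }
  stats::setNames(x, SEVEN_RANKS)
}

#' Construct a reference database
#'
#' @param seq_id unique sequence identifiers.
#' @param sequence non-empty ACGT sequences (one per id).
#' @param lineage data.frame (or matrix) with the seven rank columns, one
#'   row per sequence; normalized on construction.
#' @return object of class `ReferenceDB`: a data.frame with columns
#'   `seq_id`, `sequence` and the seven ranks.
#' @export
reference_db <- function(seq_id, sequence, lineage) {
  seq_id <- as.character(seq_id)
  sequence <- as.character(sequence)
  stopifnot(length(seq_id) == length(sequence))
  if (anyDuplicated(seq_id)) stop("duplicate seq_id in reference database")
  if (length(seq_id) && any(!nzchar(sequence)))
    stop("empty sequence in reference database")
  if (length(seq_id) == 0L) {
    db <- as.data.frame(c(list(seq_id = character(0),
                               sequence = character(0)),
                          stats::setNames(rep(list(character(0)), 7L),
                                          SEVEN_RANKS)),
                        stringsAsFactors = FALSE)
  } else {
    lin <- normalize_lineage(as.data.frame(lineage,
                                           stringsAsFactors = FALSE))
    stopifnot(nrow(lin) == length(seq_id))
    db <- cbind(data.frame(seq_id = seq_id, sequence = sequence,
                           stringsAsFactors = FALSE), lin)
  }
  rownames(db) <- NULL
  class(db) <- c("ReferenceDB", "data.frame")
  db
}

#' @export
print.ReferenceDB <- function(x, ...) {
  cat(sprintf("ReferenceDB: %d sequences, %d species, %d genera\n",
              nrow(x), length(unique(x$species)), length(unique(x$genus))))
  invisible(x)
}

#' Construct a taxonomy tree
#'
#' @param nodes data.frame with columns `taxon_id`, `name`, `parent_id`,
#'   `rank` (and optionally `depth`, which is recomputed and checked).
#'   Exactly one root (self-parented) is required; the node set must be
#'   acyclic with `depth(child) = depth(parent) + 1`.
#' @return the node table with class `TaxTree` and a validated `depth`
#'   column.
#' @export
tax_tree <- function(nodes) {
  need <- c("taxon_id", "name", "parent_id", "rank")
  if (!all(need %in% names(nodes)))
    stop("taxonomy nodes must have columns: ", paste(need, collapse = ", "))
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  nodes$taxon_id <- as.integer(nodes$taxon_id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  if (anyDuplicated(nodes$taxon_id)) stop("duplicate taxon_id")
  root <- which(nodes$taxon_id == nodes$parent_id)
  if (length(root) != 1L)
    stop("taxonomy tree must have exactly one self-parented root")
  if (any(is.na(match(nodes$parent_id, nodes$taxon_id))))
    stop("parent_id refers to a missing node")
  depth <- rep(NA_integer_, nrow(nodes))
  depth[root] <- 0L
  frontier <- nodes$taxon_id[root]
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    child <- which(is.na(depth) & nodes$parent_id %in% frontier)
    depth[child] <- d
    frontier <- nodes$taxon_id[child]
  }
  if (anyNA(depth)) stop("taxonomy tree contains a cycle or orphan nodes")
  if (!is.null(nodes$depth) && !all(nodes$depth == depth))
    stop("stated depth does not satisfy depth(child) = depth(parent) + 1")
  nodes$depth <- depth
  class(nodes) <- c("TaxTree", "data.frame")
  nodes
}

#' Attach seven-rank lineages to sequences via a taxonomy tree
#'
#' For every sequence, its taxon id is looked up and the path to the root
#' walked, picking the names of the nodes whose rank is one of the seven
#' canonical levels (intermediate ranks such as subfamily or tribe are
#' skipped); missing ranks are filled with placeholders by
#' [normalize_lineage()]. Sequences without a taxonomy mapping are dropped
#' with a warning and counted in the `n_dropped` attribute.
#'
#' @param seqs named character vector: sequence id -> sequence.
#' @param id2tax named integer vector: sequence id -> taxon id.
#' @param tree a `TaxTree`.
#' @return a `ReferenceDB` with attribute `n_dropped`.
#' @export
assign_lineages <- function(seqs, id2tax, tree) {
  stopifnot(!is.null(names(seqs)))
  if (!inherits(tree, "TaxTree")) tree <- tax_tree(tree)
  ids <- names(seqs)
  tax <- id2tax[ids]
  keep <- !is.na(tax) & tax %in% tree$taxon_id
  n_dropped <- sum(!keep)
  if (n_dropped)
    warning(sprintf("%d sequence(s) dropped: no taxonomy mapping",
                    n_dropped))
  utax <- unique(tax[keep])
  lin_one <- function(tid) {
    out <- stats::setNames(rep(NA_character_, 7L), SEVEN_RANKS)
    cur <- tid
    repeat {
      i <- match(cur, tree$taxon_id)
      r <- tree$rank[i]
      if (r %in% SEVEN_RANKS && is.na(out[[r]])) out[[r]] <- tree$name[i]
      p <- tree$parent_id[i]
      if (p == cur) break
      cur <- p
    }
    out
  }
  lin_by_tax <- do.call(rbind, lapply(utax, lin_one))
  lin <- lin_by_tax[match(tax[keep], utax), , drop = FALSE]
  db <- reference_db(ids[keep], unname(seqs[keep]),
                     as.data.frame(lin, stringsAsFactors = FALSE))
  attr(db, "n_dropped") <- n_dropped
  db
}

# dialect delimiters are not allowed inside names
sanitize_name <- function(x) gsub("[;,:\t*]", "_", x)

.utax_header <- function(db) {
  sprintf("%s;tax=d:%s,p:%s,c:%s,o:%s,f:%s,g:%s,s:%s;",
          sanitize_name(db$seq_id),
          sanitize_name(db$kingdom), sanitize_name(db$phylum),
          sanitize_name(db$class), sanitize_name(db$order),
          sanitize_name(db$family), sanitize_name(db$genus),
          sanitize_name(db$species))
}

#' Write a reference database as UTAX-annotated FASTA
#'
#' Header dialect: `>seq_id;tax=d:K,p:P,c:C,o:O,f:F,g:G,s:S;` with dialect
#' delimiters (`; , : *` and tab) in names sanitized to `_`.
#'
#' @param db a `ReferenceDB`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_utax_fasta <- function(db, path) {
  x <- Biostrings::DNAStringSet(db$sequence)
  names(x) <- .utax_header(db)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a UTAX-annotated FASTA into a reference database
#'
#' Inverse of [write_utax_fasta()] on sanitized content.
#'
#' @param path FASTA path.
#' @return a `ReferenceDB`.
#' @export
read_utax_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L)
    return(reference_db(character(0), character(0), NULL))
  x <- Biostrings::readDNAStringSet(path)
  pat <- paste0("^(.+);tax=d:([^,;]*),p:([^,;]*),c:([^,;]*),o:([^,;]*),",
                "f:([^,;]*),g:([^,;]*),s:([^,;]*);\\s*$")
  m <- regexec(pat, names(x))
  parts <- regmatches(names(x), m)
  bad <- which(lengths(parts) != 9L)
  if (length(bad))
    stop(sprintf("malformed UTAX header at record %d: %s", bad[1L],
                 names(x)[bad[1L]]))
  parts <- do.call(rbind, parts)
  lin <- as.data.frame(parts[, 3:9, drop = FALSE],
                       stringsAsFactors = FALSE)
  names(lin) <- SEVEN_RANKS
  reference_db(parts[, 2L], as.character(x), lin)
}

#' Write RDP classifier training files
#'
#' Produces the star-delimited taxonomy file (`taxid*name*parent_taxid*
#' depth*rank`, a rooted tree over all distinct lineage prefixes plus a
#' Root node) and a training FASTA whose headers are
#' `>seq_id<TAB>Root;K;P;C;O;F;G;S`.
#'
#' @param db a `ReferenceDB`.
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with `taxonomy` and `fasta` paths and the
#'   `nodes` table.
#' @export
write_rdp_training <- function(db, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  lin <- as.matrix(db[SEVEN_RANKS])
  lin[] <- sanitize_name(lin)
  ids <- sanitize_name(db$seq_id)
  nodes <- data.frame(taxon_id = 0L, name = "Root", parent_id = 0L,
                      depth = 0L, rank = "rootrank",
                      stringsAsFactors = FALSE)
  prefix_id <- c(Root = 0L)
  next_id <- 1L
  if (nrow(lin)) {
    for (d in 1:7) {
      pref <- apply(lin[, 1:d, drop = FALSE], 1L, paste, collapse = ";")
      parent <- if (d == 1L) rep("Root", length(pref))
                else apply(lin[, 1:(d - 1L), drop = FALSE], 1L, paste,
                           collapse = ";")
      new <- !duplicated(pref) & !(pref %in% names(prefix_id))
      for (i in which(new)) {
        prefix_id[pref[i]] <- next_id
        nodes <- rbind(nodes, data.frame(
          taxon_id = next_id, name = lin[i, d],
          parent_id = prefix_id[[parent[i]]], depth = d,
          rank = SEVEN_RANKS[d], stringsAsFactors = FALSE))
        next_id <- next_id + 1L
      }
    }
  }
  tax_path <- file.path(outdir, "rdp_taxonomy.txt")
  writeLines(sprintf("%d*%s*%d*%d*%s", nodes$taxon_id, nodes$name,
                     nodes$parent_id, nodes$depth, nodes$rank), tax_path)
  fa_path <- file.path(outdir, "rdp_training.fasta")
  x <- Biostrings::DNAStringSet(db$sequence)
  names(x) <- paste0(ids, "\tRoot;", apply(lin, 1L, paste, collapse = ";"))
  Biostrings::writeXStringSet(x, fa_path)
  invisible(list(taxonomy = tax_path, fasta = fa_path, nodes = nodes))
}

#' Parse an RDP star-delimited taxonomy file
#'
#' @param path taxonomy file written by [write_rdp_training()].
#' @return a `TaxTree`.
#' @export
read_rdp_taxonomy <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "*", fixed = TRUE)
  bad <- which(lengths(parts) != 5L)
  if (length(bad))
    stop(sprintf("malformed taxonomy line %d: %s", bad[1L], lines[bad[1L]]))
  parts <- do.call(rbind, parts)
  tax_tree(data.frame(taxon_id = as.integer(parts[, 1L]),
                      name = parts[, 2L],
                      parent_id = as.integer(parts[, 3L]),
                      depth = as.integer(parts[, 4L]),
                      rank = parts[, 5L],
                      stringsAsFactors = FALSE))
}

#' Checklist coverage of a reference database
#'
#' Fraction of checklist names present in the database at a given rank,
#' by case-insensitive exact match. A genus-level query counts a genus as
#' covered if any database record carries it.
#'
#' @param db a `ReferenceDB`.
#' @param checklist non-empty character vector of species or genus names.
#' @param rank the rank at which to match (default `"species"`).
#' @return list with `rank`, `fraction`, `n_covered`, `n_checklist` and
#'   the logical `covered` vector (named by checklist entry).
#' @export
coverage_report <- function(db, checklist, rank = "species") {
  rank <- match.arg(rank, SEVEN_RANKS)
  if (length(checklist) == 0L) stop("checklist is empty")
  covered <- tolower(checklist) %in% tolower(db[[rank]])
  list(rank = rank,
       fraction = mean(covered),
       n_covered = sum(covered),
       n_checklist = length(checklist),
       covered = stats::setNames(covered, checklist))
}
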