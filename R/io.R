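#' Read assembled transcript contigs from a FASTA file
#'
#' Sequences are upper-cased and RNA `U` is mapped to `T`.  A "component"
#' (gene) identifier is parsed from each contig id: trinity-style assemblies
#' name isoforms of one component with a trailing isoform suffix, so by
#' default a trailing `_seqN` or `_iN` is stripped; ids without such a suffix
#' are their own component.
#'
#' @param path path to a FASTA file.
#' @param component_pattern regular expression removed from the end of each
#'   id to obtain the component id.
#' @return A `data.frame` with columns `id`, `component_id`, `sequence`,
#'   `length`, one row per contig, in file order.
#' @export
read_fasta <- function(path, component_pattern = "_(seq|i)[0-9]+$") {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(nchar(seqs) == 0)) {
    stop("empty sequence for id: ",
         paste(ids[nchar(seqs) == 0], collapse = ", "))
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-ACGTN characters in sequence: ",
         paste(ids[bad], collapse = ", "))
  }
  transcript_records(ids, seqs, component_pattern = component_pattern)
}

#' Construct a transcript record table
#'
#' @param id character vector of unique contig ids.
#' @param sequence character vector of nucleotide sequences over ACGTN.
#' @param component_id optional explicit component (gene) ids; if missing
#'   they are parsed from `id` with `component_pattern`.
#' @param component_pattern see [read_fasta()].
#' @return `data.frame` with `id`, `component_id`, `sequence`, `length`.
#' @export
transcript_records <- function(id, sequence, component_id = NULL,
                               component_pattern = "_(seq|i)[0-9]+$") {
  stopifnot(length(id) == length(sequence))
  if (anyDuplicated(id)) {
    stop("duplicate sequence id: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (is.null(component_id)) component_id <- sub(component_pattern, "", id)
  data.frame(id = as.character(id),
             component_id = as.character(component_id),
             sequence = as.character(sequence),
             length = nchar(sequence),
             stringsAsFactors = FALSE)
}

#' Write transcript records to FASTA
#'
#' @param records transcript record table (see [read_fasta()]).
#' @param path output file path.
#' @param width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

.outfmt6_cols <- c("query_id", "subject_id", "percent_identity",
                   "alignment_length", "mismatches", "gap_opens",
                   "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Read a tabular homology hit table (BLAST outfmt-6 dialect)
#'
#' Accepts 12 tab-separated columns in outfmt-6 order, optionally followed by
#' a 13th subject-taxon column.  Hits above the E-value threshold are
#' dropped, and per query only the `max_hits_per_query` highest-bitscore rows
#' are retained (ties broken by ascending E-value then subject id).
#' Alignment coordinates are kept in their native 1-based inclusive form.
#'
#' @param path path to the TSV file.
#' @param max_evalue E-value acceptance threshold (default 1e-3).
#' @param max_hits_per_query best hits retained per query (default 20).
#' @return `data.frame` of hits; `subject_taxon` is `NA` when no 13th column
#'   is present.
#' @export
read_hit_table <- function(path, max_evalue = 1e-3, max_hits_per_query = 20L) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  stopifnot(max_hits_per_query >= 1)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_hit_table())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 12 & nf != 13)
  if (length(bad)) {
    stop("malformed hit-table row (expected 12 or 13 columns) at line ",
         bad[1], " of ", path)
  }
  mat <- do.call(rbind, lapply(fields, function(f) f[1:13]))
  hits <- data.frame(
    query_id = mat[, 1], subject_id = mat[, 2],
    percent_identity = as.numeric(mat[, 3]),
    alignment_length = as.integer(mat[, 4]),
    mismatches = as.integer(mat[, 5]), gap_opens = as.integer(mat[, 6]),
    qstart = as.integer(mat[, 7]), qend = as.integer(mat[, 8]),
    sstart = as.integer(mat[, 9]), send = as.integer(mat[, 10]),
    evalue = as.numeric(mat[, 11]), bitscore = as.numeric(mat[, 12]),
    subject_taxon = mat[, 13],
    stringsAsFactors = FALSE)
  num_bad <- which(is.na(hits$evalue) | is.na(hits$bitscore) |
                     is.na(hits$alignment_length))
  if (length(num_bad)) {
    stop("malformed numeric field in hit table at line ", num_bad[1],
         " of ", path)
  }
  if (any(hits$evalue < 0) || any(hits$bitscore < 0)) {
    stop("negative evalue or bitscore in ", path)
  }
  filter_hit_table(hits, max_evalue = max_evalue,
                   max_hits_per_query = max_hits_per_query)
}

empty_hit_table <- function() {
  data.frame(query_id = character(), subject_id = character(),
             percent_identity = numeric(), alignment_length = integer(),
             mismatches = integer(), gap_opens = integer(),
             qstart = integer(), qend = integer(),
             sstart = integer(), send = integer(),
             evalue = numeric(), bitscore = numeric(),
             subject_taxon = character(), stringsAsFactors = FALSE)
}

#' Apply E-value and best-hits-per-query filters to a hit table
#'
#' @inheritParams read_hit_table
#' @param hits a hit table `data.frame`.
#' @return filtered hit table, sorted by query then descending bitscore.
#' @export
filter_hit_table <- function(hits, max_evalue = 1e-3, max_hits_per_query = 20L) {
  hits <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  if (nrow(hits) == 0) return(hits)
  ord <- order(hits$query_id, -hits$bitscore, hits$evalue, hits$subject_id)
  hits <- hits[ord, , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(hits)), hits$query_id), function(i) {
    i[seq_len(min(length(i), max_hits_per_query))]
  }), use.names = FALSE)
  hits <- hits[sort(keep), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Assembly summary statistics
#'
#' N50 is the length `L`, taken from the observed length multiset, such that
#' contigs of length >= `L` contain at least half of all assembled bases
#' (largest-first cumulative scan).  GC percentage counts G+C over
#' A+C+G+T; ambiguity bases (`N`) count toward contig length but are
#' excluded from the GC denominator.
#'
#' @param records transcript record table.
#' @param min_len contigs shorter than this are excluded (default 200 bp,
#'   the usual reporting cutoff for trinity assemblies).
#' @return list with `n_contigs`, `mean_len`, `median_len`, `n50`,
#'   `max_len`, `min_len`, `gc_percent`, `total_bp`.
#' @export
assembly_stats <- function(records, min_len = 200L) {
  records <- records[records$length >= min_len, , drop = FALSE]
  if (nrow(records) == 0) stop("no contigs of length >= ", min_len)
  len <- sort(records$length, decreasing = TRUE)
  total <- sum(as.double(len))
  n50 <- len[which(cumsum(as.double(len)) >= total / 2)[1]]
  base_counts <- colSums(Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(records$sequence))[, c("A", "C", "G", "T"),
                                                drop = FALSE])
  gc <- 100 * (base_counts[["G"]] + base_counts[["C"]]) / sum(base_counts)
  list(n_contigs = nrow(records),
       mean_len = mean(records$length),
       median_len = stats::median(records$length),
       n50 = n50,
       max_len = max(records$length),
       min_len = min(records$length),
       gc_percent = gc,
       total_bp = total)
}

#' Coding transcriptome size range
#'
#' The coding fraction of an assembly can be delimited either by homology
#' (blastx-positive contigs) or by the Markov ORF classifier; the two sets
#' differ, so the coding transcriptome size is reported as a range over the
#' two definitions, in Mbp.
#'
#' @param blast_positive_ids,markov_positive_ids character vectors of contig
#'   ids (subsets of `records$id`).
#' @param records transcript record table.
#' @return numeric vector `c(low_mbp, high_mbp)`.
#' @export
coding_size_range <- function(blast_positive_ids, markov_positive_ids, records) {
  for (ids in list(blast_positive_ids, markov_positive_ids)) {
    missing <- setdiff(ids, records$id)
    if (length(missing)) {
      stop("ids not present in records: ", paste(missing, collapse = ", "))
    }
  }
  tot <- function(ids) sum(as.double(records$length[records$id %in% ids])) / 1e6
  sizes <- c(tot(blast_positive_ids), tot(markov_positive_ids))
  c(min(sizes), max(sizes))
}

#' Read a taxonomy from nodes and names tables
#'
#' @param nodes_path TSV with columns `taxon_id`, `parent_id`, `rank`
#'   (no header).  The root points to itself.
#' @param names_path TSV with columns `taxon_id`, `name` (no header).
#' @return `data.frame` with `taxon_id`, `parent_id`, `rank`, `name`.
#' @export
read_taxonomy <- function(nodes_path, names_path) {
  nodes <- utils::read.table(nodes_path, sep = "\t", header = FALSE,
                             colClasses = "character", quote = "",
                             col.names = c("taxon_id", "parent_id", "rank"))
  nm <- utils::read.table(names_path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "",
                          col.names = c("taxon_id", "name"))
  tax <- merge(nodes, nm, by = "taxon_id", all.x = TRUE, sort = FALSE)
  validate_taxonomy(tax)
  tax
}

#' Validate a taxonomy table
#'
#' Checks id uniqueness, parent resolvability and the absence of cycles
#' (every parent chain must reach the root, which points to itself).
#'
#' @param taxonomy taxonomy `data.frame` (`taxon_id`, `parent_id`, ...).
#' @return `taxonomy`, invisibly.
#' @export
validate_taxonomy <- function(taxonomy) {
  if (anyDuplicated(taxonomy$taxon_id)) stop("duplicate taxon_id in taxonomy")
  unknown <- setdiff(taxonomy$parent_id, taxonomy$taxon_id)
  if (length(unknown)) {
    stop("parent_id not present as taxon_id: ", paste(unknown, collapse = ", "))
  }
  roots <- taxonomy$taxon_id[taxonomy$taxon_id == taxonomy$parent_id]
  if (length(roots) != 1) stop("taxonomy must have exactly one root")
  parent <- stats::setNames(taxonomy$parent_id, taxonomy$taxon_id)
  for (t in taxonomy$taxon_id) {
    seen <- character()
    while (t != parent[[t]]) {
      if (t %in% seen) stop("cycle in taxonomy at taxon ", t)
      seen <- c(seen, t)
      t <- parent[[t]]
    }
  }
  invisible(taxonomy)
}

#' Read a rooted Newick tree
#'
#' @param path Newick file.
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick tree from ", path)
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf names in ", path)
  if (!ape::is.rooted(tree)) stop("tree in ", path, " is not rooted")
  tree
}

#' Read a gene-by-sample count matrix
#'
#' @param path TSV with a header line: `gene_id` followed by one column per
#'   sample; counts must be non-negative integers.
#' @return integer matrix with gene ids as row names.
#' @export
read_counts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, quote = "")
  if (ncol(df) < 2) stop("count table needs a gene_id column plus >= 1 sample")
  if (anyDuplicated(df[[1]])) stop("duplicate gene_id in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (any(is.na(m)) || any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers in ", path)
  }
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write a data.frame or matrix as TSV
#'
#' @param x data.frame or matrix; matrices are written with a leading
#'   row-name column.
#' @param path output path.
#' @param col_names write a header line (`FALSE` for headerless formats
#'   such as outfmt-6 hit tables).
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, col_names = TRUE) {
  if (is.matrix(x)) {
    x <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = col_names)
  invisible(path)
}

#' Load a JSON configuration file
#'
#' @param path JSON file.
#' @return named list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Log a pipeline message to stderr
#'
#' @param ... message parts, pasted together.
#' @keywords internal
log_msg <- function(...) {
  message("[polymorphome] ", ...)
}
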