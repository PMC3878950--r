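## MEGAN-style lowest-common-ancestor assignment of contigs from homology
## hit tables, bottom-up minimum-support promotion, and the host
## ("spider") vs meta-transcriptome split.

#' Default LCA parameters
#'
#' The standard MEGAN-style settings for LCA binning of blastx hits:
#' minimum support 5, minimum bitscore 35.0, top-percent window 10.0 and
#' minimum query complexity 0.3.
#'
#' @param min_support minimum number of queries a taxon must collect
#'   (including its descendants) to retain them.
#' @param min_score minimum hit bitscore.
#' @param top_percent hits scoring below `(1 - top_percent/100)` of the best
#'   bitscore for a query are discarded.
#' @param min_complexity minimum normalized mononucleotide entropy of the
#'   query sequence.
#' @return named list of parameters.
#' @export
lca_params <- function(min_support = 5L, min_score = 35.0,
                       top_percent = 10.0, min_complexity = 0.3) {
  stopifnot(min_support >= 1, top_percent >= 0, top_percent <= 100,
            min_complexity >= 0, min_complexity <= 1)
  list(min_support = as.integer(min_support), min_score = min_score,
       top_percent = top_percent, min_complexity = min_complexity)
}

#' Normalized mononucleotide sequence complexity
#'
#' Shannon entropy of the A/C/G/T composition divided by log 4, so the
#' value lies in \[0, 1\]: 0 for a single-letter sequence, 1 for a uniform
#' composition.  `N` bases are ignored; a sequence with no unambiguous
#' bases has complexity 0.
#'
#' @param sequence nucleotide string.
#' @return complexity in \[0, 1\].
#' @export
sequence_complexity <- function(sequence) {
  stopifnot(nchar(sequence) >= 1)
  counts <- Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(sequence))[1, c("A", "C", "G", "T")]
  total <- sum(counts)
  if (total == 0) return(0)
  p <- counts[counts > 0] / total
  as.numeric(-sum(p * log(p)) / log(4))
}

## named vector taxon -> parent for fast chain walking
taxonomy_parents <- function(taxonomy) {
  stats::setNames(taxonomy$parent_id, taxonomy$taxon_id)
}

#' Path from a taxon to the root
#'
#' @param taxon_id a taxon id.
#' @param taxonomy taxonomy table (see [read_taxonomy()]).
#' @return character vector of taxon ids from `taxon_id` up to and
#'   including the root.
#' @export
taxon_path <- function(taxon_id, taxonomy) {
  parent <- taxonomy_parents(taxonomy)
  if (!taxon_id %in% names(parent)) {
    stop("taxon not in taxonomy: ", taxon_id)
  }
  path <- taxon_id
  while (taxon_id != parent[[taxon_id]]) {
    taxon_id <- parent[[taxon_id]]
    path <- c(path, taxon_id)
  }
  path
}

#' Lowest common ancestor of a set of taxa
#'
#' @param taxon_ids character vector of taxon ids.
#' @inheritParams taxon_path
#' @return the taxon id of the LCA.
#' @export
taxonomy_lca <- function(taxon_ids, taxonomy) {
  taxon_ids <- unique(taxon_ids)
  path <- rev(taxon_path(taxon_ids[1], taxonomy))
  for (t in taxon_ids[-1]) {
    p <- rev(taxon_path(t, taxonomy))
    k <- min(length(path), length(p))
    eq <- path[seq_len(k)] == p[seq_len(k)]
    path <- path[seq_len(max(which(eq)))]
  }
  path[length(path)]
}

#' Assign one query to a taxon by the LCA rule (support-unaware stage)
#'
#' Queries below the complexity threshold are left unassigned.  Hits with
#' bitscore below `min_score`, or below `(1 - top_percent/100)` times the
#' query's best bitscore, are discarded; the query is assigned to the
#' lowest common ancestor of the remaining hit taxa.
#'
#' @param query_hits hit-table rows for a single query (must include
#'   `subject_taxon` and `bitscore`).
#' @param taxonomy taxonomy table.
#' @param params list from [lca_params()].
#' @param query_sequence the query's nucleotide sequence (used for the
#'   complexity filter); pass `NULL` to skip that filter.
#' @return list with `query_id`, `taxon_id` (`NA` when unassigned) and
#'   `n_hits_used`.
#' @export
assign_lca <- function(query_hits, taxonomy, params = lca_params(),
                       query_sequence = NULL) {
  qid <- unique(query_hits$query_id)
  if (length(qid) != 1) stop("assign_lca expects hits for exactly one query")
  unassigned <- list(query_id = qid, taxon_id = NA_character_,
                     n_hits_used = 0L)
  if (!is.null(query_sequence) &&
      sequence_complexity(query_sequence) < params$min_complexity) {
    return(unassigned)
  }
  hits <- query_hits[query_hits$bitscore >= params$min_score, , drop = FALSE]
  if (nrow(hits) == 0) return(unassigned)
  cutoff <- (1 - params$top_percent / 100) * max(hits$bitscore)
  hits <- hits[hits$bitscore >= cutoff, , drop = FALSE]
  missing <- setdiff(hits$subject_taxon, taxonomy$taxon_id)
  if (length(missing)) {
    stop("hit taxon absent from taxonomy: ", paste(missing, collapse = ", "))
  }
  list(query_id = qid,
       taxon_id = taxonomy_lca(hits$subject_taxon, taxonomy),
       n_hits_used = nrow(hits))
}

#' LCA-assign every query in a hit table
#'
#' @param hits full hit table (possibly many queries).
#' @param taxonomy taxonomy table.
#' @param params list from [lca_params()].
#' @param records optional transcript record table supplying query
#'   sequences for the complexity filter; queries absent from it skip the
#'   filter.
#' @param apply_support apply the bottom-up minimum-support promotion
#'   (default `TRUE`).
#' @return `data.frame` with `query_id`, `taxon_id` (`NA` = unassigned),
#'   `n_hits_used`.
#' @export
assign_lca_all <- function(hits, taxonomy, params = lca_params(),
                           records = NULL, apply_support = TRUE) {
  res <- lapply(split(hits, hits$query_id), function(qh) {
    qid <- qh$query_id[1]
    seq <- if (!is.null(records) && qid %in% records$id) {
      records$sequence[match(qid, records$id)]
    }
    as.data.frame(assign_lca(qh, taxonomy, params, seq),
                  stringsAsFactors = FALSE)
  })
  assignments <- do.call(rbind, res)
  rownames(assignments) <- NULL
  if (apply_support) {
    assignments <- apply_min_support(assignments, taxonomy,
                                     params$min_support)
  }
  assignments
}

#' Promote under-supported assignments up the taxonomy
#'
#' Working from the deepest taxa upward, any taxon whose total number of
#' assigned queries (its own plus those of all descendants) is below
#' `min_support` has its queries promoted to its parent.  Queries that
#' reach the root without ever meeting the support threshold become
#' unassigned.  Processing leaves-first makes the result order-independent.
#'
#' @param assignments `data.frame` from [assign_lca_all()].
#' @param taxonomy taxonomy table.
#' @param min_support support threshold (>= 1).
#' @return the assignments with `taxon_id` promoted where necessary.
#' @export
apply_min_support <- function(assignments, taxonomy, min_support = 5L) {
  if (min_support <= 1) return(assignments)
  parent <- taxonomy_parents(taxonomy)
  depth <- vapply(taxonomy$taxon_id,
                  function(t) length(taxon_path(t, taxonomy)), numeric(1))
  root <- taxonomy$taxon_id[taxonomy$taxon_id == taxonomy$parent_id]
  ## total queries at-or-below each taxon (stable under promotion toward root)
  subtree_count <- function(assigned) {
    counts <- stats::setNames(numeric(nrow(taxonomy)), taxonomy$taxon_id)
    for (t in assigned[!is.na(assigned)]) {
      for (p in taxon_path(t, taxonomy)) counts[[p]] <- counts[[p]] + 1
    }
    counts
  }
  counts <- subtree_count(assignments$taxon_id)
  for (t in names(sort(depth, decreasing = TRUE))) {
    if (t == root) next
    if (counts[[t]] > 0 && counts[[t]] < min_support) {
      idx <- which(!is.na(assignments$taxon_id) & assignments$taxon_id == t)
      assignments$taxon_id[idx] <- parent[[t]]
      counts[[t]] <- 0
    }
  }
  if (counts[[root]] > 0 && counts[[root]] < min_support) {
    assignments$taxon_id[!is.na(assignments$taxon_id) &
                           assignments$taxon_id == root] <- NA_character_
  }
  assignments
}

#' Split assigned queries into host ("spider") and meta-transcriptome sets
#'
#' Host sequences are those assigned within `keep_clade` (Metazoa by
#' default) and not within any of `exclude_clades` (Nematoda by default,
#' since these spiders are commonly parasitized by mermithid nematodes);
#' every other assigned query belongs to the meta-transcriptome.
#'
#' @param assignments `data.frame` from [assign_lca_all()].
#' @param taxonomy taxonomy table.
#' @param keep_clade clade name whose members count as host.
#' @param exclude_clades clade names carved out of `keep_clade`.
#' @return list with `spider_ids`, `meta_ids`, `unassigned_ids` — a
#'   partition of the query ids.
#' @export
split_spider_meta <- function(assignments, taxonomy, keep_clade = "Metazoa",
                              exclude_clades = "Nematoda") {
  name_to_id <- function(nm) {
    id <- taxonomy$taxon_id[taxonomy$name == nm]
    if (length(id) != 1) stop("clade name not resolvable in taxonomy: ", nm)
    id
  }
  keep_id <- name_to_id(keep_clade)
  excl_ids <- vapply(exclude_clades, name_to_id, character(1))
  unassigned <- is.na(assignments$taxon_id)
  in_clade <- function(taxon, clade) clade %in% taxon_path(taxon, taxonomy)
  is_spider <- vapply(seq_len(nrow(assignments)), function(i) {
    if (unassigned[i]) return(FALSE)
    t <- assignments$taxon_id[i]
    in_clade(t, keep_id) && !any(vapply(excl_ids, function(e)
      in_clade(t, e), logical(1)))
  }, logical(1))
  list(spider_ids = assignments$query_id[is_spider],
       meta_ids = assignments$query_id[!is_spider & !unassigned],
       unassigned_ids = assignments$query_id[unassigned])
}
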