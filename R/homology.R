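## Best-hit logic, reciprocal-best-hit orthology, the unique-best-hit
## fragmentation statistic and annotation keyword searches.

#' Best hit of a query in a hit table
#'
#' Maximum bitscore; ties broken by minimum E-value, then lexicographically
#' smallest subject id, so the result is deterministic.
#'
#' @param hit_table hit table `data.frame` (already filtered to the
#'   relevant E-value threshold).
#' @param query_id the query.
#' @return the best hit row, or `NULL` when the query has no hits.
#' @export
best_hit <- function(hit_table, query_id) {
  h <- hit_table[hit_table$query_id == query_id, , drop = FALSE]
  if (nrow(h) == 0) return(NULL)
  h <- h[order(-h$bitscore, h$evalue, h$subject_id), , drop = FALSE]
  h[1, , drop = FALSE]
}

## best-hit subject for every query at once; data.frame(query_id, subject_id,
## bitscore, evalue)
best_hits_all <- function(hit_table) {
  if (nrow(hit_table) == 0) {
    return(data.frame(query_id = character(), subject_id = character(),
                      bitscore = numeric(), evalue = numeric(),
                      stringsAsFactors = FALSE))
  }
  h <- hit_table[order(hit_table$query_id, -hit_table$bitscore,
                       hit_table$evalue, hit_table$subject_id), , drop = FALSE]
  h <- h[!duplicated(h$query_id),
         c("query_id", "subject_id", "bitscore", "evalue"), drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Reciprocal best hits between two sequence sets
#'
#' A pair (a, b) is reported iff b is the best hit of a in the A-to-B table
#' and a is the best hit of b in the B-to-A table, both at E-value at most
#' `max_evalue`.  Each id occurs in at most one pair.
#'
#' @param table_ab hits of A-queries against B-subjects.
#' @param table_ba hits of B-queries against A-subjects.
#' @param max_evalue acceptance threshold (default 1e-5, the usual
#'   reciprocal-blast cutoff).
#' @return `data.frame` with `a_id`, `b_id`, `ab_bitscore`, `ba_bitscore`,
#'   sorted by `a_id`.
#' @export
reciprocal_best_hits <- function(table_ab, table_ba, max_evalue = 1e-5) {
  ab <- best_hits_all(table_ab[table_ab$evalue <= max_evalue, , drop = FALSE])
  ba <- best_hits_all(table_ba[table_ba$evalue <= max_evalue, , drop = FALSE])
  if (nrow(ab) == 0 || nrow(ba) == 0) {
    return(data.frame(a_id = character(), b_id = character(),
                      ab_bitscore = numeric(), ba_bitscore = numeric(),
                      stringsAsFactors = FALSE))
  }
  back <- ba$subject_id[match(ab$subject_id, ba$query_id)]
  keep <- !is.na(back) & back == ab$query_id
  res <- data.frame(a_id = ab$query_id[keep], b_id = ab$subject_id[keep],
                    ab_bitscore = ab$bitscore[keep],
                    ba_bitscore = ba$bitscore[match(ab$subject_id[keep],
                                                    ba$query_id)],
                    stringsAsFactors = FALSE)
  res <- res[order(res$a_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Unique-best-hit fragmentation statistic
#'
#' Among queries of length >= `min_len` that have at least one hit, a query
#' is a *unique* best hit when its best-hit subject protein is not the best
#' hit of any other retained query.  A low fraction indicates that many
#' contigs are fragments of the same gene; comparing the fraction at
#' different length cutoffs indexes how fragmented the short contigs are.
#'
#' @param hit_table hit table.
#' @param contig_lengths named integer vector, `names` = query ids; must
#'   cover every query in the table.
#' @param min_len length cutoff in bp.
#' @return list with `n_unique`, `n_with_hits`, `fraction`.
#' @export
unique_best_hit_fraction <- function(hit_table, contig_lengths, min_len = 200L) {
  queries <- unique(hit_table$query_id)
  missing <- setdiff(queries, names(contig_lengths))
  if (length(missing)) {
    stop("missing contig length for query: ", paste(missing, collapse = ", "))
  }
  keep <- queries[contig_lengths[queries] >= min_len]
  bests <- best_hits_all(hit_table[hit_table$query_id %in% keep, , drop = FALSE])
  n <- nrow(bests)
  if (n == 0) return(list(n_unique = 0L, n_with_hits = 0L, fraction = NaN))
  shared <- table(bests$subject_id)
  n_unique <- sum(shared[bests$subject_id] == 1)
  list(n_unique = as.integer(n_unique), n_with_hits = n,
       fraction = n_unique / n)
}

#' Keyword search against annotation descriptions
#'
#' Case-insensitive substring match of each keyword against the free-text
#' description of every annotated sequence (non-exact-match search, so
#' "pterin" matches "sepiapterin reductase").
#'
#' @param annotation_table `data.frame` with columns `id` and `description`.
#' @param keywords non-empty character vector of keywords.
#' @return `data.frame` with `id`, `keyword` — one row per (id, matched
#'   keyword) pair.
#' @export
keyword_search <- function(annotation_table, keywords) {
  if (length(keywords) == 0) stop("keyword list is empty")
  desc <- tolower(annotation_table$description)
  out <- lapply(keywords, function(kw) {
    hit <- grepl(tolower(kw), desc, fixed = TRUE)
    if (!any(hit)) return(NULL)
    data.frame(id = annotation_table$id[hit], keyword = kw,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(id = character(), keyword = character(),
                      stringsAsFactors = FALSE)
  }
  res[order(res$id, res$keyword), , drop = FALSE]
}

#' Pigment-panel detection report
#'
#' For each gene of a query panel, reports whether its query protein was
#' confirmed by reciprocal best hit (`RBH`), detected by a one-way forward
#' hit only (`ONE_WAY`), or not detected at all (`NOT_DETECTED`) —
#' mirroring the double-arrow / single-arrow / NA notation of
#' pigment-pathway survey tables.
#'
#' @param rbh_pairs `data.frame` from [reciprocal_best_hits()]; `a_id` must
#'   be the panel-protein side.
#' @param one_way_hits forward hit table (panel protein as query).
#' @param panel `data.frame` with `symbol`, `pathway`, `query_id`.
#' @param query_ids optional character vector of all protein ids that were
#'   actually searched; when supplied, a panel entry outside it is an error.
#' @return the panel with an added `status` column.
#' @export
rbh_panel_report <- function(rbh_pairs, one_way_hits, panel,
                             query_ids = NULL) {
  required <- c("symbol", "pathway", "query_id")
  stopifnot(all(required %in% names(panel)))
  if (!is.null(query_ids)) {
    missing <- setdiff(panel$query_id, query_ids)
    if (length(missing)) {
      stop("panel query id not in the searched query set: ",
           paste(missing, collapse = ", "))
    }
  }
  panel$status <- ifelse(
    panel$query_id %in% rbh_pairs$a_id, "RBH",
    ifelse(panel$query_id %in% one_way_hits$query_id, "ONE_WAY",
           "NOT_DETECTED"))
  panel
}
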