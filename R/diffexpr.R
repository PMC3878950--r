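## Housekeeping-gene-anchored differential expression for a replicate-free
## pooled design: HK gene selection, HK-total normalization, HK-based common
## negative-binomial dispersion, an exact conditional NB test, BH FDR and
## the +/- 2 SD housekeeping fold-change band.

#' Select valid housekeeping genes
#'
#' A candidate housekeeping protein is valid when its transcriptome hits
#' fall in exactly one component (gene) in *each* species, and the match is
#' confirmed by reciprocal best hit in both species.  Candidates hitting
#' several components, or missing from either species, are dropped.
#'
#' @param hits_a,hits_b hit tables of the candidate proteins (queries)
#'   against the transcriptome of species A / B (subjects are transcript
#'   ids).
#' @param components_a,components_b named character vectors mapping
#'   transcript id to component id in each species.
#' @param rbh_a,rbh_b reciprocal-best-hit tables
#'   (see [reciprocal_best_hits()]) with `a_id` = candidate protein and
#'   `b_id` = spider component id.
#' @return `data.frame` with `candidate_id`, `component_a`, `component_b`,
#'   `rbh_verified`; the final HK set is the subset with
#'   `rbh_verified == TRUE`.
#' @export
select_hk_genes <- function(hits_a, hits_b, components_a, components_b,
                            rbh_a, rbh_b) {
  comp_hits <- function(hits, components) {
    missing <- setdiff(hits$subject_id, names(components))
    if (length(missing)) {
      stop("transcript without component mapping: ",
           paste(missing, collapse = ", "))
    }
    comps <- components[hits$subject_id]
    lapply(split(comps, hits$query_id), unique)
  }
  ca <- comp_hits(hits_a, components_a)
  cb <- comp_hits(hits_b, components_b)
  shared <- intersect(names(ca), names(cb))
  single <- shared[lengths(ca[shared]) == 1 & lengths(cb[shared]) == 1]
  if (length(single) == 0) {
    return(data.frame(candidate_id = character(), component_a = character(),
                      component_b = character(), rbh_verified = logical(),
                      stringsAsFactors = FALSE))
  }
  comp_a <- vapply(ca[single], identity, character(1))
  comp_b <- vapply(cb[single], identity, character(1))
  verified <- function(rbh, cand, comp) {
    any(rbh$a_id == cand & rbh$b_id == comp)
  }
  rbh_ok <- vapply(seq_along(single), function(i) {
    verified(rbh_a, single[i], comp_a[i]) && verified(rbh_b, single[i], comp_b[i])
  }, logical(1))
  res <- data.frame(candidate_id = single, component_a = unname(comp_a),
                    component_b = unname(comp_b), rbh_verified = rbh_ok,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Housekeeping normalization factors
#'
#' Per-sample scaling factors proportional to each sample's total count
#' over the housekeeping genes, rescaled to geometric mean 1.  Dividing a
#' sample's counts by its factor equalizes the HK totals across samples,
#' which is the normalization anchor when no biological replicates exist.
#'
#' @param counts gene-by-sample count matrix.
#' @param hk_ids housekeeping gene ids (non-empty, present in `counts`).
#' @return named numeric vector of factors, one per sample.
#' @export
hk_normalization_factors <- function(counts, hk_ids) {
  if (length(hk_ids) == 0) stop("housekeeping set is empty")
  missing <- setdiff(hk_ids, rownames(counts))
  if (length(missing)) {
    stop("housekeeping genes absent from count matrix: ",
         paste(missing, collapse = ", "))
  }
  totals <- colSums(counts[hk_ids, , drop = FALSE])
  if (any(totals == 0)) {
    stop("sample with zero housekeeping total: ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  }
  totals / exp(mean(log(totals)))
}

#' Normalize counts by per-sample factors
#'
#' @param counts count matrix.
#' @param factors factors from [hk_normalization_factors()].
#' @return matrix of normalized (generally non-integer) counts.
#' @export
normalize_counts <- function(counts, factors) {
  sweep(counts, 2, factors, "/")
}

## negative-binomial conditional log-likelihood of a group of equalized
## counts given their total, summed over genes; y is a genes x samples
## matrix, r = 1/phi per sample
nb_conditional_loglik <- function(y, r) {
  n <- ncol(y)
  z <- rowSums(y)
  rowSums(lgamma(y + r)) - n * lgamma(r) - rowSums(lgamma(y + 1)) -
    (lgamma(z + n * r) - lgamma(n * r) - lgamma(z + 1))
}

#' Estimate the common negative-binomial dispersion from housekeeping genes
#'
#' Maximizes, over the dispersion `phi` (variance = mu + phi * mu^2), the
#' sum across housekeeping genes of the NB conditional log-likelihood of
#' the within-class counts given their class totals, after the libraries
#' are equalized by the normalization factors.  The maximization is a
#' bounded one-dimensional search of `phi` in \[1e-6, 10\].
#'
#' @param counts count matrix.
#' @param hk_ids housekeeping gene ids.
#' @param factors per-sample normalization factors.
#' @param groups factor/character vector of sample classes (e.g. Yellow /
#'   Colored); only classes with >= 2 samples contribute.
#' @return list with `phi` and `n_genes_used`.
#' @export
estimate_common_dispersion <- function(counts, hk_ids, factors, groups) {
  stopifnot(length(groups) == ncol(counts))
  pseudo <- normalize_counts(counts[hk_ids, , drop = FALSE], factors)
  usable <- names(which(table(groups) >= 2))
  if (length(usable) == 0) {
    stop("need at least one class with >= 2 samples to estimate dispersion")
  }
  obj <- function(log_phi) {
    r <- 1 / exp(log_phi)
    sum(vapply(usable, function(g) {
      sum(nb_conditional_loglik(pseudo[, groups == g, drop = FALSE], r))
    }, numeric(1)))
  }
  opt <- stats::optimize(obj, interval = log(c(1e-6, 10)), maximum = TRUE,
                         tol = 1e-8)
  ## prefer the boundary when the likelihood is monotone toward it
  cand <- c(opt$maximum, log(1e-6), log(10))
  best <- cand[which.max(vapply(cand, obj, numeric(1)))]
  list(phi = exp(best), n_genes_used = length(hk_ids))
}

#' Exact conditional negative-binomial test for a two-class comparison
#'
#' Counts are assumed on a common per-sample scale (equalized libraries);
#' `n1` and `n2` are the effective numbers of samples summed into `y1` and
#' `y2`.  Each class sum is modelled as NB with mean proportional to its
#' effective size and dispersion `phi` per sample (size `n/phi`).
#' Conditional on the total `t = y1 + y2`, the two-sided p-value is the sum
#' of the probabilities of all splits `(a, t - a)` whose conditional
#' probability does not exceed that of the observed split.  With `phi = 0`
#' the conditional distribution is binomial with probability
#' `n1 / (n1 + n2)`.
#'
#' @param y1,y2 non-negative class-summed counts (rounded to integers).
#' @param n1,n2 effective class sizes (> 0).
#' @param phi common NB dispersion (>= 0).
#' @return the two-sided exact p-value, in (0, 1].
#' @export
exact_nb_test <- function(y1, y2, n1, n2, phi) {
  if (y1 < 0 || y2 < 0) stop("counts must be non-negative")
  if (n1 <= 0 || n2 <= 0) stop("effective sizes must be positive")
  if (phi < 0) stop("dispersion must be non-negative")
  y1 <- round(y1); y2 <- round(y2)
  t <- y1 + y2
  if (t == 0) return(1)
  a <- 0:t
  if (phi == 0) {
    logp <- stats::dbinom(a, t, n1 / (n1 + n2), log = TRUE)
  } else {
    r1 <- n1 / phi; r2 <- n2 / phi
    logp <- lgamma(a + r1) - lgamma(a + 1) - lgamma(r1) +
      lgamma(t - a + r2) - lgamma(t - a + 1) - lgamma(r2) -
      (lgamma(t + r1 + r2) - lgamma(t + 1) - lgamma(r1 + r2))
  }
  obs <- logp[y1 + 1]
  min(1, sum(exp(logp[logp <= obs + 1e-12])))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement, capped at 1.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values (FDR).
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Log2 fold-change, Colored over Yellow
#'
#' `log2((mean normalized Colored + prior) / (mean normalized Yellow +
#' prior))`.  The prior count keeps zero-containing genes finite and
#' symmetric: a gene with no reads in either class has fold-change 0.
#'
#' @param y_colored,y_yellow normalized counts (vectors over replicates or
#'   scalars) for the Colored and Yellow classes.
#' @param prior_count additive prior (default 0.5).
#' @return the log2 fold-change.
#' @export
log2_fold_change <- function(y_colored, y_yellow, prior_count = 0.5) {
  log2((mean(y_colored) + prior_count) / (mean(y_yellow) + prior_count))
}

#' Housekeeping fold-change band
#'
#' Sample mean and standard deviation (n - 1 denominator) of the
#' housekeeping log2 fold-changes; the band is mean +/- 2 SD, with the
#' corresponding linear fold-change edges `2^lo` and `2^hi`.  Pigment-gene
#' fold-changes outside the band are taken as likely meaningful in the
#' absence of biological replicates.
#'
#' @param hk_log2fcs log2 fold-changes of the housekeeping genes (>= 2).
#' @return object of class `band_model`: `hk_mean`, `hk_sd`, `lo`, `hi`,
#'   `fc_lo`, `fc_hi`.
#' @export
hk_band <- function(hk_log2fcs) {
  if (length(hk_log2fcs) < 2) stop("need >= 2 housekeeping fold-changes")
  m <- mean(hk_log2fcs)
  s <- stats::sd(hk_log2fcs)
  structure(list(hk_mean = m, hk_sd = s, lo = m - 2 * s, hi = m + 2 * s,
                 fc_lo = 2^(m - 2 * s), fc_hi = 2^(m + 2 * s)),
            class = "band_model")
}

#' Classify log2 fold-changes against the housekeeping band
#'
#' `WITHIN`: inside the +/- 2 SD band; `UP` / `DOWN`: outside the band by
#' at most one further SD (2-3 SD from the HK mean); `UP_BEYOND_BAND` /
#' `DOWN_BEYOND_BAND`: more than 3 SD from the HK mean.  Genes counted as
#' meaningfully regulated are those outside the 2 SD band, i.e. the union
#' of the non-`WITHIN` classes on each side.
#'
#' @param log2fc numeric vector of log2 fold-changes.
#' @param band a `band_model` from [hk_band()].
#' @return character vector of band classes.
#' @export
classify_band <- function(log2fc, band) {
  d <- log2fc - band$hk_mean
  s <- band$hk_sd
  ifelse(d > 3 * s, "UP_BEYOND_BAND",
         ifelse(d > 2 * s, "UP",
                ifelse(d < -3 * s, "DOWN_BEYOND_BAND",
                       ifelse(d < -2 * s, "DOWN", "WITHIN"))))
}

#' Housekeeping-anchored differential expression of a gene panel
#'
#' The full chain for the two-species pooled design: HK normalization
#' factors, HK-based common dispersion, exact conditional NB test per panel
#' gene (classes Yellow vs Colored, the two species acting as replicates),
#' Benjamini-Hochberg FDR within the panel, and classification of each
#' fold-change against the +/- 2 SD housekeeping band.
#'
#' @param counts gene-by-sample count matrix.
#' @param panel_ids panel (e.g. pigment) gene ids.
#' @param hk_ids housekeeping gene ids.
#' @param design `data.frame` with `sample`, `species`, `class` (`class`
#'   must contain "Yellow" and "Colored"); defaults to parsing sample names
#'   of the form `species_class`.
#' @param prior_count prior for fold-changes.
#' @return list with `table` (a `data.frame` of `gene_id`, `log2fc`,
#'   `pvalue`, `fdr`, `band_class`, sorted by decreasing `log2fc`), `band`,
#'   `phi`, `factors` and `band_counts`.
#' @export
pigment_panel_de <- function(counts, panel_ids, hk_ids, design = NULL,
                             prior_count = 0.5) {
  if (is.null(design)) {
    parts <- strsplit(colnames(counts), "_", fixed = TRUE)
    design <- data.frame(sample = colnames(counts),
                         species = vapply(parts, `[`, character(1), 1),
                         class = vapply(parts, `[`, character(1), 2),
                         stringsAsFactors = FALSE)
  }
  stopifnot(all(c("Yellow", "Colored") %in% design$class))
  missing <- setdiff(panel_ids, rownames(counts))
  if (length(missing)) {
    stop("panel genes absent from count matrix: ",
         paste(missing, collapse = ", "))
  }
  factors <- hk_normalization_factors(counts, hk_ids)
  pseudo <- normalize_counts(counts, factors)
  disp <- estimate_common_dispersion(counts, hk_ids, factors, design$class)
  yellow <- design$sample[design$class == "Yellow"]
  colored <- design$sample[design$class == "Colored"]

  fc_of <- function(ids) {
    vapply(ids, function(g) {
      log2_fold_change(pseudo[g, colored], pseudo[g, yellow], prior_count)
    }, numeric(1))
  }
  band <- hk_band(fc_of(hk_ids))
  log2fc <- fc_of(panel_ids)
  pvalue <- vapply(panel_ids, function(g) {
    exact_nb_test(sum(pseudo[g, yellow]), sum(pseudo[g, colored]),
                  length(yellow), length(colored), disp$phi)
  }, numeric(1))
  tab <- data.frame(gene_id = panel_ids, log2fc = log2fc, pvalue = pvalue,
                    fdr = bh_fdr(pvalue),
                    band_class = classify_band(log2fc, band),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$log2fc, tab$gene_id), , drop = FALSE]
  rownames(tab) <- NULL
  classes <- c("UP_BEYOND_BAND", "UP", "WITHIN", "DOWN", "DOWN_BEYOND_BAND")
  band_counts <- vapply(classes, function(cl) sum(tab$band_class == cl),
                        integer(1))
  list(table = tab, band = band, phi = disp$phi, factors = factors,
       band_counts = band_counts)
}

#' Rank genes by mean normalized expression
#'
#' @param counts count matrix.
#' @param factors per-sample normalization factors.
#' @param top_n number of top genes to return (>= 1; capped at the number
#'   of genes).
#' @return `data.frame` with `rank`, `gene_id`, `mean_normalized`, ordered
#'   by decreasing expression (ties by gene id).
#' @export
rank_expression <- function(counts, factors, top_n) {
  stopifnot(top_n >= 1)
  m <- rowMeans(normalize_counts(counts, factors))
  ord <- order(-m, rownames(counts))
  n <- min(top_n, length(m))
  data.frame(rank = seq_len(n), gene_id = rownames(counts)[ord][seq_len(n)],
             mean_normalized = unname(m[ord][seq_len(n)]),
             stringsAsFactors = FALSE)
}

#' Mean absolute Yellow-vs-Colored mapped-read difference of a gene set
#'
#' For each gene the absolute difference between its share of mapped reads
#' in the Yellow sample and in the Colored sample; the mean over the set.
#' The ratio of this quantity between a pigment panel and the housekeeping
#' set measures how much more the panel moves between morphs than the
#' stable baseline does.
#'
#' @param counts count matrix.
#' @param gene_ids gene set.
#' @param yellow_sample,colored_sample column names of the two samples.
#' @return mean absolute difference of mapped-read proportions.
#' @export
mapped_read_difference <- function(counts, gene_ids, yellow_sample,
                                   colored_sample) {
  py <- counts[gene_ids, yellow_sample] / sum(counts[, yellow_sample])
  pc <- counts[gene_ids, colored_sample] / sum(counts[, colored_sample])
  mean(abs(py - pc))
}
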