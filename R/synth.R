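## Seeded synthetic-data generators with recorded ground truth for every
## pipeline stage: transcripts with hexamer-biased ORFs, homology hit
## tables with planted orthologs / decoys / contaminants / fragments,
## negative-binomial count matrices with a zero-fold-change housekeeping
## set, and presence/absence family profiles from a single-gain /
## multiple-loss process.

#' Synthetic-data configuration
#'
#' One integer seed drives independent per-generator substreams, so the
#' generators are individually reproducible and adding one never perturbs
#' another.  Defaults describe the study conditions the package targets:
#' two pooled samples (Yellow, Colored) per species for two species, a
#' 196-gene housekeeping anchor, a ~40-gene pigment panel, and moderate
#' NB overdispersion.
#'
#' @param seed integer master seed.
#' @param n_coding,n_noncoding numbers of coding / non-coding transcripts.
#' @param coding_bias strength (>= 0) of the hexamer preference of the
#'   coding source; 0 makes the coding source exactly uniform.
#' @param orf_len_range inclusive range of planted ORF peptide lengths (aa).
#' @param flank_len_range inclusive range of non-coding flank lengths (nt).
#' @param n_orthologs,n_decoys,n_fragment_groups,n_plain planted ortholog
#'   pairs, one-way decoy queries, 3-contig fragment groups, and plain
#'   queries in the simulated hit tables.
#' @param contaminant_fraction fraction of hit-table queries whose hits go
#'   to non-metazoan (contaminant) taxa.
#' @param nb_dispersion common NB dispersion phi (variance = mu + phi mu^2).
#' @param hk_n,pigment_n,n_other numbers of housekeeping, pigment-panel and
#'   background genes in the count matrix.
#' @param pigment_log2fc_range range the per-gene pigment log2 fold-changes
#'   (Colored over Yellow) are drawn from.
#' @param mu_range range of baseline gene means (log-uniform).
#' @param tree_leaves leaf count of the random family-evolution tree.
#' @param n_families number of simulated gene families.
#' @param family_loss_prob per-branch loss probability below the gain.
#' @return a validated named list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_coding = 200L, n_noncoding = 200L,
                         coding_bias = 1.0,
                         orf_len_range = c(100L, 300L),
                         flank_len_range = c(50L, 200L),
                         n_orthologs = 60L, n_decoys = 20L,
                         n_fragment_groups = 10L, n_plain = 60L,
                         contaminant_fraction = 0.2,
                         nb_dispersion = 0.2,
                         hk_n = 196L, pigment_n = 40L, n_other = 200L,
                         pigment_log2fc_range = c(1, 3),
                         mu_range = c(100, 2000),
                         tree_leaves = 8L, n_families = 100L,
                         family_loss_prob = 0.2) {
  cfg <- list(seed = as.integer(seed), n_coding = n_coding,
              n_noncoding = n_noncoding, coding_bias = coding_bias,
              orf_len_range = orf_len_range,
              flank_len_range = flank_len_range,
              n_orthologs = n_orthologs, n_decoys = n_decoys,
              n_fragment_groups = n_fragment_groups, n_plain = n_plain,
              contaminant_fraction = contaminant_fraction,
              nb_dispersion = nb_dispersion, hk_n = hk_n,
              pigment_n = pigment_n, n_other = n_other,
              pigment_log2fc_range = pigment_log2fc_range,
              mu_range = mu_range, tree_leaves = tree_leaves,
              n_families = n_families,
              family_loss_prob = family_loss_prob)
  counts <- c("n_coding", "n_noncoding", "n_orthologs", "n_decoys",
              "n_fragment_groups", "n_plain", "hk_n", "pigment_n",
              "n_other", "tree_leaves", "n_families")
  for (f in counts) if (cfg[[f]] < 0) stop(f, " must be >= 0")
  if (cfg$coding_bias < 0) stop("coding_bias must be >= 0")
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  for (f in c("contaminant_fraction", "family_loss_prob")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  }
  if (cfg$orf_len_range[1] < 1 || diff(cfg$orf_len_range) < 0) {
    stop("invalid orf_len_range")
  }
  structure(cfg, class = "synth_config")
}

## independent substream seed per generator (kept below 2^31)
derive_seed <- function(seed, stream) {
  offset <- match(stream, c("transcripts", "hits", "counts", "families"))
  as.integer((as.double(seed) * 48271 + offset * 16807) %% 2147483647)
}

## per-context conditional base distribution of the coding source:
## uniform mixed with a Dirichlet(1,1,1,1) draw, mixture weight set by bias
coding_source <- function(coding_bias) {
  g <- matrix(stats::rgamma(1024 * 4, shape = 1), 1024, 4)
  g <- g / rowSums(g)
  (matrix(0.25, 1024, 4) + coding_bias * g) / (1 + coding_bias)
}

## sample `len` bases from a 5th-order chain with conditional matrix `cond`
## (1024 x 4), starting from a uniform 5-mer context; returns base codes 0-3
sample_chain <- function(len, cond) {
  cum <- cbind(cond[, 1], cond[, 1] + cond[, 2],
               cond[, 1] + cond[, 2] + cond[, 3])
  v <- integer(len)
  ctx <- 0L
  warm <- sample.int(4L, 5L, replace = TRUE) - 1L
  for (b in warm) ctx <- (ctx * 4L + b) %% 1024L
  u <- stats::runif(len)
  for (i in seq_len(len)) {
    row <- ctx + 1L
    b <- (u[i] > cum[row, 1]) + (u[i] > cum[row, 2]) + (u[i] > cum[row, 3])
    v[i] <- b
    ctx <- (ctx * 4L + b) %% 1024L
  }
  v
}

codes_to_string <- function(v) {
  paste(c("A", "C", "G", "T")[v + 1L], collapse = "")
}

## replace in-frame stop codons of an ORF interior by uniform non-stop codons
strip_internal_stops <- function(v) {
  n_codons <- length(v) %/% 3L
  for (k in seq_len(n_codons)) {
    i <- 3L * (k - 1L) + 1L
    repeat {
      codon <- codes_to_string(v[i:(i + 2L)])
      if (!codon %in% STOP_CODONS) break
      v[i:(i + 2L)] <- sample.int(4L, 3L, replace = TRUE) - 1L
    }
  }
  v
}

#' Simulate transcripts with planted coding ORFs
#'
#' Coding transcripts carry one embedded complete ORF (ATG ... stop, peptide
#' length uniform in `orf_len_range`) whose interior is drawn from a
#' hexamer-biased source, flanked by sequence from the unbiased (uniform)
#' source; non-coding transcripts are drawn entirely from the unbiased
#' source at matched lengths.  Ground truth records the class and the
#' planted ORF coordinates (0-based half-open, forward strand).
#'
#' @param config a [synth_config()].
#' @param min_aa the downstream classifier's minimum ORF length; an
#'   `orf_len_range` below it is an error.
#' @return list with `records` (transcript table) and `truth`
#'   (`data.frame(id, class, orf_start, orf_end)`).
#' @export
simulate_transcripts <- function(config, min_aa = 100L) {
  if (config$orf_len_range[1] < min_aa) {
    stop("orf_len_range starts below the classifier minimum of ", min_aa,
         " aa")
  }
  set.seed(derive_seed(config$seed, "transcripts"))
  cond <- coding_source(config$coding_bias)
  fl <- config$flank_len_range
  ol <- config$orf_len_range
  ids <- character(0); seqs <- character(0)
  cls <- character(0); ostart <- integer(0); oend <- integer(0)
  for (i in seq_len(config$n_coding)) {
    left <- sample.int(4L, sample(fl[1]:fl[2], 1), replace = TRUE) - 1L
    right <- sample.int(4L, sample(fl[1]:fl[2], 1), replace = TRUE) - 1L
    aa <- sample(ol[1]:ol[2], 1)
    interior <- strip_internal_stops(sample_chain(3L * aa, cond))
    stop_codon <- encode_bases(sample(STOP_CODONS, 1))
    v <- c(left, encode_bases("ATG"), interior, stop_codon, right)
    ids <- c(ids, sprintf("cod%04d_seq1", i))
    seqs <- c(seqs, codes_to_string(v))
    cls <- c(cls, "coding")
    ostart <- c(ostart, length(left))
    oend <- c(oend, length(left) + 3L + 3L * aa + 3L)
  }
  for (i in seq_len(config$n_noncoding)) {
    len <- sample(fl[1]:fl[2], 1) + sample(fl[1]:fl[2], 1) +
      3L * (sample(ol[1]:ol[2], 1) + 2L)
    ids <- c(ids, sprintf("non%04d_seq1", i))
    seqs <- c(seqs, codes_to_string(sample.int(4L, len, replace = TRUE) - 1L))
    cls <- c(cls, "noncoding")
    ostart <- c(ostart, NA_integer_)
    oend <- c(oend, NA_integer_)
  }
  list(records = transcript_records(ids, seqs),
       truth = data.frame(id = ids, class = cls, orf_start = ostart,
                          orf_end = oend, stringsAsFactors = FALSE))
}

#' Toy taxonomy for simulated hit tables
#'
#' A small NCBI-style taxonomy with a metazoan clade (arachnids, an insect,
#' a nematode) and contaminant clades (bacteria, fungi), sufficient for LCA
#' assignment and the host / meta-transcriptome split.
#'
#' @return taxonomy `data.frame` (`taxon_id`, `parent_id`, `rank`, `name`).
#' @export
toy_taxonomy <- function() {
  tax <- data.frame(
    taxon_id  = c("1", "2", "3", "4", "5", "6", "7", "8", "9",
                  "10", "11", "12", "13", "14", "15", "16", "17"),
    parent_id = c("1", "1", "1", "3", "3", "5", "5", "6", "8",
                  "9", "9", "6", "12", "2", "14", "4", "7"),
    rank = c("root", "superkingdom", "superkingdom", "kingdom", "kingdom",
             "phylum", "phylum", "class", "genus",
             "species", "species", "class", "species", "genus", "species",
             "species", "species"),
    name = c("root", "Bacteria", "Eukaryota", "Fungi", "Metazoa",
             "Arthropoda", "Nematoda", "Arachnida", "Theridion",
             "Theridion grallator", "Theridion californicum", "Insecta",
             "Drosophila melanogaster", "Escherichia", "Escherichia coli",
             "Candida sp.", "Mermithidae sp."),
    stringsAsFactors = FALSE)
  validate_taxonomy(tax)
  tax
}

hit_row <- function(query, subject, bitscore, evalue, taxon = NA_character_,
                    alen = 100L) {
  data.frame(query_id = query, subject_id = subject,
             percent_identity = 60, alignment_length = alen,
             mismatches = 30L, gap_opens = 2L, qstart = 1L, qend = alen,
             sstart = 1L, send = alen, evalue = evalue, bitscore = bitscore,
             subject_taxon = taxon, stringsAsFactors = FALSE)
}

#' Simulate homology hit tables with planted structure
#'
#' Plants: mutual-best ortholog pairs between contig set A and protein set
#' B; one-way decoy queries (forward best hit whose reciprocal best is a
#' different contig); fragment groups of three short contigs sharing one
#' best subject (so none is a unique best hit); and plain contigs with a
#' private best subject.  Each A-query is independently tagged as a
#' contaminant with probability `contaminant_fraction`: its hits carry
#' non-metazoan taxa, all other queries hit metazoan taxa.
#'
#' @param config a [synth_config()].
#' @return list with `hits_ab`, `hits_ba` (hit tables), `taxonomy`,
#'   `lengths` (named contig lengths) and `truth` (`rbh` pairs,
#'   `contaminants`, `fragment_groups`, `unique_best`).
#' @export
simulate_hits <- function(config) {
  set.seed(derive_seed(config$seed, "hits"))
  taxonomy <- toy_taxonomy()
  metazoan_taxa <- c("10", "11", "13")
  contaminant_taxa <- c("15", "16", "17")
  ab <- list(); ba <- list()
  lengths <- integer(0)
  contaminants <- character(0)
  unique_best <- character(0)

  tag <- function(qid) {
    if (stats::runif(1) < config$contaminant_fraction) {
      contaminants <<- c(contaminants, qid)
      sample(contaminant_taxa, 1)
    } else {
      sample(metazoan_taxa, 1)
    }
  }
  add_len <- function(qid, lo = 200L, hi = 2000L) {
    lengths[qid] <<- sample(lo:hi, 1)
  }

  orth_a <- sprintf("orthA%03d", seq_len(config$n_orthologs))
  orth_b <- sprintf("orthB%03d", seq_len(config$n_orthologs))
  for (i in seq_len(config$n_orthologs)) {
    top <- stats::runif(1, 150, 300)
    taxon <- tag(orth_a[i])
    ab[[length(ab) + 1]] <- hit_row(orth_a[i], orth_b[i], top, 1e-40, taxon)
    ba[[length(ba) + 1]] <- hit_row(orth_b[i], orth_a[i],
                                    top * stats::runif(1, 0.9, 1), 1e-38)
    ## weaker secondary hit to a different subject
    other <- orth_b[sample(seq_len(config$n_orthologs)[-i], 1)]
    ab[[length(ab) + 1]] <- hit_row(orth_a[i], other,
                                    top * stats::runif(1, 0.3, 0.7), 1e-10,
                                    taxon)
    add_len(orth_a[i])
    unique_best <- c(unique_best, orth_a[i])
  }
  decoys <- sprintf("decoyA%03d", seq_len(config$n_decoys))
  for (i in seq_len(config$n_decoys)) {
    ## forward best to a private subject that never hits back, so the decoy
    ## is detected one-way but never forms an RBH pair
    ab[[length(ab) + 1]] <- hit_row(decoys[i], sprintf("decoyB%03d", i),
                                    stats::runif(1, 40, 100), 1e-8,
                                    tag(decoys[i]))
    add_len(decoys[i])
    unique_best <- c(unique_best, decoys[i])
  }
  frag_groups <- list()
  for (g in seq_len(config$n_fragment_groups)) {
    subject <- sprintf("fragB%03d", g)
    members <- sprintf("fragA%03d_%d", g, 1:3)
    taxon <- tag(members[1])
    contaminants <- setdiff(contaminants, members[1])
    if (taxon %in% contaminant_taxa) contaminants <- c(contaminants, members)
    for (m in members) {
      ab[[length(ab) + 1]] <- hit_row(m, subject, stats::runif(1, 60, 120),
                                      1e-12, taxon)
      add_len(m, 100L, 199L)
    }
    frag_groups[[g]] <- members
  }
  plain <- sprintf("plainA%03d", seq_len(config$n_plain))
  for (i in seq_len(config$n_plain)) {
    subject <- sprintf("plainB%03d", i)
    ab[[length(ab) + 1]] <- hit_row(plain[i], subject,
                                    stats::runif(1, 50, 200), 1e-15,
                                    tag(plain[i]))
    add_len(plain[i])
    unique_best <- c(unique_best, plain[i])
  }
  hits_ab <- do.call(rbind, ab)
  hits_ba <- do.call(rbind, ba)
  rownames(hits_ab) <- rownames(hits_ba) <- NULL
  list(hits_ab = hits_ab, hits_ba = hits_ba, taxonomy = taxonomy,
       lengths = lengths,
       truth = list(rbh = data.frame(a_id = orth_a, b_id = orth_b,
                                     stringsAsFactors = FALSE),
                    contaminants = sort(unique(contaminants)),
                    fragment_groups = frag_groups,
                    unique_best = unique_best))
}

#' Simulate a negative-binomial count matrix for the two-species design
#'
#' Four pooled samples (Yellow and Colored for each of two species).
#' Housekeeping and background genes have log2 fold-change 0 between the
#' color classes; each pigment-panel gene gets a log2 fold-change drawn
#' uniformly from `pigment_log2fc_range`, applied to the Colored samples.
#' Counts are NB with common dispersion `nb_dispersion` (Poisson when 0)
#' around `mu_g * f_s * 2^(log2fc_g)` for Colored samples.
#'
#' @param config a [synth_config()].
#' @return list with `counts` (integer matrix), `design`, `hk_ids`,
#'   `pigment_ids`, `truth` (`mu`, `log2fc`, `phi`, `sample_factors`).
#' @export
simulate_counts <- function(config) {
  set.seed(derive_seed(config$seed, "counts"))
  hk_ids <- sprintf("hk%04d", seq_len(config$hk_n))
  pigment_ids <- sprintf("pig%04d", seq_len(config$pigment_n))
  other_ids <- sprintf("bg%04d", seq_len(config$n_other))
  genes <- c(hk_ids, pigment_ids, other_ids)
  samples <- c("Tcal_Yellow", "Tcal_Colored", "Tgra_Yellow", "Tgra_Colored")
  design <- data.frame(sample = samples,
                       species = c("Tcal", "Tcal", "Tgra", "Tgra"),
                       class = c("Yellow", "Colored", "Yellow", "Colored"),
                       stringsAsFactors = FALSE)
  mu <- exp(stats::runif(length(genes), log(config$mu_range[1]),
                         log(config$mu_range[2])))
  names(mu) <- genes
  lfc <- stats::setNames(numeric(length(genes)), genes)
  lfc[pigment_ids] <- stats::runif(config$pigment_n,
                                   config$pigment_log2fc_range[1],
                                   config$pigment_log2fc_range[2])
  f <- exp(stats::rnorm(4, 0, 0.2))
  names(f) <- samples
  phi <- config$nb_dispersion
  counts <- matrix(0L, length(genes), 4, dimnames = list(genes, samples))
  for (s in samples) {
    colored <- design$class[design$sample == s] == "Colored"
    m <- mu * f[s] * if (colored) 2^lfc else 1
    counts[, s] <- if (phi == 0) {
      stats::rpois(length(m), m)
    } else {
      stats::rnbinom(length(m), mu = m, size = 1 / phi)
    }
  }
  list(counts = counts, design = design, hk_ids = hk_ids,
       pigment_ids = pigment_ids,
       truth = list(mu = mu, log2fc = lfc, phi = phi, sample_factors = f))
}

#' Simulate gene-family presence/absence profiles on a tree
#'
#' For each family one gain branch is chosen uniformly over all branches
#' (the root counts as the root edge); below it every branch independently
#' loses the family with probability `family_loss_prob`, and a lost clade
#' becomes entirely absent.  Loss draws leaving no present leaf are redrawn
#' so every profile has at least one present taxon.
#'
#' @param tree rooted [ape::phylo].
#' @param n_families number of families.
#' @param family_loss_prob per-branch loss probability.
#' @param seed integer seed.
#' @return list with `profiles` (logical family-by-taxon matrix) and
#'   `truth` (list per family: `gain_node`, `loss_nodes`).
#' @export
simulate_family_profiles <- function(tree, n_families, family_loss_prob,
                                     seed = 1L) {
  set.seed(seed)
  n_tip <- ape::Ntip(tree)
  n_nodes <- n_tip + tree$Nnode
  ch <- tree_children(tree)
  clades <- tree_clades(tree)
  profiles <- matrix(FALSE, n_families, n_tip,
                     dimnames = list(paste0("fam", seq_len(n_families)),
                                     tree$tip.label))
  truth <- vector("list", n_families)
  for (fam in seq_len(n_families)) {
    gain <- sample.int(n_nodes, 1)
    repeat {
      lost <- rep(FALSE, n_nodes)
      loss_nodes <- integer(0)
      walk <- function(v) {
        for (c in ch[[v]]) {
          if (stats::runif(1) < family_loss_prob) {
            loss_nodes <<- c(loss_nodes, c)
          } else {
            walk(c)
          }
        }
      }
      walk(gain)
      present <- clades[[gain]]
      for (l in loss_nodes) present <- setdiff(present, clades[[l]])
      if (length(present) > 0) break
    }
    profiles[fam, present] <- TRUE
    truth[[fam]] <- list(gain_node = gain, loss_nodes = sort(loss_nodes))
  }
  list(profiles = profiles, truth = truth)
}

#' Random rooted binary tree for simulations
#'
#' @param n_leaves number of leaves (named `t1 ... tn`).
#' @param seed integer seed.
#' @return rooted [ape::phylo].
#' @export
random_rooted_tree <- function(n_leaves, seed = 1L) {
  set.seed(seed)
  tree <- ape::rtree(n_leaves, rooted = TRUE,
                     tip.label = paste0("t", seq_len(n_leaves)))
  tree
}
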