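# Independent oracles used to cross-check the implementation.  Each is a
# deliberately different construction from the code path it validates.

# Exhaustive six-frame ORF enumeration: per strand and frame, locate stop
# and ATG codon indices directly, then pair every stop with the first ATG
# after the previous stop.
oracle_orfs <- function(sequence, min_aa) {
  n <- nchar(sequence)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(sequence)))
  out <- data.frame(strand = character(), frame = integer(),
                    start = integer(), end = integer(), aa_len = integer())
  for (strand in c("+", "-")) {
    s <- if (strand == "+") sequence else rc
    for (frame in 0:2) {
      n_codons <- (n - frame) %/% 3
      if (n_codons < 1) next
      pos <- frame + 3 * (seq_len(n_codons) - 1) + 1
      codons <- substring(s, pos, pos + 2)
      clean <- !grepl("N", codons, fixed = TRUE)
      stop_idx <- which(codons %in% c("TAA", "TAG", "TGA") & clean)
      atg_idx <- which(codons == "ATG" & clean)
      prev_stop <- 0
      for (st in stop_idx) {
        cands <- atg_idx[atg_idx > prev_stop & atg_idx < st]
        if (length(cands)) {
          a <- pos[min(cands)]; b <- pos[st] + 2
          aa <- (b - a + 1) %/% 3 - 1
          if (aa >= min_aa) {
            start <- if (strand == "+") a - 1 else n - b
            end <- if (strand == "+") b else n - a + 1
            out <- rbind(out, data.frame(strand = strand, frame = frame,
                                         start = start, end = end,
                                         aa_len = aa))
          }
        }
        prev_stop <- st
      }
    }
  }
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

# Full conditional enumeration of the exact NB test via dnbinom products.
oracle_nb_test <- function(y1, y2, n1, n2, phi) {
  t <- y1 + y2
  if (t == 0) return(1)
  a <- 0:t
  if (phi == 0) {
    p <- dbinom(a, t, n1 / (n1 + n2))
  } else {
    jp <- dnbinom(a, size = n1 / phi, mu = n1 * 7) *
      dnbinom(t - a, size = n2 / phi, mu = n2 * 7)
    p <- jp / sum(jp)
  }
  sum(p[p <= p[y1 + 1] * (1 + 1e-12)])
}

# Naive LCA: intersect the full root paths of all hit taxa and take the
# deepest shared node.
oracle_lca <- function(taxon_ids, taxonomy) {
  paths <- lapply(unique(taxon_ids), function(t) taxon_path(t, taxonomy))
  shared <- Reduce(intersect, paths)
  depths <- vapply(shared, function(t) length(taxon_path(t, taxonomy)),
                   numeric(1))
  shared[which.max(depths)]
}

# Exhaustive single-gain Dollo search: try every gain node whose clade
# covers the present leaves and count maximal all-absent subtrees below it.
oracle_dollo <- function(tree, presence) {
  n_tip <- ape::Ntip(tree)
  n_nodes <- n_tip + tree$Nnode
  ch <- vector("list", n_nodes)
  for (i in seq_len(nrow(tree$edge))) {
    ch[[tree$edge[i, 1]]] <- c(ch[[tree$edge[i, 1]]], tree$edge[i, 2])
  }
  tips_under <- function(v) {
    if (is.null(ch[[v]])) return(v)
    unlist(lapply(ch[[v]], tips_under))
  }
  count_losses <- function(v) {
    total <- 0
    for (c in ch[[v]]) {
      if (!any(presence[tree$tip.label[tips_under(c)]])) {
        total <- total + 1
      } else {
        total <- total + count_losses(c)
      }
    }
    total
  }
  present_tips <- which(presence[tree$tip.label])
  best <- NULL
  for (g in seq_len(n_nodes)) {
    tu <- tips_under(g)
    if (!all(present_tips %in% tu)) next
    losses <- count_losses(g)
    if (is.null(best) || losses < best$losses ||
        (losses == best$losses && length(tu) < best$clade_size)) {
      best <- list(gain_node = g, losses = losses, clade_size = length(tu))
    }
  }
  best
}

# Random nucleotide sequence, optionally salted with N bases.
random_sequence <- function(len, n_frac = 0) {
  alphabet <- c("A", "C", "G", "T")
  s <- sample(alphabet, len, replace = TRUE)
  if (n_frac > 0) {
    k <- rbinom(1, len, n_frac)
    if (k > 0) s[sample(len, k)] <- "N"
  }
  paste(s, collapse = "")
}

# Random tree-shaped taxonomy: node i attaches to a uniform earlier node.
random_taxonomy <- function(n_nodes) {
  parent <- c("n1", vapply(2:n_nodes, function(i) {
    paste0("n", sample(i - 1, 1))
  }, character(1)))
  data.frame(taxon_id = paste0("n", seq_len(n_nodes)),
             parent_id = parent, rank = "clade",
             name = paste0("name", seq_len(n_nodes)),
             stringsAsFactors = FALSE)
}

# Simple hit-table builder for tests.
make_hits <- function(query, subject, bitscore, evalue = 1e-20,
                      taxon = NA_character_) {
  data.frame(query_id = query, subject_id = subject, percent_identity = 50,
             alignment_length = 100L, mismatches = 0L, gap_opens = 0L,
             qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
             evalue = evalue, bitscore = bitscore, subject_taxon = taxon,
             stringsAsFactors = FALSE)
}
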