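## Coding-potential classification: six-frame ORF finding, a 5th-order
## ("hexamer") nucleotide Markov model trained on the longest ORFs in the
## dataset, a composition-preserving shuffled null model, and a
## log-likelihood-ratio decision rule.

STOP_CODONS <- c("TAA", "TAG", "TGA")

encode_bases <- function(sequence) {
  match(strsplit(sequence, "", fixed = TRUE)[[1]],
        c("A", "C", "G", "T")) - 1L
}

## integer codes of all hexamer windows (NA where the window contains N)
hexamer_codes <- function(sequence) {
  v <- encode_bases(sequence)
  if (length(v) < 6) return(integer(0))
  e <- embed(v, 6)
  e[, 6] * 1024L + e[, 5] * 256L + e[, 4] * 64L +
    e[, 3] * 16L + e[, 2] * 4L + e[, 1]
}

reverse_complement <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(sequence)))
}

#' Find open reading frames in all six reading frames
#'
#' An ORF starts at the first ATG following a stop codon (or the frame
#' start) and runs to the next in-frame stop; the stop codon is included in
#' the reported span.  Codons containing `N` are never treated as start or
#' stop codons but do not interrupt the frame.  Coordinates are 0-based
#' half-open on the forward strand; `frame` is the offset (0, 1, 2) on the
#' ORF's own strand.
#'
#' @param sequence a nucleotide string over ACGTN.
#' @param min_aa minimum peptide length (codons between start and stop);
#'   the span of a reported ORF is therefore at least `3 * (min_aa + 1)` nt.
#' @param id transcript id attached to the output rows.
#' @param allow_partial also report a trailing stopless ORF (ATG to the 3'
#'   frame end); off by default, so only complete ORFs are returned.
#' @return `data.frame` with `transcript_id`, `strand`, `frame`, `start`,
#'   `end`, `aa_len`, ordered by `start`.
#' @export
find_orfs <- function(sequence, min_aa = 100L, id = "seq",
                      allow_partial = FALSE) {
  stopifnot(min_aa >= 1)
  n <- nchar(sequence)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") sequence else reverse_complement(sequence)
    for (frame in 0:2) {
      n_codons <- (n - frame) %/% 3
      if (n_codons < 1) next
      starts <- frame + 3L * (seq_len(n_codons) - 1L) + 1L
      codons <- substring(s, starts, starts + 2L)
      has_n <- grepl("N", codons, fixed = TRUE)
      is_stop <- codons %in% STOP_CODONS & !has_n
      is_atg <- codons == "ATG" & !has_n
      orf_from <- NA_integer_
      for (k in seq_len(n_codons)) {
        if (is_stop[k]) {
          if (!is.na(orf_from)) {
            a <- starts[orf_from]        # 1-based first base of ATG
            b <- starts[k] + 2L          # 1-based last base of stop
            aa <- (b - a + 1L) %/% 3L - 1L
            if (aa >= min_aa) {
              out[[length(out) + 1L]] <-
                c(strand = strand, frame = frame, a = a, b = b, aa = aa)
            }
          }
          orf_from <- NA_integer_
        } else if (is_atg[k] && is.na(orf_from)) {
          orf_from <- k
        }
      }
      if (allow_partial && !is.na(orf_from)) {
        a <- starts[orf_from]
        b <- starts[n_codons] + 2L
        aa <- (b - a + 1L) %/% 3L
        if (aa >= min_aa) {
          out[[length(out) + 1L]] <-
            c(strand = strand, frame = frame, a = a, b = b, aa = aa)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(transcript_id = character(), strand = character(),
                      frame = integer(), start = integer(), end = integer(),
                      aa_len = integer(), stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, out)
  strand <- m[, "strand"]
  a <- as.integer(m[, "a"]); b <- as.integer(m[, "b"])
  ## map minus-strand spans back to forward-strand coordinates
  start <- ifelse(strand == "+", a - 1L, n - b)
  end <- ifelse(strand == "+", b, n - (a - 1L))
  res <- data.frame(transcript_id = id, strand = strand,
                    frame = as.integer(m[, "frame"]),
                    start = as.integer(start), end = as.integer(end),
                    aa_len = as.integer(m[, "aa"]),
                    stringsAsFactors = FALSE)
  res <- res[order(res$start, res$end, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## forward-strand nucleotide sequence of an ORF row, read 5'->3' on its strand
orf_sequence <- function(records, orf) {
  s <- substring(records$sequence[match(orf$transcript_id, records$id)],
                 orf$start + 1L, orf$end)
  if (orf$strand == "-") s <- reverse_complement(s)
  s
}

#' Train a hexamer Markov model
#'
#' A 5th-order nucleotide Markov chain: 6-mer counts over the training
#' sequences give the conditional probability of the 6th base given its
#' 5-mer context, with additive smoothing.  Contexts never observed fall
#' back to the uniform 0.25 by construction.
#'
#' @param sequences character vector of nucleotide training sequences
#'   (typically ORF sequences); windows containing `N` are skipped.
#' @param pseudocount additive smoothing constant (> 0).
#' @return an object of class `hexamer_model` holding the log conditional
#'   probabilities.
#' @export
train_hexamer_model <- function(sequences, pseudocount = 1) {
  if (length(sequences) == 0) stop("training set is empty")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  counts <- numeric(4096)
  for (s in sequences) {
    h <- hexamer_codes(s)
    h <- h[!is.na(h)]
    if (length(h)) counts <- counts + tabulate(h + 1L, nbins = 4096)
  }
  cmat <- matrix(counts, nrow = 1024, ncol = 4, byrow = TRUE)
  cond <- (cmat + pseudocount) / (rowSums(cmat) + 4 * pseudocount)
  logp <- as.numeric(t(log(cond)))  # index = context*4 + base + 1
  structure(list(log_cond = logp, pseudocount = pseudocount),
            class = "hexamer_model")
}

#' Build the shuffled null model
#'
#' Each training sequence is independently shuffled by a seeded permutation
#' of its bases (preserving mononucleotide composition exactly) and a
#' hexamer model is trained on the shuffles.  This removes hexamer-level
#' structure while keeping base composition, giving the non-coding null for
#' the likelihood-ratio test.
#'
#' @inheritParams train_hexamer_model
#' @param seed integer seed for the permutation.
#' @return a `hexamer_model`.
#' @export
build_null_model <- function(sequences, seed = 1L, pseudocount = 1) {
  if (length(sequences) == 0) stop("training set is empty")
  set.seed(seed)
  shuffled <- vapply(sequences, function(s) {
    paste(sample(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  train_hexamer_model(shuffled, pseudocount = pseudocount)
}

#' Log-likelihood ratio of a sequence under coding vs null hexamer models
#'
#' Sums, over every position from the 6th base on, the difference in log
#' conditional probability of the observed base given its 5-mer context
#' under the two models.  Windows containing `N` are skipped.
#'
#' @param model,null `hexamer_model` objects (coding and null).
#' @param sequence nucleotide string, length >= 6.
#' @return the log-likelihood ratio (natural log).
#' @export
score_llr <- function(model, null, sequence) {
  if (nchar(sequence) < 6) stop("sequence shorter than 6 nt cannot be scored")
  h <- hexamer_codes(sequence)
  h <- h[!is.na(h)]
  if (length(h) == 0) return(0)
  sum(model$log_cond[h + 1L] - null$log_cond[h + 1L])
}

## llr of a forward-strand span and of its reverse complement.  For a
## sliding-window 5th-order model the three same-strand frames share the
## score up to one or two boundary terms and carry no frame information,
## so the operative six-frame comparison collapses to the two strands.
strand_scores <- function(model, null, span) {
  c(fwd = score_llr(model, null, span),
    rev = score_llr(model, null, reverse_complement(span)))
}

#' Classify transcripts as coding or non-coding
#'
#' The `n_train` longest ORFs found dataset-wide (six frames, complete ORFs
#' only) parameterize the hexamer Markov model; the same ORFs, shuffled,
#' give the null.  For each transcript the candidate is the ORF maximizing
#' the log-likelihood ratio (ties: longer ORF, then smaller start
#' coordinate, then strand/frame).  A transcript is called coding when the
#' candidate's LLR is positive *and* the candidate's reading of the span
#' strictly out-scores the reverse-complement reading; same-strand frame
#' shifts are not compared because a sliding-window hexamer model scores
#' them identically apart from boundary terms.
#'
#' @param records transcript record table (see [read_fasta()]).
#' @param n_train number of longest ORFs used for training (default 500;
#'   ties broken by transcript id, then start coordinate).
#' @param min_aa minimum ORF peptide length considered (default 100 aa).
#' @param seed seed for the null-model shuffle.
#' @param pseudocount smoothing constant for both models.
#' @param allow_partial passed to [find_orfs()].
#' @return `data.frame` with one row per input transcript: `transcript_id`,
#'   `strand`, `frame`, `start`, `end`, `aa_len`, `llr`, `is_coding`.
#'   Transcripts with no qualifying ORF get `NA` coordinates and
#'   `is_coding = FALSE`.
#' @export
classify_transcripts <- function(records, n_train = 500L, min_aa = 100L,
                                 seed = 1L, pseudocount = 1,
                                 allow_partial = FALSE) {
  orfs <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    find_orfs(records$sequence[i], min_aa = min_aa, id = records$id[i],
              allow_partial = allow_partial)
  }))
  if (is.null(orfs) || nrow(orfs) == 0) {
    stop("no ORFs of >= ", min_aa, " aa found in ", nrow(records),
         " transcripts; cannot train the coding model")
  }
  train_ord <- order(-orfs$aa_len, orfs$transcript_id, orfs$start)
  train <- orfs[train_ord[seq_len(min(n_train, nrow(orfs)))], , drop = FALSE]
  train_seqs <- vapply(seq_len(nrow(train)), function(i)
    orf_sequence(records, train[i, ]), character(1))
  model <- train_hexamer_model(train_seqs, pseudocount = pseudocount)
  null <- build_null_model(train_seqs, seed = seed, pseudocount = pseudocount)

  orfs$llr <- vapply(seq_len(nrow(orfs)), function(i)
    score_llr(model, null, orf_sequence(records, orfs[i, ])), numeric(1))

  calls <- lapply(records$id, function(id) {
    cand <- orfs[orfs$transcript_id == id, , drop = FALSE]
    if (nrow(cand) == 0) {
      return(data.frame(transcript_id = id, strand = NA_character_,
                        frame = NA_integer_, start = NA_integer_,
                        end = NA_integer_, aa_len = NA_integer_,
                        llr = NA_real_, is_coding = FALSE,
                        stringsAsFactors = FALSE))
    }
    cand <- cand[order(-cand$llr, -cand$aa_len, cand$start, cand$strand,
                       cand$frame), , drop = FALSE]
    best <- cand[1, , drop = FALSE]
    span <- substring(records$sequence[match(id, records$id)],
                      best$start + 1L, best$end)
    scores <- strand_scores(model, null, span)
    own <- if (best$strand == "+") 1L else 2L
    best$is_coding <- best$llr > 0 && scores[own] > scores[-own]
    rownames(best) <- NULL
    best
  })
  res <- do.call(rbind, calls)
  attr(res, "model") <- model
  attr(res, "null") <- null
  res
}
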