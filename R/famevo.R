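## Gene-family construction by Markov clustering of an all-vs-all
## similarity graph, phylogenetic presence/absence profiles, and
## Dollo-parsimony reconstruction of family gains and losses on a rooted
## species tree (single gain, unlimited subsequent losses).

#' Keep the longest isoform per component
#'
#' @param records transcript record table with `component_id` parsed.
#' @return one record per component: maximal length, ties broken by the
#'   lexicographically smallest id.
#' @export
longest_isoform_filter <- function(records) {
  ord <- order(records$component_id, -records$length, records$id)
  r <- records[ord, , drop = FALSE]
  r <- r[!duplicated(r$component_id), , drop = FALSE]
  rownames(r) <- NULL
  r
}

#' Build an undirected similarity graph from an all-vs-all hit table
#'
#' Nodes are sequence ids; the weight of an edge is the maximum bitscore
#' over the two directed hits at E-value at most `max_evalue`.
#'
#' @param hits all-vs-all hit table.
#' @param max_evalue acceptance cutoff (default 1e-5).
#' @return list with `nodes` (character) and `edges`
#'   (`data.frame(a, b, weight)`, `a <= b`).
#' @export
similarity_graph <- function(hits, max_evalue = 1e-5) {
  hits <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  nodes <- sort(unique(c(hits$query_id, hits$subject_id)))
  if (nrow(hits) == 0) {
    return(list(nodes = nodes,
                edges = data.frame(a = character(), b = character(),
                                   weight = numeric())))
  }
  a <- pmin(hits$query_id, hits$subject_id)
  b <- pmax(hits$query_id, hits$subject_id)
  key <- paste(a, b, sep = "\r")
  w <- tapply(hits$bitscore, key, max)
  parts <- strsplit(names(w), "\r", fixed = TRUE)
  edges <- data.frame(a = vapply(parts, `[`, character(1), 1),
                      b = vapply(parts, `[`, character(1), 2),
                      weight = as.numeric(w), stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  list(nodes = nodes, edges = edges)
}

## minimal union-find
uf_new <- function(n) seq_len(n)
uf_find <- function(uf, i) { while (uf[i] != i) i <- uf[i]; i }
uf_union <- function(uf, i, j) {
  ri <- uf_find(uf, i); rj <- uf_find(uf, j)
  if (ri != rj) uf[max(ri, rj)] <- min(ri, rj)
  uf
}

#' Markov clustering (MCL) of a weighted similarity graph
#'
#' The column-stochastic transition matrix (with self-loops set to each
#' node's maximum incident weight, the usual regularization) is iterated
#' through expansion (matrix squaring) and inflation (elementwise power
#' `inflation`, column renormalization) until the maximum column change
#' falls below `tol`.  Clusters are the attractor systems of the limit
#' matrix; a node attracted by several systems is assigned to its
#' highest-probability attractor, ties broken lexicographically.
#'
#' @param graph a list from [similarity_graph()], or a symmetric named
#'   weight matrix.
#' @param inflation inflation factor (> 1; 2.0 is the standard default for
#'   protein-family construction).
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the transition matrix.
#' @return named integer vector: cluster id (1, 2, ...) per node; every
#'   node is in exactly one cluster.
#' @export
mcl_cluster <- function(graph, inflation = 2.0, max_iter = 200L, tol = 1e-8) {
  stopifnot(inflation > 1)
  if (is.matrix(graph)) {
    A <- graph
    nodes <- rownames(A)
  } else {
    nodes <- graph$nodes
    n <- length(nodes)
    A <- matrix(0, n, n, dimnames = list(nodes, nodes))
    e <- graph$edges
    if (nrow(e)) {
      A[cbind(match(e$a, nodes), match(e$b, nodes))] <- e$weight
      A[cbind(match(e$b, nodes), match(e$a, nodes))] <- e$weight
    }
  }
  if (length(nodes) == 0) stop("empty graph")
  if (any(A < 0)) stop("edge weights must be positive")
  loop <- apply(A, 1, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  normalize <- function(m) sweep(m, 2, colSums(m), "/")
  M <- normalize(A)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2[M2 < 1e-14] <- 0
    M2 <- normalize(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop("MCL did not converge in ", max_iter,
         " iterations (residual ", signif(delta, 3), ")")
  }
  ## attractor of column j = row with the largest mass
  uf <- uf_new(length(nodes))
  for (j in seq_along(nodes)) {
    attr_rows <- which(M[, j] > 1e-6)
    if (length(attr_rows) == 0) next  # numerically isolated: singleton
    best <- attr_rows[order(-M[attr_rows, j], nodes[attr_rows])][1]
    uf <- uf_union(uf, j, best)
  }
  roots <- vapply(seq_along(nodes), function(i) uf_find(uf, i), integer(1))
  cluster <- match(roots, sort(unique(roots)))
  stats::setNames(cluster, nodes)
}

#' Build family presence/absence profiles from clusters
#'
#' @param clusters named cluster membership from [mcl_cluster()] (or any
#'   named integer/character vector: sequence id -> family).
#' @param sequence_to_taxon named character vector: sequence id -> taxon.
#' @return logical matrix, families (rows, named `fam<k>`) by taxa
#'   (columns): `TRUE` iff the family contains at least one sequence from
#'   the taxon.
#' @export
build_profiles <- function(clusters, sequence_to_taxon) {
  missing <- setdiff(names(clusters), names(sequence_to_taxon))
  if (length(missing)) {
    stop("sequence without taxon mapping: ", paste(missing, collapse = ", "))
  }
  taxa <- sort(unique(sequence_to_taxon[names(clusters)]))
  fams <- sort(unique(clusters))
  m <- matrix(FALSE, length(fams), length(taxa),
              dimnames = list(paste0("fam", fams), taxa))
  for (i in seq_along(clusters)) {
    m[paste0("fam", clusters[i]), sequence_to_taxon[[names(clusters)[i]]]] <- TRUE
  }
  m
}

## children list indexed by node for an ape phylo tree
tree_children <- function(tree) {
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  ch <- vector("list", n_nodes)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    ch[[p]] <- c(ch[[p]], tree$edge[i, 2])
  }
  ch
}

## tip numbers under each node
tree_clades <- function(tree) {
  ch <- tree_children(tree)
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  clade <- vector("list", n_nodes)
  fill <- function(v) {
    if (is.null(ch[[v]])) { clade[[v]] <<- v; return(v) }
    tips <- unlist(lapply(ch[[v]], fill))
    clade[[v]] <<- tips
    tips
  }
  fill(ape::Ntip(tree) + 1L)
  clade
}

#' Dollo-parsimony reconstruction of one gene family
#'
#' Under Dollo parsimony a family is gained exactly once and can only be
#' lost afterwards.  The gain is placed on the branch above the lowest
#' common ancestor of all taxa carrying the family (the root edge when that
#' ancestor is the root); losses are the maximal branches inside the gain
#' clade whose entire leaf set lacks the family.  This placement minimizes
#' the number of losses among all single-gain scenarios.
#'
#' @param tree a rooted [ape::phylo] tree.
#' @param presence named logical vector over the tree's tip labels.
#' @return list with `gain_node` (the node below the gain branch),
#'   `loss_nodes` (nodes below loss branches), and `node_presence`
#'   (logical per node, tips first then internal nodes, in ape numbering).
#' @export
dollo_reconstruct <- function(tree, presence) {
  tips <- tree$tip.label
  if (!setequal(names(presence), tips)) {
    stop("presence names must match the tree's tip labels")
  }
  presence <- presence[tips]
  if (!any(presence)) stop("family absent from every taxon")
  n_tip <- ape::Ntip(tree)
  n_nodes <- n_tip + tree$Nnode
  present_tips <- unname(which(presence))
  gain_node <- if (length(present_tips) == 1) {
    present_tips
  } else {
    ape::getMRCA(tree, present_tips)
  }
  ch <- tree_children(tree)
  clades <- tree_clades(tree)
  node_presence <- rep(FALSE, n_nodes)
  loss_nodes <- integer(0)
  walk <- function(v) {
    tips_v <- clades[[v]]
    if (!any(presence[tips_v])) {
      loss_nodes <<- c(loss_nodes, v)
      return(invisible())
    }
    node_presence[v] <<- TRUE
    for (c in ch[[v]]) walk(c)
  }
  walk(gain_node)
  list(gain_node = gain_node, loss_nodes = sort(loss_nodes),
       node_presence = node_presence)
}

#' Reconstruct all families of a profile matrix
#'
#' @param tree rooted [ape::phylo].
#' @param profiles logical family-by-taxon matrix (see [build_profiles()]).
#' @return named list of [dollo_reconstruct()] results, one per family.
#' @export
dollo_reconstruct_all <- function(tree, profiles) {
  stats::setNames(lapply(rownames(profiles), function(f) {
    dollo_reconstruct(tree, stats::setNames(profiles[f, ],
                                            colnames(profiles)))
  }), rownames(profiles))
}

#' Per-branch gain/loss tallies and per-node family counts
#'
#' Branches are identified by their child node.  The tallies satisfy the
#' conservation identity `count(child) = count(parent) + gains(child) -
#' losses(child)` along every edge; `count(root)` equals the number of
#' families gained on the root edge.
#'
#' @param reconstructions list from [dollo_reconstruct_all()].
#' @param tree rooted [ape::phylo].
#' @return list with `branch_events` (`data.frame(node, n_gains,
#'   n_losses)`) and `node_family_counts` (integer per node).
#' @export
branch_event_summary <- function(reconstructions, tree) {
  if (length(reconstructions) == 0) stop("no reconstructions supplied")
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  gains <- integer(n_nodes)
  losses <- integer(n_nodes)
  counts <- integer(n_nodes)
  for (rec in reconstructions) {
    gains[rec$gain_node] <- gains[rec$gain_node] + 1L
    losses[rec$loss_nodes] <- losses[rec$loss_nodes] + 1L
    counts <- counts + rec$node_presence
  }
  list(branch_events = data.frame(node = seq_len(n_nodes), n_gains = gains,
                                  n_losses = losses),
       node_family_counts = counts)
}
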