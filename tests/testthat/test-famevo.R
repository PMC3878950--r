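test_that("longest isoform per component is kept, ties by id", {
  rec <- transcript_records(
    c("c1_seq1", "c1_seq2", "c2_seq1", "c3_seq1", "c3_seq2"),
    c(strrep("A", 300), strrep("A", 500), strrep("A", 100),
      strrep("A", 200), strrep("A", 200)))
  out <- longest_isoform_filter(rec)
  expect_equal(out$id, c("c1_seq2", "c2_seq1", "c3_seq1"))
  expect_equal(nrow(out), 3)
})

test_that("similarity graph takes the max bitscore over both directions", {
  h <- make_hits(c("x", "y", "x"), c("y", "x", "z"), c(50, 80, 30))
  g <- similarity_graph(h)
  expect_setequal(g$nodes, c("x", "y", "z"))
  expect_equal(g$edges$weight[g$edges$a == "x" & g$edges$b == "y"], 80)
  # hits above the cutoff are excluded
  weak <- make_hits("x", "y", 50, evalue = 1e-3)
  expect_equal(nrow(similarity_graph(weak)$edges), 0)
})

test_that("MCL separates components and cuts weak bridges", {
  tri <- function(p, w = 1) data.frame(
    a = paste0(p, c(1, 1, 2)), b = paste0(p, c(2, 3, 3)), weight = w)
  two_tri <- list(nodes = c(paste0("u", 1:3), paste0("v", 1:3)),
                  edges = rbind(tri("u"), tri("v")))
  cl <- mcl_cluster(two_tri)
  expect_equal(length(unique(cl)), 2)
  expect_equal(length(unique(cl[paste0("u", 1:3)])), 1)
  expect_equal(length(unique(cl[paste0("v", 1:3)])), 1)

  # isolated node forms a singleton
  iso <- list(nodes = c("a", "b", "solo"),
              edges = data.frame(a = "a", b = "b", weight = 1))
  cli <- mcl_cluster(iso)
  expect_equal(sum(cli == cli[["solo"]]), 1)

  # 6-node barbell with a weak bridge: inflation 2 yields two 3-node clusters
  barbell <- list(nodes = paste0("n", 1:6),
                  edges = data.frame(
                    a = c("n1", "n1", "n2", "n4", "n4", "n5", "n3"),
                    b = c("n2", "n3", "n3", "n5", "n6", "n6", "n4"),
                    weight = c(1, 1, 1, 1, 1, 1, 0.1)))
  clb <- mcl_cluster(barbell, inflation = 2.0)
  expect_equal(length(unique(clb)), 2)
  expect_equal(length(unique(clb[paste0("n", 1:3)])), 1)
  expect_equal(length(unique(clb[paste0("n", 4:6)])), 1)
})

test_that("MCL yields a partition that never crosses connected components", {
  set.seed(19)
  for (k in 1:10) {
    # two random blocks with no connecting edges
    mk <- function(p, n) {
      pairs <- t(combn(n, 2))
      keep <- runif(nrow(pairs)) < 0.6
      data.frame(a = paste0(p, pairs[keep, 1]), b = paste0(p, pairs[keep, 2]),
                 weight = runif(sum(keep), 0.5, 2))
    }
    nA <- sample(3:6, 1); nB <- sample(3:6, 1)
    g <- list(nodes = c(paste0("A", 1:nA), paste0("B", 1:nB)),
              edges = rbind(mk("A", nA), mk("B", nB)))
    cl <- mcl_cluster(g)
    expect_setequal(names(cl), g$nodes)             # partition: all nodes once
    crossing <- intersect(unique(cl[paste0("A", 1:nA)]),
                          unique(cl[paste0("B", 1:nB)]))
    expect_length(crossing, 0)
    expect_identical(cl, mcl_cluster(g))            # deterministic
  }
})

test_that("profiles mark presence per taxon and demand a mapping", {
  cl <- c(a_Tc = 1L, b_Tg = 1L, c_Tc = 2L)
  map <- c(a_Tc = "Tcal", b_Tg = "Tgra", c_Tc = "Tcal")
  p <- build_profiles(cl, map)
  expect_equal(unname(p["fam1", c("Tcal", "Tgra")]), c(TRUE, TRUE))
  expect_equal(unname(p["fam2", c("Tcal", "Tgra")]), c(TRUE, FALSE))
  expect_error(build_profiles(c(cl, z = 3L), map), "without taxon")
})

test_that("Dollo reconstruction handles the canonical cases", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  root <- ape::Ntip(tr) + 1

  all_present <- dollo_reconstruct(tr, c(A = TRUE, B = TRUE, C = TRUE,
                                         D = TRUE))
  expect_equal(all_present$gain_node, root)
  expect_length(all_present$loss_nodes, 0)

  only_a <- dollo_reconstruct(tr, c(A = TRUE, B = FALSE, C = FALSE,
                                    D = FALSE))
  expect_equal(only_a$gain_node, which(tr$tip.label == "A"))
  expect_length(only_a$loss_nodes, 0)

  abd <- dollo_reconstruct(tr, c(A = TRUE, B = TRUE, C = FALSE, D = TRUE))
  expect_equal(abd$gain_node, root)
  expect_equal(abd$loss_nodes, which(tr$tip.label == "C"))

  expect_error(dollo_reconstruct(tr, c(A = FALSE, B = FALSE, C = FALSE,
                                       D = FALSE)), "absent from every")
})

test_that("Dollo reconstruction equals the exhaustive single-gain search", {
  set.seed(83)
  for (k in 1:150) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n, tip.label = paste0("t", 1:n))
    pres <- stats::setNames(runif(n) < 0.5, tr$tip.label)
    if (!any(pres)) pres[sample(n, 1)] <- TRUE
    got <- dollo_reconstruct(tr, pres)
    want <- oracle_dollo(tr, pres)
    expect_equal(got$gain_node, want$gain_node)
    expect_equal(length(got$loss_nodes), want$losses)
  }
})

test_that("simulated gains are recovered and branch events balance", {
  tr <- random_rooted_tree(8, seed = 14)
  sim0 <- simulate_family_profiles(tr, 100, 0, seed = 15)
  rec0 <- dollo_reconstruct_all(tr, sim0$profiles)
  hits <- vapply(seq_len(100), function(i) {
    rec0[[i]]$gain_node == sim0$truth[[i]]$gain_node
  }, logical(1))
  expect_true(all(hits))

  sim <- simulate_family_profiles(tr, 200, 0.2, seed = 16)
  rec <- dollo_reconstruct_all(tr, sim$profiles)
  ev <- branch_event_summary(rec, tr)
  expect_equal(sum(ev$branch_events$n_gains), 200)  # exactly one gain each
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    expect_equal(ev$node_family_counts[child],
                 ev$node_family_counts[parent] +
                   ev$branch_events$n_gains[child] -
                   ev$branch_events$n_losses[child])
  }
})

test_that("branch summary matches hand tallies on a scripted family set", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  root <- 5; ab <- 6; cd <- 7
  recs <- list(
    dollo_reconstruct(tr, c(A = TRUE, B = TRUE, C = TRUE, D = TRUE)),
    dollo_reconstruct(tr, c(A = TRUE, B = TRUE, C = FALSE, D = FALSE)),
    dollo_reconstruct(tr, c(A = TRUE, B = TRUE, C = FALSE, D = TRUE)))
  ev <- branch_event_summary(recs, tr)
  # gains: fam1 + fam3 at the root, fam2 on the (A,B) branch
  expect_equal(ev$branch_events$n_gains[root], 2L)
  expect_equal(ev$branch_events$n_gains[ab], 1L)
  # losses: fam3 loses C on its terminal branch
  expect_equal(ev$branch_events$n_losses[which(tr$tip.label == "C")], 1L)
  # node counts: root carries 2 families, (A,B) ancestor carries 3
  expect_equal(ev$node_family_counts[root], 2L)
  expect_equal(ev$node_family_counts[ab], 3L)
  expect_equal(ev$node_family_counts[cd], 2L)
})
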