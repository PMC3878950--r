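tax <- toy_taxonomy()

test_that("sequence complexity matches the closed-form entropy values", {
  expect_equal(sequence_complexity("AAAA"), 0)
  expect_equal(sequence_complexity("ACGT"), 1)
  expect_equal(sequence_complexity("AACC"), 0.5)
  expect_equal(sequence_complexity("NNNN"), 0)  # no unambiguous bases
})

test_that("assign_lca applies score, top-percent and complexity filters", {
  # one hit to a leaf -> that leaf
  a <- assign_lca(make_hits("q1", "p1", 80, taxon = "10"), tax)
  expect_equal(a$taxon_id, "10")

  # equal-score hits to sibling species -> their genus
  h <- make_hits(c("q1", "q1"), c("p1", "p2"), c(80, 80),
                 taxon = c("10", "11"))
  expect_equal(assign_lca(h, tax)$taxon_id, "9")

  # top-percent window: 85 < 0.9 * 100 -> second hit dropped
  h <- make_hits(c("q1", "q1"), c("p1", "p2"), c(100, 85),
                 taxon = c("10", "13"))
  a <- assign_lca(h, tax, lca_params(top_percent = 10))
  expect_equal(a$taxon_id, "10")
  expect_equal(a$n_hits_used, 1L)
  # widening the window to 20% keeps both -> Arthropoda (6)
  expect_equal(assign_lca(h, tax, lca_params(top_percent = 20))$taxon_id, "6")

  # all hits below min_score -> unassigned
  low <- make_hits("q1", "p1", 20, taxon = "10")
  expect_true(is.na(assign_lca(low, tax)$taxon_id))

  # low-complexity query sequence -> unassigned before any hit is used
  a <- assign_lca(make_hits("q1", "p1", 80, taxon = "10"), tax,
                  query_sequence = strrep("A", 60))
  expect_true(is.na(a$taxon_id))

  expect_error(assign_lca(make_hits("q1", "p1", 80, taxon = "999"), tax),
               "999")
})

test_that("minimum-support promotion moves queries up until supported", {
  asg <- data.frame(query_id = paste0("q", 1:4),
                    taxon_id = rep("10", 4), n_hits_used = 1L,
                    stringsAsFactors = FALSE)
  # 4 assignments at a species with min_support 5: promoted toward the root;
  # with only 4 queries total they never reach support and become unassigned
  out <- apply_min_support(asg, tax, min_support = 5)
  expect_true(all(is.na(out$taxon_id)))

  # 5 queries at the species stay put
  asg5 <- data.frame(query_id = paste0("q", 1:5), taxon_id = rep("10", 5),
                     n_hits_used = 1L, stringsAsFactors = FALSE)
  expect_equal(apply_min_support(asg5, tax, min_support = 5)$taxon_id,
               rep("10", 5))

  # 4 at the species plus 1 at the genus: subtree support at the genus is 5,
  # so the species queries stop at the genus
  asg41 <- data.frame(query_id = paste0("q", 1:5),
                      taxon_id = c(rep("10", 4), "9"), n_hits_used = 1L,
                      stringsAsFactors = FALSE)
  out41 <- apply_min_support(asg41, tax, min_support = 5)
  expect_equal(out41$taxon_id, rep("9", 5))

  # min_support 1 is the identity
  expect_equal(apply_min_support(asg, tax, min_support = 1), asg)
})

test_that("the spider/meta split partitions queries by clade", {
  asg <- data.frame(query_id = c("sp1", "nem1", "fun1", "un1"),
                    taxon_id = c("10", "17", "16", NA), n_hits_used = 1L,
                    stringsAsFactors = FALSE)
  sp <- split_spider_meta(asg, tax)
  expect_equal(sp$spider_ids, "sp1")       # Theridion species -> spider
  expect_setequal(sp$meta_ids, c("nem1", "fun1"))  # Nematoda + Fungi -> meta
  expect_equal(sp$unassigned_ids, "un1")
  # partition: disjoint and exhaustive
  all_ids <- c(sp$spider_ids, sp$meta_ids, sp$unassigned_ids)
  expect_setequal(all_ids, asg$query_id)
  expect_equal(length(all_ids), nrow(asg))
  expect_error(split_spider_meta(asg, tax, keep_clade = "NoSuchClade"),
               "not resolvable")
})

test_that("LCA assignment equals the naive path-intersection oracle", {
  set.seed(17)
  for (k in 1:40) {
    rt <- random_taxonomy(sample(10:40, 1))
    taxa <- sample(rt$taxon_id, sample(1:6, 1), replace = TRUE)
    h <- make_hits(rep("q", length(taxa)), paste0("p", seq_along(taxa)),
                   rep(50, length(taxa)), taxon = taxa)
    a <- assign_lca(h, rt, lca_params(min_score = 0, top_percent = 100))
    expect_equal(a$taxon_id, oracle_lca(taxa, rt))
    # the assignment is an ancestor-or-equal of every hit taxon
    for (t in taxa) expect_true(a$taxon_id %in% taxon_path(t, rt))
  }
})

test_that("shrinking the retained-hit set refines the assignment", {
  set.seed(23)
  for (k in 1:30) {
    rt <- random_taxonomy(25)
    n <- sample(2:6, 1)
    h <- make_hits(rep("q", n), paste0("p", 1:n),
                   runif(n, 40, 100), taxon = sample(rt$taxon_id, n, TRUE))
    loose <- assign_lca(h, rt, lca_params(min_score = 0, top_percent = 100))
    strict <- assign_lca(h, rt, lca_params(min_score = 0, top_percent = 20))
    # strict assignment must lie on or below the loose one
    expect_true(loose$taxon_id %in% taxon_path(strict$taxon_id, rt))
  }
})

test_that("planted contaminants are recovered from simulated hit tables", {
  sim <- simulate_hits(synth_config(seed = 13, contaminant_fraction = 0.25))
  asg <- assign_lca_all(sim$hits_ab, sim$taxonomy, lca_params(min_support = 1))
  sp <- split_spider_meta(asg, sim$taxonomy)
  expect_setequal(sp$meta_ids, sim$truth$contaminants)
  n <- length(unique(sim$hits_ab$query_id))
  frac <- length(sp$meta_ids) / n
  expect_lt(abs(frac - 0.25), 4 * sqrt(0.25 * 0.75 / n))
})
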