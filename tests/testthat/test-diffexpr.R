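test_that("housekeeping selection keeps single-component, two-species, RBH-verified candidates", {
  hits_a <- make_hits(c("P1", "P2", "P2", "P3"),
                      c("a1_seq1", "a2_seq1", "a3_seq1", "a4_seq1"),
                      c(100, 90, 80, 70))
  hits_b <- make_hits(c("P1", "P2"), c("b1_seq1", "b2_seq1"), c(95, 85))
  comp_a <- c(a1_seq1 = "a1", a2_seq1 = "a2", a3_seq1 = "a3", a4_seq1 = "a4")
  comp_b <- c(b1_seq1 = "b1", b2_seq1 = "b2")
  rbh_a <- data.frame(a_id = "P1", b_id = "a1", ab_bitscore = 1,
                      ba_bitscore = 1, stringsAsFactors = FALSE)
  rbh_b <- data.frame(a_id = "P1", b_id = "b1", ab_bitscore = 1,
                      ba_bitscore = 1, stringsAsFactors = FALSE)
  hk <- select_hk_genes(hits_a, hits_b, comp_a, comp_b, rbh_a, rbh_b)
  # P1: single component in both species + RBH in both -> valid
  expect_true(hk$rbh_verified[hk$candidate_id == "P1"])
  # P2: hits two components in species A -> dropped entirely
  expect_false("P2" %in% hk$candidate_id)
  # P3: absent from species B -> dropped
  expect_false("P3" %in% hk$candidate_id)
})

test_that("normalization factors equalize HK totals with geometric mean one", {
  counts <- matrix(c(500L, 500L, 1000L, 1000L,
                     50L, 20L, 100L, 40L), nrow = 2, byrow = TRUE,
                   dimnames = list(c("hk1", "g1"),
                                   c("s1", "s2", "s3", "s4")))
  f <- hk_normalization_factors(counts, "hk1")
  expect_equal(unname(f), c(500, 500, 1000, 1000) / sqrt(5e5))
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  norm_tot <- colSums(normalize_counts(counts, f)["hk1", , drop = FALSE])
  expect_true(max(abs(norm_tot / norm_tot[1] - 1)) < 1e-9)

  # two samples with HK totals 1000 and 2000 -> factors (1/sqrt2, sqrt2)
  c2 <- matrix(c(1000L, 2000L), 1, dimnames = list("hk1", c("s1", "s2")))
  expect_equal(unname(hk_normalization_factors(c2, "hk1")),
               c(1 / sqrt(2), sqrt(2)))

  # doubling one sample's counts doubles its factor relative to the others
  c3 <- c2; c3[, "s1"] <- c3[, "s1"] * 2L
  f2 <- hk_normalization_factors(c2, "hk1")
  f3 <- hk_normalization_factors(c3, "hk1")
  expect_equal((f3[["s1"]] / f3[["s2"]]) / (f2[["s1"]] / f2[["s2"]]), 2)

  c0 <- matrix(c(0L, 10L), 1, dimnames = list("hk1", c("s1", "s2")))
  expect_error(hk_normalization_factors(c0, "hk1"), "zero housekeeping")
  expect_error(hk_normalization_factors(counts, character(0)), "empty")
})

test_that("common dispersion is recovered from Poisson and degenerate data", {
  set.seed(44)
  # Poisson counts (phi = 0): estimate collapses toward the lower bound
  pois <- matrix(rpois(200 * 4, 500), 200, 4,
                 dimnames = list(paste0("hk", 1:200),
                                 c("s1", "s2", "s3", "s4")))
  f <- rep(1, 4)
  d <- estimate_common_dispersion(pois, rownames(pois), f,
                                  c("Y", "C", "Y", "C"))
  expect_lt(d$phi, 0.01)

  # identical counts across samples: dispersion at the lower bound
  const <- matrix(500L, 50, 4, dimnames = list(paste0("hk", 1:50),
                                               paste0("s", 1:4)))
  d0 <- estimate_common_dispersion(const, rownames(const), f,
                                   c("Y", "C", "Y", "C"))
  expect_equal(d0$phi, 1e-6, tolerance = 1e-3)

  expect_error(estimate_common_dispersion(pois[, 1, drop = FALSE],
                                          rownames(pois), 1, "Y"),
               ">= 2 samples")
})

test_that("the exact NB test matches its closed forms and the enumeration oracle", {
  # observed at the mode: everything is at least as extreme
  expect_equal(exact_nb_test(7, 7, 1, 1, 0.3), 1)
  # (0, 10) under phi = 0, equal sizes: the two extreme splits
  expect_equal(exact_nb_test(0, 10, 1, 1, 0), 2 * 0.5^10)
  expect_equal(exact_nb_test(10, 0, 1, 1, 0), 2 * 0.5^10)

  set.seed(61)
  for (k in 1:100) {
    y1 <- sample(0:100, 1); y2 <- sample(0:100, 1)
    n1 <- sample(1:3, 1); n2 <- sample(1:3, 1)
    phi <- runif(1, 0, 1.5)
    expect_equal(exact_nb_test(y1, y2, n1, n2, phi),
                 oracle_nb_test(y1, y2, n1, n2, phi), tolerance = 1e-10)
    # symmetry under equal effective sizes
    expect_equal(exact_nb_test(y1, y2, 2, 2, phi),
                 exact_nb_test(y2, y1, 2, 2, phi))
  }

  # phi -> 0 approaches the conditional binomial
  expect_equal(exact_nb_test(3, 12, 1, 1, 1e-8),
               exact_nb_test(3, 12, 1, 1, 0), tolerance = 1e-6)

  expect_error(exact_nb_test(-1, 3, 1, 1, 0.1), "non-negative")
  expect_error(exact_nb_test(1, 3, 0, 1, 0.1), "positive")
  expect_error(exact_nb_test(1, 3, 1, 1, -0.1), "non-negative")
})

test_that("the exact NB test agrees with edgeR's small-p exact test", {
  set.seed(71)
  y1 <- matrix(rnbinom(40, mu = 300, size = 5), 20, 2)
  y2 <- matrix(rnbinom(40, mu = 300, size = 5), 20, 2)
  ref <- edgeR::exactTestBySmallP(y1, y2, dispersion = 0.2)
  mine <- vapply(1:20, function(g) {
    exact_nb_test(sum(y1[g, ]), sum(y2[g, ]), 2, 2, 0.2)
  }, numeric(1))
  expect_equal(mine, ref, tolerance = 1e-8)
})

test_that("BH adjustment matches the step-up construction", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(2)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= p) && all(q <= 1))
  # monotone in p-rank
  expect_true(all(diff(q[order(p)]) >= 0))
})

test_that("log2 fold-change uses the prior symmetric around zero", {
  expect_equal(log2_fold_change(10, 10), 0)
  expect_equal(log2_fold_change(40000, 10000), 2, tolerance = 1e-3)
  expect_equal(log2_fold_change(0, 0), 0)
  expect_equal(log2_fold_change(c(100, 300), c(50, 150)), 1,
               tolerance = 1e-2)
})

test_that("the housekeeping band reproduces the fold-change conversion", {
  b0 <- hk_band(c(0, 0, 0))
  expect_equal(c(b0$lo, b0$hi), c(0, 0))
  # two points with mean 0.145 and sd 0.4475 -> edges (-0.75, 1.04)
  vals <- c(0.145 - 0.4475 / sqrt(2), 0.145 + 0.4475 / sqrt(2))
  b <- hk_band(vals)
  expect_equal(b$hk_mean, 0.145)
  expect_equal(b$hk_sd, 0.4475, tolerance = 1e-12)
  expect_equal(b$lo, -0.75, tolerance = 1e-12)
  expect_equal(b$hi, 1.04, tolerance = 1e-12)
  expect_equal(b$fc_lo, 2^-0.75)
  expect_equal(b$fc_hi, 2^1.04)
  expect_error(hk_band(0.3), ">= 2")
})

test_that("the full panel chain flags planted signal and spares null genes", {
  cfg <- synth_config(seed = 51, nb_dispersion = 0.05,
                      pigment_log2fc_range = c(3, 3),
                      mu_range = c(500, 2000))
  sim <- simulate_counts(cfg)
  de <- pigment_panel_de(sim$counts, sim$pigment_ids, sim$hk_ids, sim$design)
  expect_true(all(de$table$band_class == "UP_BEYOND_BAND"))
  # output ordered by decreasing fold-change
  expect_true(all(diff(de$table$log2fc) <= 0))
  # estimated fold-changes all have the planted sign
  expect_true(all(de$table$log2fc > 0))

  cfg0 <- synth_config(seed = 52, pigment_log2fc_range = c(0, 0))
  sim0 <- simulate_counts(cfg0)
  de0 <- pigment_panel_de(sim0$counts, sim0$pigment_ids, sim0$hk_ids,
                          sim0$design)
  expect_gte(mean(de0$table$band_class == "WITHIN"), 0.85)
})

test_that("expression ranking orders by mean normalized count", {
  counts <- matrix(c(10L, 20L, 400L, 600L, 400L, 600L), 3, 2, byrow = TRUE,
                   dimnames = list(c("low", "hi1", "hi2"), c("s1", "s2")))
  r <- rank_expression(counts, c(s1 = 1, s2 = 1), top_n = 10)
  expect_equal(r$gene_id, c("hi1", "hi2", "low"))  # tie broken by id
  expect_equal(nrow(rank_expression(counts, c(s1 = 1, s2 = 1), 2)), 2)
  one <- rank_expression(counts[1, , drop = FALSE], c(s1 = 1, s2 = 1), 1)
  expect_equal(one$rank, 1L)
})

test_that("mapped-read difference contrasts a moving panel with a stable baseline", {
  counts <- matrix(c(100L, 100L,   # hk: same share
                     100L, 300L,   # pigment: moves
                     800L, 600L),  # filler keeps totals equal
                   3, 2, byrow = TRUE,
                   dimnames = list(c("hk1", "pig1", "bg1"), c("Y", "C")))
  hk_d <- mapped_read_difference(counts, "hk1", "Y", "C")
  pig_d <- mapped_read_difference(counts, "pig1", "Y", "C")
  expect_equal(hk_d, 0)
  expect_equal(pig_d, 0.2)
})
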