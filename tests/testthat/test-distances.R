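test_that("Bray-Curtis follows its closed form", {
  expect_equal(bray_curtis(c(2, 3), c(2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 2)), 1) # disjoint supports
  expect_equal(bray_curtis(c(1, 1), c(1, 0)), 1 / 3)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "undefined")
  # matrix route agrees with the scalar definition
  set.seed(2)
  m <- matrix(rexp(12), 3, 4)
  d <- as.matrix(beta_distance(m, "bray-curtis"))
  expect_equal(d[1, 2], bray_curtis(m[1, ], m[2, ]), tolerance = 1e-12)
})

test_that("UniFrac trivial geometries", {
  tr2 <- ape::read.tree(text = "(t1:1,t2:1);")
  expect_equal(unweighted_unifrac(tr2, c(t1 = 1), c(t2 = 1)), 1)
  expect_equal(weighted_unifrac(tr2, c(t1 = 1, t2 = 0), c(t1 = 0, t2 = 1)), 1)
  expect_equal(weighted_unifrac(tr2, c(t1 = 0.3, t2 = 0.7),
                                c(t1 = 0.3, t2 = 0.7)), 0)
  tr3 <- ape::read.tree(text = "((t1:1,t2:1):1,t3:1);")
  expect_equal(unweighted_unifrac(tr3, c(t1 = 1, t2 = 1), c(t1 = 1, t2 = 1)),
               0)
  # hand enumeration for a = {t1,t2}, b = {t2,t3} on unit branches:
  # unique: t1 branch (1) + t3 branch (1); union adds t2 (1) + stem of
  # (t1,t2) clade (1) -> 2/4
  expect_equal(unweighted_unifrac(tr3, c(t1 = 1, t2 = 1), c(t2 = 1, t3 = 1)),
               oracle_unweighted_unifrac(tr3, c("t1", "t2"), c("t2", "t3")))
  expect_equal(unweighted_unifrac(tr3, c(t1 = 1, t2 = 1), c(t2 = 1, t3 = 1)),
               2 / 4)
  expect_error(unweighted_unifrac(tr3, c(t1 = 0), c(t2 = 1)), "non-empty")
  expect_error(weighted_unifrac(tr3, c(t1 = 0.5), c(t3 = 1)), "summing to 1")
  expect_error(weighted_unifrac(tr3, c(zz = 1), c(t3 = 1)), "absent")
})

test_that("UniFrac equals the brute-force branch oracle on random trees", {
  set.seed(11)
  for (i in 1:40) {
    ntip <- sample(3:8, 1)
    tr <- ape::rtree(ntip)
    a <- random_relabund(tr$tip.label)
    b <- random_relabund(tr$tip.label)
    expect_equal(weighted_unifrac(tr, a, b),
                 oracle_weighted_unifrac(tr, a, b), tolerance = 1e-10)
    expect_equal(weighted_unifrac(tr, a, b, normalized = FALSE),
                 oracle_weighted_unifrac(tr, a, b, normalized = FALSE),
                 tolerance = 1e-10)
    pa <- names(a)[a > stats::median(a)]
    pb <- names(b)[b > stats::median(b)]
    if (length(pa) && length(pb)) {
      av <- setNames(as.numeric(tr$tip.label %in% pa), tr$tip.label)
      bv <- setNames(as.numeric(tr$tip.label %in% pb), tr$tip.label)
      expect_equal(unweighted_unifrac(tr, av, bv),
                   oracle_unweighted_unifrac(tr, pa, pb), tolerance = 1e-10)
    }
  }
})

test_that("matrix UniFrac agrees with the pairwise scalar version", {
  co <- generate_cohort(synthetic_config(n_samples = 6, n_otus = 25,
                                         n_genera = 10, seed = 13))
  rel <- to_relative_abundance(co$otu_table$counts)
  dmat <- as.matrix(beta_distance(co$otu_table$counts, "weighted-unifrac",
                                  tree = co$tree))
  for (pair in list(c(1, 2), c(3, 6))) {
    expect_equal(dmat[pair[1], pair[2]],
                 weighted_unifrac(co$tree, rel[pair[1], ], rel[pair[2], ]),
                 tolerance = 1e-10)
  }
  du <- as.matrix(beta_distance(co$otu_table$counts, "unweighted-unifrac",
                                tree = co$tree))
  expect_equal(du[1, 3],
               unweighted_unifrac(co$tree, rel[1, ], rel[3, ]),
               tolerance = 1e-10)
  # metric axioms
  expect_true(all(abs(dmat - t(dmat)) < 1e-12))
  expect_true(all(diag(dmat) == 0) && all(dmat >= 0) && all(dmat <= 1))
})

test_that("PCoA recovers collinear points and flags negative eigenvalues", {
  x <- c(0, 1, 3, 7, 12)
  d <- dist(x)
  ord <- pcoa_ordination(d, n_axes = 2)
  # axis 1 recovers the line up to sign/scale: pairwise distances match
  rec <- dist(ord$points[, 1])
  expect_equal(as.numeric(rec), as.numeric(d), tolerance = 1e-8)
  # duplicated sample lands on the same coordinates
  m <- as.matrix(dist(c(0, 1, 3, 3)))
  ord2 <- pcoa_ordination(m, n_axes = 1)
  expect_equal(ord2$points[3, 1], ord2$points[4, 1], tolerance = 1e-10)
  # sum of positive eigenvalues <= trace of the centered Gower matrix
  set.seed(5)
  dm <- dist(matrix(rnorm(30), 10, 3))
  ord3 <- pcoa_ordination(dm, n_axes = 3)
  ev <- ord3$eigenvalues
  expect_lte(sum(ev[ev > 0]), sum(ev[ev > 0]) - sum(ev[ev < 0]) + 1e-9)
  expect_warning(pcoa_ordination(dist(c(0, 1, 3)), n_axes = 5), "truncated")
})

test_that("NMDS reaches near-zero stress on embeddable distances", {
  set.seed(8)
  pts <- matrix(rnorm(24), 12, 2)
  d <- dist(pts)
  ord <- nmds_ordination(d, k = 2, seed = 4)
  expect_lt(ord$stress, 0.01)
  ord_again <- nmds_ordination(d, k = 2, seed = 4)
  expect_equal(ord$points, ord_again$points)
  # stress is non-increasing in the embedding dimension (up to optimizer
  # noise once both runs are near convergence)
  co <- generate_cohort(synthetic_config(n_samples = 30, n_otus = 60,
                                         n_genera = 25, seed = 6))
  db <- beta_distance(genus_table(co$otu_table, relative = TRUE),
                      "bray-curtis")
  s2 <- nmds_ordination(db, k = 2, seed = 1)$stress
  s3 <- nmds_ordination(db, k = 3, seed = 1)$stress
  expect_lte(s3, s2 + 1e-3)
})
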