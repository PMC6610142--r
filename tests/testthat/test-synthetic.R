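test_that("generate_tree yields rooted binary trees, deterministically", {
  tr <- generate_tree(2, seed = 1)
  expect_equal(length(tr$tip.label), 2)
  expect_equal(length(tr$edge.length), 2)
  expect_true(all(tr$edge.length > 0))

  t1 <- ape::write.tree(generate_tree(100, seed = 7))
  t2 <- ape::write.tree(generate_tree(100, seed = 7))
  expect_identical(t1, t2)

  tr50 <- generate_tree(50, seed = 3)
  expect_gt(sum(tr50$edge.length), 0)
  expect_false(anyDuplicated(tr50$tip.label) > 0)
  expect_true(ape::is.rooted(tr50) && ape::is.binary(tr50))
  expect_error(generate_tree(1), "n_otus")
})

test_that("cohorts are bit-identical given the same config", {
  cfg <- synthetic_config(n_samples = 10, n_otus = 40, n_genera = 15,
                          seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$otu_table$counts, b$otu_table$counts)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$scfa, b$scfa)
  expect_identical(a$metabolite_bins, b$metabolite_bins)
})

test_that("cohort invariants hold: labels, SCFA simplex, integer counts", {
  co <- fixture_cohort()
  expect_true(all(co$true_labels %in% 1:2))
  expect_equal(length(co$true_labels), nrow(co$otu_table$counts))
  expect_equal(rowSums(co$scfa), rep(1, nrow(co$scfa)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(co$otu_table$counts >= 0))
  expect_true(is.integer(co$otu_table$counts))
  # genus clades: each genus's OTUs form a monophyletic group
  tax <- co$otu_table$taxonomy
  some_genera <- unique(tax$genus)[1:10]
  for (g in some_genera) {
    tips <- tax$otu_id[tax$genus == g]
    if (length(tips) >= 2 &&
        length(tips) < length(co$tree$tip.label)) {
      expect_true(ape::is.monophyletic(co$tree, tips))
    }
  }
})

test_that("null configuration gives identical expected genus profiles", {
  cfg <- synthetic_config(effect_size = 0, n_exclusive_genera = 0L, seed = 9)
  co <- generate_cohort(cfg)
  # with no shift and no exclusives both communities share the base alphas:
  # compare mean relative genus abundance between communities on many samples
  cfg_big <- synthetic_config(n_samples = 600, n_otus = 60, n_genera = 20,
                              effect_size = 0, n_exclusive_genera = 0L,
                              depth_log_mean = log(1000), seed = 9)
  big <- generate_cohort(cfg_big)
  g <- genus_table(big$otu_table, relative = TRUE)
  lab <- big$true_labels[rownames(g)]
  m1 <- colMeans(g[lab == 1, ])
  m2 <- colMeans(g[lab == 2, ])
  se <- sqrt(apply(g[lab == 1, ], 2, var) / sum(lab == 1) +
               apply(g[lab == 2, ], 2, var) / sum(lab == 2))
  expect_true(all(abs(m1 - m2) < 4 * se + 1e-12))
  expect_identical(sum(co$genus_info$exclusive_to != 0), 0L)
})

test_that("empirical genus means match the analytic Dirichlet means", {
  cfg <- synthetic_config(n_samples = 4000, n_otus = 60, n_genera = 20,
                          depth_log_mean = log(800), seed = 31)
  co <- generate_cohort(cfg)
  g <- genus_table(co$otu_table, relative = TRUE)
  lab <- co$true_labels[rownames(g)]
  info <- co$genus_info
  alpha2 <- info$base_alpha
  alpha2[info$exclusive_to == 1] <- 0
  expected2 <- alpha2 / sum(alpha2)
  obs <- g[lab == 2, info$genus]
  m <- colMeans(obs)
  se <- apply(obs, 2, sd) / sqrt(nrow(obs))
  z <- abs(m - expected2) / pmax(se, 1e-12)
  expect_gte(mean(z < 3), 0.95)
  expect_lt(max(z), 6)
})

test_that("elimination rates reproduce the configured 33% vs 16%", {
  cfg <- synthetic_config(n_samples = 5100, n_otus = 40, n_genera = 15,
                          depth_log_mean = log(300), seed = 77)
  co <- generate_cohort(cfg)
  elim <- co$metadata$eliminated
  lab <- co$true_labels
  # expected eliminated counts at the cohort's 15/36 split: n1*0.33, n2*0.16
  p1_hat <- mean(elim[lab == 1])
  p2_hat <- mean(elim[lab == 2])
  expect_lt(abs(p1_hat - 0.33), 3 * sqrt(0.33 * 0.67 / sum(lab == 1)))
  expect_lt(abs(p2_hat - 0.16), 3 * sqrt(0.16 * 0.84 / sum(lab == 2)))
  # at the study's n = 51 the expected counts are ~5 and ~5.8
  expect_equal(round(15 * 0.33), 5)
  expect_equal(36 * 0.16, 5.76, tolerance = 0.01)
})

test_that("config validation rejects inconsistent settings", {
  expect_error(synthetic_config(community_proportions = c(0.5, 0.4)),
               "sum to 1")
  expect_error(synthetic_config(effect_size = -1), "non-negative")
  expect_error(synthetic_config(n_genera = 10, n_discriminant_genera = 8,
                                n_exclusive_genera = 5), "exceeds")
  expect_error(synthetic_config(n_otus = 10, n_genera = 20), "n_genera")
})

test_that("write_cohort emits readable plain-text artifacts", {
  co <- generate_cohort(synthetic_config(n_samples = 6, n_otus = 20,
                                         n_genera = 8, seed = 5))
  dir <- file.path(tempdir(), "cohort_out")
  write_cohort(co, dir)
  files <- c("otu_counts.tsv", "taxonomy.tsv", "tree.nwk", "metadata.tsv",
             "scfa.tsv", "metabolite_bins.tsv", "config.json")
  expect_true(all(file.exists(file.path(dir, files))))
  back <- read_otu_table(file.path(dir, "otu_counts.tsv"),
                         file.path(dir, "taxonomy.tsv"))
  expect_identical(back$counts, co$otu_table$counts)
  tr <- ape::read.tree(file.path(dir, "tree.nwk"))
  expect_setequal(tr$tip.label, co$tree$tip.label)
})
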