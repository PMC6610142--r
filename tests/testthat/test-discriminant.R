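test_that("Mann-Whitney matches exact enumeration and is rank-based", {
  got <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$U, 0)
  expect_equal(got$p, 0.1) # 2 * 1/20 over the C(6,3) arrangements
  expect_equal(got$p, oracle_mw_exact_p(c(1, 2, 3), c(4, 5, 6)))
  set.seed(21)
  x <- rnorm(6); y <- rnorm(7)
  base <- mann_whitney_u(x, y)
  mono <- mann_whitney_u(exp(x), exp(y)) # monotone transform
  expect_equal(base$U, mono$U)
  expect_equal(base$p, mono$p)
  expect_equal(base$U + mann_whitney_u(y, x)$U, length(x) * length(y))
  expect_error(mann_whitney_u(numeric(0), y), "non-empty")
})

test_that("Fisher 2x2 matches hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  p_diag <- fisher_exact_2x2(rbind(c(10, 0), c(0, 10)))
  expect_equal(p_diag, 2 / choose(20, 10), tolerance = 1e-10)
  set.seed(3)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 4), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab), oracle_fisher_p(tab),
                 tolerance = 1e-9)
  }
  expect_warning(p0 <- fisher_exact_2x2(rbind(c(0, 0), c(3, 4))), "margin")
  expect_equal(p0, 1)
})

test_that("BH adjustment: worked example and monotonicity", {
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(rep(0.3, 5)), rep(0.3, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(7)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  expect_true(all(diff(q[order(p)]) >= -1e-15)) # order preserved
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("differential_genera flags exclusive and spiked genera", {
  co <- fixture_cohort()
  g <- genus_table(co$otu_table, relative = TRUE)
  lab <- co$true_labels[rownames(g)]
  res <- differential_genera(g, lab)
  info <- co$genus_info
  excl1 <- info$genus[info$exclusive_to == 1]
  got_excl <- res$exclusive_to[match(excl1, res$genus)]
  expect_true(all(got_excl == 1))
  expect_true(all(res$significant[match(excl1, res$genus)]))
  # >= 90% of the spiked (discriminant + exclusive) genera are recovered
  spiked <- info$genus[info$discriminant_sign != 0 | info$exclusive_to != 0]
  expect_gte(mean(res$significant[match(spiked, res$genus)]), 0.9)
  expect_true(all(res$q_mw >= res$p_mw, na.rm = TRUE))
  # all-null cohorts: almost nothing is called at FDR 0.05
  null_frac <- vapply(1:5, function(s) {
    c0 <- generate_cohort(synthetic_config(n_genera = 150L, n_otus = 200L,
                                           effect_size = 0,
                                           n_discriminant_genera = 0L,
                                           n_exclusive_genera = 0L,
                                           richness_thinning = 0,
                                           seed = 500 + s))
    g0 <- genus_table(c0$otu_table, relative = TRUE)
    mean(differential_genera(g0, c0$true_labels[rownames(g0)])$significant)
  }, numeric(1))
  expect_lte(mean(null_frac), 0.02)
  # constant genus: p = 1, lfc = 0
  g2 <- cbind(g, constant_genus = 0)
  g2 <- g2 / rowSums(g2)
  res2 <- differential_genera(g2, lab)
  row <- res2[res2$genus == "constant_genus", ]
  expect_equal(row$p_mw, 1)
  expect_equal(row$lfc, 0)
})

test_that("PLS-DA ranks a single separating genus first, scores orthogonal", {
  set.seed(14)
  n <- 40
  lab <- rep(c("a", "b"), each = n / 2)
  x <- matrix(rnorm(n * 15), n, 15,
              dimnames = list(NULL, paste0("g", 1:15)))
  x[, 7] <- x[, 7] + ifelse(lab == "a", 3, -3)
  fit <- plsda_fit(x, lab, n_components = 2)
  expect_equal(fit$ranking[1], "g7")
  gram <- crossprod(fit$scores)
  off <- abs(gram[1, 2]) / sqrt(gram[1, 1] * gram[2, 2])
  expect_lt(off, 1e-8)
  pred <- predict(fit, x)
  expect_equal(pred$class, lab)
})

test_that("PLS-DA component agrees with the mixOmics implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(15)
  n <- 30
  lab <- rep(c("a", "b"), each = n / 2)
  x <- matrix(rnorm(n * 12), n, 12,
              dimnames = list(paste0("s", 1:n), paste0("g", 1:12)))
  x[, 3] <- x[, 3] + ifelse(lab == "a", 1.5, -1.5)
  x[, 9] <- x[, 9] + ifelse(lab == "a", -1, 1)
  mine <- plsda_fit(x, lab, n_components = 2, scale = TRUE)
  theirs <- mixOmics::plsda(x, factor(lab), ncomp = 2, scale = TRUE)
  expect_gt(abs(cor(mine$scores[, 1], theirs$variates$X[, 1])), 0.99)
  expect_gt(abs(cor(mine$weights[, 1], theirs$loadings$X[, 1])), 0.99)
})

test_that("permuted labels give chance-level CV accuracy", {
  set.seed(16)
  n <- 40
  x <- matrix(rnorm(n * 20), n, 20,
              dimnames = list(NULL, paste0("g", 1:20)))
  lab <- sample(rep(c("a", "b"), each = n / 2))
  res <- sparse_plsda_cv(x, lab, sparsity_grid = c(2, 5, 10), folds = 5,
                         seed = 2)
  expect_lt(abs(res$auc - 0.5), 0.25)
  aucs <- vapply(1:10, function(i) {
    sparse_plsda_cv(x, sample(lab), sparsity_grid = 5, folds = 5,
                    seed = i)$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("sparse PLS-DA recovers a small informative genus set", {
  set.seed(17)
  n <- 60
  lab <- rep(c("a", "b"), each = n / 2)
  p <- 105
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("g", 1:p)))
  informative <- paste0("g", 1:5)
  for (j in 1:5) x[, j] <- x[, j] + ifelse(lab == "a", 2, -2)
  res <- sparse_plsda_cv(x, lab, sparsity_grid = c(1, 2, 3, 5, 8), folds = 5,
                         seed = 3)
  expect_gte(res$auc, 0.95)
  expect_lte(length(setdiff(res$selected, informative)), 1)
  # a perfectly separable genus yields AUC 1
  x1 <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "g1"))
  x1[lab == "a", 1] <- x1[lab == "a", 1] + 100
  res1 <- sparse_plsda_cv(cbind(x1, g2 = rnorm(n)), lab, sparsity_grid = 1,
                          folds = 5, seed = 4)
  expect_equal(res1$auc, 1)
})

test_that("sparse k-means: loose constraint equals plain k-means; recovery", {
  bl <- blob_data(n_per = 15, gap = 6, d = 4, seed = 21)
  colnames(bl$x) <- paste0("f", 1:4)
  sk <- sparse_kmeans(bl$x, 2, l1_bound = sqrt(4), seed = 5)
  km <- with_seed_kmeans(scale(bl$x), 2, seed = 5)
  expect_equal(match_labels(km, sk$labels)$n_misclassified, 0)
  expect_equal(match_labels(bl$labels, sk$labels)$n_misclassified, 0)
  # feasibility: ||w||_2 <= 1, ||w||_1 <= s, w >= 0
  expect_lte(sqrt(sum(sk$weights^2)), 1 + 1e-8)
  expect_lte(sum(sk$weights), sqrt(4) + 1e-8)
  expect_true(all(sk$weights >= 0))

  set.seed(22) # 3 informative features among 60
  n <- 50
  lab <- rep(1:2, c(20, 30))
  x <- matrix(rnorm(n * 60), n, 60, dimnames = list(NULL, paste0("f", 1:60)))
  for (j in 1:3) x[, j] <- x[, j] + ifelse(lab == 1, 2.5, -2.5)
  sk2 <- sparse_kmeans(x, 2, l1_bound = 1.5, seed = 6)
  expect_lte(sqrt(sum(sk2$weights^2)), 1 + 1e-8)
  expect_lte(sum(sk2$weights), 1.5 + 1e-8)
  top <- names(sort(sk2$weights, decreasing = TRUE))[1:3]
  expect_setequal(top, paste0("f", 1:3))
  expect_gte(sum(sk2$weights[paste0("f", 1:3)]) / sum(sk2$weights), 0.9)
  expect_lte(match_labels(lab, sk2$labels)$n_misclassified, 2)
  expect_error(sparse_kmeans(x, 2, l1_bound = 0.5), "l1_bound")
})
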