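test_that("PERMANOVA pseudo-F matches a hand decomposition on 4 samples", {
  # two groups of two on a line: x = (0, 1, 10, 11), groups (a, a, b, b)
  x <- c(0, 1, 10, 11)
  d <- dist(x)
  res <- permanova(d, factor(c("a", "a", "b", "b")), n_perm = 999, seed = 1)
  # SS_total = sum d^2 / n; SS_within = within-pair squared dists / group n
  ss_tot <- sum(as.matrix(d)^2) / 2 / 4
  ss_within <- (1^2) / 2 + (1^2) / 2
  ss_between <- ss_tot - ss_within
  f_hand <- (ss_between / 1) / (ss_within / 2)
  expect_equal(res$pseudo_f[1], f_hand, tolerance = 1e-10)
  expect_equal(res$ss[1], ss_between, tolerance = 1e-10)
  # extreme separation: p at the permutation floor 3/(perms+1) for 2+2
  # (only 4!/(2!2!2) = 3 distinct splits, all permutations of a tiny design)
  expect_lte(res$p[1], 0.4)
  expect_gte(res$p[1], 1 / 1000)
})

test_that("PERMANOVA detects separation and validates inputs", {
  bl <- blob_data(n_per = 10, gap = 10, seed = 41)
  res <- permanova(bl$d, factor(bl$labels), n_perm = 199, seed = 2)
  expect_equal(res$p[1], 1 / 200) # extreme-separation limit: add-one floor
  expect_error(permanova(bl$d, rep("a", 20)), "constant")
  expect_error(permanova(bl$d, factor(bl$labels), n_perm = 50), "99")
})

test_that("envfit recovers planted directions", {
  set.seed(42)
  pts <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("A1", "A2")))
  vars <- data.frame(v_axis1 = pts[, 1],
                     v_diag = pts[, 1] + pts[, 2],
                     v_noise = rnorm(30),
                     v_const = rep(1, 30))
  res <- envfit_screen(pts, vars, n_perm = 999, seed = 3)
  r <- res[match(c("v_axis1", "v_diag", "v_noise", "v_const"), res$variable), ]
  expect_gt(r$r2[1], 0.999)
  expect_equal(r$p[1], 1 / 1000)
  expect_equal(abs(unlist(r[2, c("A1", "A2")])), c(A1 = 1, A2 = 1) / sqrt(2),
               tolerance = 0.02)
  expect_equal(r$r2[4], 0)
  expect_equal(r$p[4], 1)
  expect_true(all(res$q >= res$p))
})

test_that("two-way ANOVA: Type II equals Type I under balance, detects effects", {
  set.seed(43)
  a <- factor(rep(c("c1", "c2"), each = 12))
  b <- factor(rep(rep(c("90", "120", "160"), each = 4), 2))
  y <- rnorm(24)
  t2 <- two_way_anova(y, a, b)
  t1 <- anova(lm(y ~ a + b))
  expect_equal(t2$ss, t1$`Sum Sq`[1:2], tolerance = 1e-10)
  expect_equal(t2$p, t1$`Pr(>F)`[1:2], tolerance = 1e-10)
  # pure factor-a effect
  y2 <- ifelse(a == "c1", 2, 0) + rnorm(24, sd = 0.5)
  t2b <- two_way_anova(y2, a, b)
  expect_lt(t2b$p[t2b$term == "factor_a"], 0.001)
  expect_gt(t2b$p[t2b$term == "factor_b"], 0.05)
  expect_error(two_way_anova(y, factor(rep("x", 24)), b), "levels")
})

test_that("probabilistic quotient normalization recovers dilution factors", {
  set.seed(44)
  base <- abs(rnorm(40, 10, 2))
  spectra <- rbind(s1 = base, s2 = 2 * base, s3 = 4 * base)
  norm <- pq_normalize(spectra)
  expect_equal(attr(norm, "dilution") / attr(norm, "dilution")[1],
               c(s1 = 1, s2 = 2, s3 = 4), tolerance = 1e-12)
  expect_equal(unname(norm[2, ]), unname(norm[1, ]), tolerance = 1e-12)
  same <- rbind(base, base, base)
  expect_equal(pq_normalize(same)[1, ], base, ignore_attr = TRUE)
  expect_error(pq_normalize(rbind(base, 0 * base)), "all-zero")
})

test_that("screen_variables finds planted diet effects, not null host ones", {
  co <- fixture_cohort()
  md <- co$metadata
  res <- screen_variables(co$true_labels, md,
                          families = list(host = c("sex", "breed",
                                                   "age_years"),
                                          diet = c("protein_intake_kg",
                                                   "fiber_intake_kg",
                                                   "ash_intake_kg",
                                                   "ufc_intake")))
  fiber <- res[res$variable == "fiber_intake_kg", ]
  expect_true(fiber$significant)
  expect_equal(fiber$direction, -1) # higher intake in community 2
  expect_identical(res$test[res$variable == "sex"], "fisher")
  expect_identical(res$test[res$variable == "age_years"], "mann-whitney")
  expect_true(all(res$q >= res$p, na.rm = TRUE))
  # null age variable: not significant across replicate cohorts
  hits <- vapply(1:12, function(s) {
    c2 <- generate_cohort(synthetic_config(n_samples = 30, n_otus = 30,
                                           n_genera = 10, seed = 1000 + s))
    r <- screen_variables(c2$true_labels, c2$metadata["age_years"])
    r$p[1] < 0.05
  }, logical(1))
  expect_lte(mean(hits), 0.25)
})

test_that("skipped variables and Monte-Carlo Fisher are handled", {
  labels <- setNames(rep(1:2, each = 10), paste0("s", 1:20))
  md <- data.frame(sample_id = paste0("s", 1:20),
                   mostly_na = c(rnorm(3), rep(NA, 17)),
                   many_levels = sample(letters[1:6], 20, TRUE),
                   stringsAsFactors = FALSE)
  expect_message(res <- screen_variables(labels, md, seed = 5), "skipped")
  expect_identical(res$test[res$variable == "mostly_na"], "skipped")
  expect_true(is.na(res$q[res$variable == "mostly_na"]))
})
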