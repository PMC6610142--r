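# Shared small cohorts, built once per test run.
.fixtures <- new.env(parent = emptyenv())

fixture_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    .fixtures$cohort <- generate_cohort(synthetic_config(seed = 101L))
  }
  .fixtures$cohort
}

fixture_reference_typing <- function() {
  if (is.null(.fixtures$typing)) {
    co <- fixture_cohort()
    d <- beta_distance(co$otu_table$counts, "weighted-unifrac",
                       tree = co$tree)
    .fixtures$typing <- select_k(d, k_max = 10)
  }
  .fixtures$typing
}

with_seed_kmeans <- function(x, k, seed) {
  set.seed(seed)
  stats::kmeans(x, k, nstart = 10)$cluster
}

# two well-separated Gaussian blobs and their Euclidean distances
blob_data <- function(n_per = 10, gap = 8, d = 3, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * d), n_per, d),
             matrix(rnorm(n_per * d, mean = gap), n_per, d))
  list(x = x, d = dist(x), labels = rep(1:2, each = n_per))
}
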