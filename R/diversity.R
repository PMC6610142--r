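#' Rarefy an OTU table to even depth
#'
#' Subsamples each sample's counts without replacement to exactly `depth`
#' reads (via [vegan::rrarefy()]), dropping samples whose library is smaller
#' than `depth` with a warning. Deterministic given `seed`.
#'
#' @param x an [otu_table].
#' @param depth target library size (> 0).
#' @param seed integer seed.
#' @return a rarefied [otu_table] (possibly fewer samples), with attributes
#'   `depth` and `seed`.
#' @export
rarefy_counts <- function(x, depth, seed = 1L) {
  stopifnot(inherits(x, "otu_table"))
  depth <- check_scalar_count(depth, "depth")
  libs <- sample_depths(x)
  keep <- libs >= depth
  if (!any(keep)) stop_invalid("no sample reaches the rarefaction depth")
  if (!all(keep)) {
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped: ",
            paste(names(libs)[!keep], collapse = ", "), call. = FALSE)
  }
  m <- x$counts[keep, , drop = FALSE]
  rar <- with_local_seed(seed, withCallingHandlers(
    vegan::rrarefy(m, sample = depth),
    warning = function(w) { # vegan's counts-look-odd heuristic is noise here
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }))
  out <- otu_table(rar, x$taxonomy)
  attr(out, "depth") <- depth
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Chao1 richness estimator
#'
#' Bias-corrected Chao1: `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, where `F1` and
#' `F2` are the numbers of singleton and doubleton taxa. Always at least the
#' observed richness; invariant to appending zero-count taxa.
#'
#' @param counts non-negative integer vector, not all zero.
#' @return Chao1 estimate (scalar).
#' @examples
#' chao1(c(5, 5, 5)) # no singletons: equals observed richness
#' chao1(c(1, 1, 1, 2, rep(5, 6))) # S=10, F1=3, F2=1 -> 11.5
#' @export
chao1 <- function(counts) {
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_invalid("counts must be non-negative integers")
  }
  if (all(counts == 0)) stop_invalid("Chao1 is undefined for an empty sample")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon entropy (natural log)
#' @param counts non-negative abundance vector, not all zero.
#' @return entropy in nats.
#' @export
shannon_entropy <- function(counts) {
  if (any(counts < 0)) stop_invalid("abundances must be non-negative")
  if (all(counts == 0)) stop_invalid("entropy undefined for an empty sample")
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Pielou's evenness
#'
#' `J = H / ln(S)` with `H` the Shannon entropy and `S` the number of taxa
#' with non-zero abundance. Equals 1 when all present taxa are equally
#' abundant. Undefined (returned as `NA`) when only one taxon is present.
#'
#' @param counts non-negative abundance vector with at least one non-zero
#'   entry.
#' @return evenness in `[0, 1]`, or `NA` for a single-taxon sample.
#' @examples
#' pielou_evenness(c(10, 10, 10, 10)) # 1
#' @export
pielou_evenness <- function(counts) {
  if (all(counts == 0)) stop_invalid("evenness undefined for an empty sample")
  s <- sum(counts > 0)
  if (s == 1L) return(NA_real_)
  shannon_entropy(counts) / log(s)
}

#' Dominance and rarity
#'
#' Dominance is the relative abundance of the single most abundant taxon;
#' rarity is the summed relative abundance of taxa individually below the
#' detection threshold (default 0.2% relative abundance).
#'
#' @param rel_abund relative-abundance vector summing to 1.
#' @param rarity_threshold detection threshold for "rare" taxa.
#' @return named numeric vector `c(dominance, rarity)`.
#' @export
dominance_and_rarity <- function(rel_abund, rarity_threshold = 0.002) {
  if (any(rel_abund < 0) || abs(sum(rel_abund) - 1) > 1e-9) {
    stop_invalid("'rel_abund' must be non-negative and sum to 1")
  }
  c(dominance = max(rel_abund),
    rarity = sum(rel_abund[rel_abund > 0 & rel_abund < rarity_threshold]))
}

#' Per-sample alpha-diversity report
#'
#' Computes observed richness, Chao1, Shannon entropy, Pielou evenness,
#' dominance and rarity for every sample, optionally after rarefaction to a
#' common depth (singleton OTUs are retained during this step, as is standard
#' for richness estimation).
#'
#' @param x an [otu_table].
#' @param rarefy_depth optional rarefaction depth; `NULL` uses raw counts.
#' @param seed seed for rarefaction.
#' @param rarity_threshold passed to [dominance_and_rarity()].
#' @return data.frame (one row per retained sample) with attributes `depth`
#'   and `seed`.
#' @export
alpha_diversity <- function(x, rarefy_depth = NULL, seed = 1L,
                            rarity_threshold = 0.002) {
  stopifnot(inherits(x, "otu_table"))
  if (!is.null(rarefy_depth)) x <- rarefy_counts(x, rarefy_depth, seed)
  m <- x$counts
  rel <- m / rowSums(m)
  out <- data.frame(
    sample_id = rownames(m),
    observed = rowSums(m > 0),
    chao1 = apply(m, 1, chao1),
    shannon = apply(m, 1, shannon_entropy),
    pielou = apply(m, 1, pielou_evenness),
    t(apply(rel, 1, dominance_and_rarity,
            rarity_threshold = rarity_threshold)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "depth") <- if (is.null(rarefy_depth)) NA_integer_ else rarefy_depth
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Core microbiota
#'
#' Taxa whose relative abundance exceeds `detection` in at least a
#' `prevalence` fraction of samples (defaults mirror a 0.001% detection
#' threshold and 99.9% prevalence).
#'
#' @param rel_abund samples x taxa relative-abundance matrix.
#' @param detection detection threshold in `(0, 1]`.
#' @param prevalence prevalence threshold in `(0, 1]`.
#' @return character vector of core taxon names.
#' @export
core_taxa <- function(rel_abund, detection = 1e-5, prevalence = 0.999) {
  detection <- check_probability(detection, "detection", open_zero = TRUE)
  prevalence <- check_probability(prevalence, "prevalence", open_zero = TRUE)
  if (any(rel_abund < 0)) stop_invalid("relative abundances required")
  prev <- colMeans(rel_abund > detection)
  colnames(rel_abund)[prev >= prevalence]
}
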