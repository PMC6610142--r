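#' Partition samples into community types with PAM
#'
#' Partitioning around medoids ([cluster::pam()], BUILD + SWAP run to
#' convergence) on a precomputed distance matrix, returning per-sample
#' silhouette widths and the silhouette coefficient (their mean). PAM on a
#' fixed distance matrix is deterministic.
#'
#' @param d a `dist` or square symmetric matrix.
#' @param k number of clusters, `2 <= k < n`.
#' @return list of class `community_types`: `labels` (named integer vector in
#'   `1..k`), `k`, `medoids` (sample ids), `sil_widths` (named),
#'   `sil_coefficient`, `objective` (total cost after BUILD and after SWAP),
#'   `metric` (taken from the `metric` attribute of `d`, if any).
#' @export
pam_communities <- function(d, k) {
  d <- as_dist_checked(d)
  n <- attr(d, "Size")
  if (k < 2 || k >= n) stop_invalid("'k' must satisfy 2 <= k < n")
  fit <- cluster::pam(d, k = k, diss = TRUE, keep.diss = FALSE)
  labels <- stats::setNames(as.integer(fit$clustering), dist_labels(d))
  sw <- silhouette_widths(d, labels)
  structure(list(labels = labels,
                 k = as.integer(k),
                 medoids = dist_labels(d)[fit$id.med],
                 sil_widths = sw$widths,
                 sil_coefficient = sw$coefficient,
                 objective = fit$objective,
                 metric = attr(d, "metric")),
            class = "community_types")
}

#' @export
print.community_types <- function(x, ...) {
  cat(sprintf("community_types: K = %d (%s), silhouette coefficient %.3f\n",
              x$k, paste(table(x$labels), collapse = "/"),
              x$sil_coefficient))
  invisible(x)
}

#' Silhouette widths and coefficient
#'
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a(i)` the mean distance of
#' sample `i` to its own cluster and `b(i)` the mean distance to the nearest
#' other cluster; samples in singleton clusters get `s = 0`
#' (via [cluster::silhouette()]).
#'
#' @param d a `dist` or square symmetric matrix.
#' @param labels integer cluster labels (>= 2 non-empty clusters).
#' @return list with `widths` (named numeric) and `coefficient` (mean width).
#' @export
silhouette_widths <- function(d, labels) {
  d <- as_dist_checked(d)
  labels <- as.integer(as.factor(labels))
  if (length(labels) != attr(d, "Size")) {
    stop_invalid("labels must match the distance matrix")
  }
  if (length(unique(labels)) < 2) {
    stop_invalid("silhouette requires at least two clusters")
  }
  sil <- cluster::silhouette(labels, dist = d)
  widths <- stats::setNames(sil[, "sil_width"], dist_labels(d))
  list(widths = widths, coefficient = mean(widths))
}

#' Select the number of community types by the silhouette coefficient
#'
#' Runs PAM for every `K` in `2..k_max` and returns the partition maximizing
#' the silhouette coefficient (ties broken toward smaller `K`). A coefficient
#' above 0.5 is flagged as a reasonable clustering structure.
#'
#' @param d a `dist` or square symmetric matrix.
#' @param k_max largest `K` considered.
#' @return the winning [pam_communities()] result, augmented with
#'   `sc_by_k` (named vector over the grid) and `reasonable_structure`
#'   (`sil_coefficient > 0.5`).
#' @export
select_k <- function(d, k_max = 10) {
  d <- as_dist_checked(d)
  n <- attr(d, "Size")
  if (k_max < 2) stop_invalid("'k_max' must be >= 2")
  ks <- seq(2L, min(k_max, n - 1L))
  fits <- lapply(ks, function(k) pam_communities(d, k))
  sc <- vapply(fits, `[[`, numeric(1), "sil_coefficient")
  best <- fits[[which.max(sc)]]
  best$sc_by_k <- stats::setNames(sc, ks)
  best$reasonable_structure <- best$sil_coefficient > 0.5
  best
}

#' Optimal label matching between two partitions
#'
#' Relabels `labels` to best agree with `reference` by exhaustive search over
#' label permutations (optimal assignment; feasible for the small K used in
#' community typing) and counts the remaining disagreements.
#'
#' @param reference,labels equal-length cluster label vectors.
#' @return list with `labels` (relabelled to the reference's coding),
#'   `n_misclassified`, and `agreement` (fraction matching).
#' @export
match_labels <- function(reference, labels) {
  if (length(reference) != length(labels)) {
    stop_invalid("partitions must cover the same samples")
  }
  ref <- as.integer(as.factor(reference))
  lab <- as.integer(as.factor(labels))
  k <- max(max(ref), max(lab))
  if (k > 8) stop_invalid("label matching supports at most 8 clusters")
  conf <- table(factor(lab, levels = seq_len(k)),
                factor(ref, levels = seq_len(k)))
  perms <- all_permutations(k)
  hits <- apply(perms, 1, function(p) sum(conf[cbind(seq_len(k), p)]))
  best <- perms[which.max(hits), ]
  relab <- best[lab]
  list(labels = relab,
       n_misclassified = sum(relab != ref),
       agreement = mean(relab == ref))
}

all_permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    ins <- cbind(sub[, seq_len(i - 1), drop = FALSE], k,
                 sub[, seq(i, k - 1)[seq_len(k - i)], drop = FALSE])
    out <- rbind(out, ins)
  }
  out
}

#' Concordance between partitions from different distances
#'
#' Pairwise adjusted Rand index plus an exact-match flag after optimal label
#' matching, for checking that alternative dissimilarity measures produce the
#' same community types.
#'
#' @param partitions named list of [pam_communities()] results or label
#'   vectors over the same samples.
#' @return data.frame with one row per pair: `ari`, `n_misclassified`,
#'   `exact_match`.
#' @export
concordance <- function(partitions) {
  labs <- lapply(partitions, function(p) {
    if (inherits(p, "community_types")) p$labels else p
  })
  nm <- names(labs)
  if (is.null(nm)) nm <- paste0("partition_", seq_along(labs))
  base_ids <- names(labs[[1]])
  for (l in labs) {
    if (length(l) != length(labs[[1]])) {
      stop_invalid("partitions cover different sample sets")
    }
    if (!is.null(base_ids) && !is.null(names(l)) &&
        !identical(sort(names(l)), sort(base_ids))) {
      stop_invalid("partitions cover different sample sets")
    }
  }
  labs <- lapply(labs, function(l) {
    if (!is.null(names(l)) && !is.null(base_ids)) l[base_ids] else l
  })
  pairs <- utils::combn(seq_along(labs), 2)
  out <- data.frame(
    partition_a = nm[pairs[1, ]],
    partition_b = nm[pairs[2, ]],
    ari = apply(pairs, 2, function(ij) {
      mclust::adjustedRandIndex(labs[[ij[1]]], labs[[ij[2]]])
    }),
    n_misclassified = apply(pairs, 2, function(ij) {
      match_labels(labs[[ij[1]]], labs[[ij[2]]])$n_misclassified
    }),
    stringsAsFactors = FALSE
  )
  out$exact_match <- out$n_misclassified == 0
  out
}

#' Top-k genus-deletion robustness profile
#'
#' Deletes the `k` highest-ranked genera (for `k = 0 .. k_max`), re-normalizes
#' each sample's remaining composition, recomputes Bray-Curtis distances,
#' re-runs PAM at the reference partition's `K`, and records the number of
#' misclassified samples (after optimal label matching) and the silhouette
#' coefficient.
#'
#' @param genus_relabund samples x genera relative-abundance matrix.
#' @param reference a [pam_communities()] result (or label vector) defining
#'   the community types and their `K`.
#' @param ranking character vector of genus names, most discriminant first
#'   (e.g. by PLS-DA loading).
#' @param k_max deepest deletion; truncated with a warning if fewer ranked
#'   genera remain than `k_max + 1`.
#' @return data.frame of class `robustness_profile`: `k`, `n_misclassified`,
#'   `silhouette`.
#' @export
topk_deletion <- function(genus_relabund, reference, ranking, k_max = 100) {
  ref_labels <- if (inherits(reference, "community_types")) {
    reference$labels
  } else {
    reference
  }
  k_ref <- length(unique(ref_labels))
  ranking <- intersect(ranking, colnames(genus_relabund))
  if (k_max >= ncol(genus_relabund)) {
    k_max <- ncol(genus_relabund) - 1L
    warning("k_max reaches the number of genera; truncated to ", k_max,
            call. = FALSE)
  }
  if (k_max > length(ranking)) {
    k_max <- length(ranking)
    warning("ranking covers only ", k_max, " genera; grid truncated",
            call. = FALSE)
  }
  rows <- lapply(0:k_max, function(k) {
    keep <- setdiff(colnames(genus_relabund), ranking[seq_len(k)])
    m <- genus_relabund[, keep, drop = FALSE]
    m <- m / rowSums(m)
    d <- beta_distance(m, "bray-curtis")
    fit <- pam_communities(d, k_ref)
    data.frame(k = k,
               n_misclassified = match_labels(ref_labels,
                                              fit$labels)$n_misclassified,
               silhouette = fit$sil_coefficient)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("robustness_profile", "data.frame")
  out
}
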