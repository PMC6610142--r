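#' Bray-Curtis dissimilarity between two samples
#'
#' `BC = sum |x_i - y_i| / sum (x_i + y_i)`; 0 for identical vectors, 1 for
#' disjoint supports. For a whole table use [beta_distance()].
#'
#' @param x,y non-negative abundance vectors of equal length, not both zero.
#' @return dissimilarity in `[0, 1]`.
#' @examples
#' bray_curtis(c(1, 1), c(1, 0)) # 1/3
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) stop_invalid("abundances must be non-negative")
  tot <- sum(x + y)
  if (tot == 0) stop_invalid("Bray-Curtis undefined for two empty samples")
  sum(abs(x - y)) / tot
}

# Per-edge descendant abundance: rows = edges (postorder), cols = samples.
# Root has no incoming edge, so the root branch is naturally excluded.
edge_abundance <- function(tree, mat) {
  tips <- tree$tip.label
  unknown <- setdiff(colnames(mat), tips)
  if (length(unknown)) {
    stop_invalid("abundance on taxa absent from the tree: ",
                 paste(utils::head(unknown, 3), collapse = ", "))
  }
  ntip <- length(tips)
  full <- matrix(0, nrow(mat), ntip, dimnames = list(rownames(mat), tips))
  full[, colnames(mat)] <- mat
  tr <- stats::reorder(tree, "postorder")
  node_ab <- matrix(0, ntip + tr$Nnode, nrow(mat))
  node_ab[seq_len(ntip), ] <- t(full)
  for (e in seq_len(nrow(tr$edge))) {
    node_ab[tr$edge[e, 1], ] <- node_ab[tr$edge[e, 1], ] +
      node_ab[tr$edge[e, 2], ]
  }
  list(M = node_ab[tr$edge[, 2], , drop = FALSE], len = tr$edge.length)
}

#' UniFrac distances
#'
#' Weighted UniFrac between two samples is
#' `sum_i b_i |A_i - B_i|` over branches `i` with length `b_i`, where `A_i`
#' and `B_i` are the fractions of each sample's total abundance descending
#' from the branch; the normalized variant divides by `sum_i b_i (A_i + B_i)`
#' and lies in `[0, 1]`. Unweighted UniFrac is the branch length leading
#' exclusively to taxa of one sample divided by the branch length leading to
#' taxa of either sample. Branch abundances are accumulated by a post-order
#' traversal; the root branch is excluded.
#'
#' @param tree rooted `phylo` with branch lengths; tips name the taxa.
#' @param a,b named abundance vectors (weighted: relative abundances summing
#'   to 1; unweighted: presence is any positive value). Names must be tree
#'   tips; absent tips count as zero.
#' @param normalized divide the weighted sum by its maximum attainable value.
#' @return distance (scalar).
#' @examples
#' tr <- ape::read.tree(text = "((t1:1,t2:1):1,t3:2);")
#' unweighted_unifrac(tr, c(t1 = 1, t2 = 1), c(t2 = 1, t3 = 1))
#' @export
weighted_unifrac <- function(tree, a, b, normalized = TRUE) {
  if (abs(sum(a) - 1) > 1e-6 || abs(sum(b) - 1) > 1e-6) {
    stop_invalid("weighted UniFrac expects relative abundances summing to 1")
  }
  taxa <- union(names(a), names(b))
  if (is.null(taxa)) stop_invalid("abundance vectors must be named by taxon")
  av <- bv <- stats::setNames(numeric(length(taxa)), taxa)
  av[names(a)] <- a
  bv[names(b)] <- b
  ea <- edge_abundance(tree, rbind(a = av, b = bv))
  raw <- sum(ea$len * abs(ea$M[, 1] - ea$M[, 2]))
  if (!normalized) return(raw)
  denom <- sum(ea$len * (ea$M[, 1] + ea$M[, 2]))
  raw / denom
}

#' @rdname weighted_unifrac
#' @export
unweighted_unifrac <- function(tree, a, b) {
  if (all(a <= 0) || all(b <= 0)) {
    stop_invalid("unweighted UniFrac requires a non-empty taxon set per sample")
  }
  taxa <- union(names(a)[a > 0], names(b)[b > 0])
  mat <- matrix(0, 2, length(taxa), dimnames = list(c("a", "b"), taxa))
  mat[1, names(a)[a > 0]] <- 1
  mat[2, names(b)[b > 0]] <- 1
  ea <- edge_abundance(tree, mat)
  pa <- ea$M[, 1] > 0
  pb <- ea$M[, 2] > 0
  sum(ea$len * xor(pa, pb)) / sum(ea$len * (pa | pb))
}

#' Beta-diversity distance matrix
#'
#' Computes all pairwise distances between the rows of an abundance table.
#' UniFrac variants require `tree`; abundances are converted to per-sample
#' relative abundances internally for `"weighted-unifrac"` and
#' `"bray-curtis"` is computed on the table as given (the standard choice is
#' relative abundances), while `"euclidean"` is meant for normalized genus
#' tables.
#'
#' @param mat samples x taxa abundance matrix (column names = taxa).
#' @param method one of `"weighted-unifrac"`, `"unweighted-unifrac"`,
#'   `"bray-curtis"`, `"euclidean"`.
#' @param tree rooted `phylo`, required for UniFrac.
#' @param normalized normalized weighted UniFrac (default `TRUE`).
#' @return a `dist` with attribute `metric`.
#' @export
beta_distance <- function(mat,
                          method = c("weighted-unifrac", "unweighted-unifrac",
                                     "bray-curtis", "euclidean"),
                          tree = NULL, normalized = TRUE) {
  method <- match.arg(method)
  if (grepl("unifrac", method)) {
    if (is.null(tree)) stop_invalid("UniFrac requires a phylogenetic tree")
    rel <- to_relative_abundance(mat)
    ea <- edge_abundance(tree, rel)
    if (method == "weighted-unifrac") {
      wM <- ea$M * ea$len
      raw <- stats::dist(t(wM), method = "manhattan")
      if (normalized) {
        s <- colSums(wM)
        denom <- outer(s, s, "+")
        d <- stats::as.dist(as.matrix(raw) / denom)
      } else {
        d <- raw
      }
    } else {
      P <- (ea$M > 0) + 0
      and <- t(P) %*% (P * ea$len)
      s <- colSums(P * ea$len)
      tot <- outer(s, s, "+")
      d <- stats::as.dist((tot - 2 * and) / (tot - and))
    }
    attr(d, "Labels") <- rownames(mat)
  } else if (method == "bray-curtis") {
    d <- vegan::vegdist(mat, method = "bray")
  } else {
    d <- stats::dist(mat, method = "euclidean")
  }
  attr(d, "metric") <- method
  d
}

#' Principal coordinates analysis
#'
#' Gower double-centering of squared distances followed by an
#' eigendecomposition; coordinates are eigenvectors scaled by the square root
#' of their eigenvalues. Axes with non-positive eigenvalues are excluded
#' (negative eigenvalues are reported, not corrected).
#'
#' @param d a `dist` or square symmetric matrix.
#' @param n_axes number of coordinate axes to return.
#' @return list of class `ordination`: `points` (samples x axes),
#'   `eigenvalues` (all), `prop_explained` (over positive eigenvalues),
#'   `n_negative_eig`, `type = "pcoa"`.
#' @export
pcoa_ordination <- function(d, n_axes = 2) {
  d <- as_dist_checked(d)
  m <- as.matrix(d)
  n <- nrow(m)
  b <- -0.5 * m^2
  b <- sweep(b, 1, rowMeans(b))
  b <- sweep(b, 2, colMeans(b))
  b <- b + mean(-0.5 * m^2) # complete double-centering: B = (I-J)(−D²/2)(I-J)
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  pos <- which(e$values > max(e$values) * 1e-12)
  if (n_axes > length(pos)) {
    warning("only ", length(pos), " axes with positive eigenvalues; truncated",
            call. = FALSE)
    n_axes <- length(pos)
  }
  ax <- pos[seq_len(n_axes)]
  pts <- e$vectors[, ax, drop = FALSE] %*% diag(sqrt(e$values[ax]), n_axes)
  dimnames(pts) <- list(dist_labels(d), paste0("PCo", seq_len(n_axes)))
  structure(list(points = pts,
                 eigenvalues = e$values,
                 prop_explained = e$values[pos] / sum(e$values[pos]),
                 n_negative_eig = sum(e$values < -max(abs(e$values)) * 1e-12),
                 type = "pcoa"),
            class = "ordination")
}

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 NMDS via [vegan::metaMDS()] (monotone regression with
#' random restarts); the best of `n_restarts` configurations is returned and
#' non-convergence is flagged rather than raised.
#'
#' @param d a `dist` or square symmetric matrix.
#' @param k target dimensionality.
#' @param n_restarts maximum random restarts.
#' @param max_iter iterations per run.
#' @param seed integer seed.
#' @return list of class `ordination`: `points`, `stress` (in `[0, 1]`),
#'   `converged`, `restarts`, `type = "nmds"`.
#' @export
nmds_ordination <- function(d, k = 2, n_restarts = 20, max_iter = 300,
                            seed = 1L) {
  d <- as_dist_checked(d)
  if (k < 1) stop_invalid("'k' must be >= 1")
  fit <- with_local_seed(seed, {
    vegan::metaMDS(d, k = k, trymax = n_restarts, maxit = max_iter,
                   trace = 0, autotransform = FALSE, wascores = FALSE)
  })
  pts <- fit$points
  dimnames(pts) <- list(dist_labels(d), paste0("NMDS", seq_len(k)))
  structure(list(points = pts,
                 stress = fit$stress,
                 converged = isTRUE(fit$converged) || fit$converged > 0,
                 restarts = n_restarts,
                 type = "nmds"),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("ordination (%s): %d samples x %d axes", x$type,
              nrow(x$points), ncol(x$points)))
  if (x$type == "nmds") cat(sprintf(", stress %.4f", x$stress))
  cat("\n")
  invisible(x)
}
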