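#' PCIT significance filter for a correlation matrix
#'
#' Partial correlation and information theory filter: for every trio
#' `(x, y, z)` the three first-order partial correlations
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))` (and
#' permutations) are computed, the trio tolerance is the mean of the three
#' absolute partial-to-direct ratios, and the edge `(x, y)` is flagged
#' non-significant when, for some third node `z`,
#' `|r_xy| <= eps |r_xz|` and `|r_xy| <= eps |r_yz|`. Trios where a partial
#' correlation is undefined (`|r| = 1` in a denominator, or a zero direct
#' correlation in a ratio) are skipped and counted.
#'
#' @param r symmetric correlation matrix with unit diagonal.
#' @return symmetric logical matrix: `TRUE` where the edge survives
#'   (diagonal `TRUE`); attribute `n_skipped_trios` counts skipped trios.
#' @export
pcit_filter <- function(r) {
  r <- as.matrix(r)
  n <- nrow(r)
  if (n != ncol(r)) stop_invalid("'r' must be square")
  if (max(abs(r - t(r))) > 1e-8) stop_invalid("'r' must be symmetric")
  if (max(abs(diag(r) - 1)) > 1e-8) stop_invalid("'r' must have unit diagonal")
  if (max(abs(r)) > 1 + 1e-8) stop_invalid("correlations must lie in [-1, 1]")
  keep <- matrix(TRUE, n, n, dimnames = dimnames(r))
  skipped <- 0L
  if (n < 3) {
    attr(keep, "n_skipped_trios") <- skipped
    return(keep)
  }
  for (x in seq_len(n - 1)) {
    for (y in seq(x + 1, n)) {
      z <- setdiff(seq_len(n), c(x, y))
      rxy <- r[x, y]
      rxz <- r[x, z]
      ryz <- r[y, z]
      d_xy <- (1 - rxz^2) * (1 - ryz^2)
      d_xz <- (1 - rxy^2) * (1 - ryz^2)
      d_yz <- (1 - rxy^2) * (1 - rxz^2)
      valid <- d_xy > 0 & d_xz > 0 & d_yz > 0 &
        rxy != 0 & rxz != 0 & ryz != 0
      skipped <- skipped + sum(!valid)
      if (!any(valid)) next
      rxz <- rxz[valid]; ryz <- ryz[valid]
      pxy <- (rxy - rxz * ryz) / sqrt(d_xy[valid])
      pxz <- (rxz - rxy * ryz) / sqrt(d_xz[valid])
      pyz <- (ryz - rxy * rxz) / sqrt(d_yz[valid])
      eps <- (abs(pxy / rxy) + abs(pxz / rxz) + abs(pyz / ryz)) / 3
      kill <- abs(rxy) <= eps * abs(rxz) & abs(rxy) <= eps * abs(ryz)
      if (any(kill)) keep[x, y] <- keep[y, x] <- FALSE
    }
  }
  attr(keep, "n_skipped_trios") <- skipped
  keep
}

#' Build a PCIT-filtered genus co-occurrence network
#'
#' Excludes genera below a mean relative abundance threshold, computes
#' Pearson correlations among the remaining genera with two-sided t-test
#' p-values (`n - 2` df), and keeps the edges that are PCIT-significant with
#' `|r| >= r_cut` and `p <= p_cut`. Edges with `|r| >= strong_cut` carry a
#' `strong` flag.
#'
#' @param genus_relabund samples x genera relative-abundance matrix for one
#'   community type (>= 4 samples).
#' @param min_mean_abund mean relative-abundance node filter (default 0.1%).
#' @param r_cut correlation magnitude cutoff.
#' @param p_cut correlation p-value cutoff.
#' @param strong_cut threshold for the strong-edge flag.
#' @param phylum optional named vector genus -> phylum for node attributes
#'   (defaults to the matrix's `"phylum"` attribute, if present).
#' @return list of class `genus_network`: `graph` (igraph), `nodes`
#'   (data.frame: genus, mean_abund, phylum), `edges` (data.frame: from, to,
#'   r, p, sign, strong).
#' @export
build_network <- function(genus_relabund, min_mean_abund = 0.001,
                          r_cut = 0.35, p_cut = 0.05, strong_cut = 0.60,
                          phylum = NULL) {
  m <- as.matrix(genus_relabund)
  n <- nrow(m)
  if (n < 4) stop_invalid("need >= 4 samples for stable correlations")
  if (is.null(phylum)) phylum <- attr(genus_relabund, "phylum")
  mean_ab <- colMeans(m)
  m <- m[, mean_ab >= min_mean_abund, drop = FALSE]
  sdv <- apply(m, 2, stats::sd)
  if (any(sdv == 0)) m <- m[, sdv > 0, drop = FALSE]
  if (ncol(m) < 2) stop_invalid("fewer than two genera pass the filters")
  r <- stats::cor(m)
  tt <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
  pv <- 2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
  keep <- pcit_filter(r)
  adj <- keep & abs(r) >= r_cut & pv <= p_cut
  diag(adj) <- FALSE
  idx <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  genera <- colnames(m)
  nodes <- data.frame(genus = genera,
                      mean_abund = colMeans(m),
                      phylum = if (is.null(phylum)) NA_character_ else
                        unname(phylum[genera]),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = genera[idx[, 1]],
                      to = genera[idx[, 2]],
                      r = r[idx],
                      p = pv[idx],
                      stringsAsFactors = FALSE)
  edges$sign <- ifelse(edges$r >= 0, 1L, -1L)
  edges$strong <- abs(edges$r) >= strong_cut
  graph <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                         vertices = nodes)
  structure(list(graph = graph, nodes = nodes, edges = edges,
                 r_cut = r_cut, p_cut = p_cut, strong_cut = strong_cut),
            class = "genus_network")
}

#' @export
print.genus_network <- function(x, ...) {
  cat(sprintf("genus_network: %d nodes, %d edges (%d strong)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$strong)))
  invisible(x)
}

#' Node topology and scale-free fit of a genus network
#'
#' Degree, shortest-path betweenness centrality (normalized to `[0, 1]` by
#' `(n-1)(n-2)/2`), local clustering coefficient (0 for nodes of degree < 2),
#' and the network-level scale-free fit: the squared correlation of
#' log(frequency) versus log(degree) over observed degrees >= 1.
#'
#' @param network a [build_network()] result or an igraph graph.
#' @return list: `node_metrics` (data.frame: genus, degree, betweenness,
#'   clustering), `scale_free_r2`.
#' @export
network_topology <- function(network) {
  g <- if (inherits(network, "genus_network")) network$graph else network
  if (igraph::ecount(g) == 0) stop_invalid("network has no edges")
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, normalized = TRUE)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[is.na(cc)] <- 0
  pos <- deg[deg >= 1]
  freq <- table(pos)
  lx <- log(as.numeric(names(freq)))
  ly <- log(as.numeric(freq))
  r2 <- if (length(freq) >= 2 && stats::sd(lx) > 0 && stats::sd(ly) > 0) {
    stats::cor(lx, ly)^2
  } else {
    NA_real_ # degenerate degree distribution: fit undefined
  }
  list(node_metrics = data.frame(genus = igraph::V(g)$name,
                                 degree = unname(deg),
                                 betweenness = unname(btw),
                                 clustering = unname(cc),
                                 stringsAsFactors = FALSE),
       scale_free_r2 = r2)
}

#' Write a genus network to disk
#'
#' GraphML plus a plain TSV edge list and node attribute table.
#'
#' @param network a [build_network()] result.
#' @param prefix output path prefix; writes `<prefix>.graphml`,
#'   `<prefix>_edges.tsv`, `<prefix>_nodes.tsv`.
#' @return `prefix`, invisibly.
#' @export
write_network <- function(network, prefix) {
  stopifnot(inherits(network, "genus_network"))
  igraph::write_graph(network$graph, paste0(prefix, ".graphml"),
                      format = "graphml")
  utils::write.table(network$edges, paste0(prefix, "_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(network$nodes, paste0(prefix, "_nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
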