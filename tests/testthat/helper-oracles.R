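# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (edge_abundance, cluster::silhouette, vectorized PCIT, ...)
# so implementation and oracle can disagree.

# tips descending from each edge, by walking tip-to-root paths
oracle_edge_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  parent_of <- integer(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  below <- vector("list", nrow(tree$edge))
  for (tip in seq_len(ntip)) {
    node <- tip
    while (node != root) {
      e <- which(tree$edge[, 2] == node)
      below[[e]] <- c(below[[e]], tree$tip.label[tip])
      node <- parent_of[node]
    }
  }
  below
}

oracle_weighted_unifrac <- function(tree, a, b, normalized = TRUE) {
  below <- oracle_edge_tips(tree)
  num <- den <- 0
  for (e in seq_along(below)) {
    ai <- sum(a[names(a) %in% below[[e]]])
    bi <- sum(b[names(b) %in% below[[e]]])
    num <- num + tree$edge.length[e] * abs(ai - bi)
    den <- den + tree$edge.length[e] * (ai + bi)
  }
  if (normalized) num / den else num
}

oracle_unweighted_unifrac <- function(tree, set_a, set_b) {
  below <- oracle_edge_tips(tree)
  uniq <- shared_or <- 0
  for (e in seq_along(below)) {
    in_a <- any(set_a %in% below[[e]])
    in_b <- any(set_b %in% below[[e]])
    if (in_a || in_b) {
      shared_or <- shared_or + tree$edge.length[e]
      if (xor(in_a, in_b)) uniq <- uniq + tree$edge.length[e]
    }
  }
  uniq / shared_or
}

oracle_silhouette <- function(d, labels) {
  m <- as.matrix(d)
  n <- nrow(m)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(m[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(k) mean(m[i, labels == k]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# literal trio-enumeration PCIT
oracle_pcit <- function(r) {
  n <- nrow(r)
  keep <- matrix(TRUE, n, n)
  if (n < 3) return(keep)
  trios <- utils::combn(n, 3)
  for (t in seq_len(ncol(trios))) {
    x <- trios[1, t]; y <- trios[2, t]; z <- trios[3, t]
    rxy <- r[x, y]; rxz <- r[x, z]; ryz <- r[y, z]
    if (abs(rxy) == 1 || abs(rxz) == 1 || abs(ryz) == 1) next
    if (rxy == 0 || rxz == 0 || ryz == 0) next
    pxy <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
    pxz <- (rxz - rxy * ryz) / sqrt((1 - rxy^2) * (1 - ryz^2))
    pyz <- (ryz - rxy * rxz) / sqrt((1 - rxy^2) * (1 - rxz^2))
    eps <- (abs(pxy / rxy) + abs(pxz / rxz) + abs(pyz / ryz)) / 3
    if (abs(rxy) <= eps * abs(rxz) && abs(rxy) <= eps * abs(ryz)) {
      keep[x, y] <- keep[y, x] <- FALSE
    }
    if (abs(rxz) <= eps * abs(rxy) && abs(rxz) <= eps * abs(ryz)) {
      keep[x, z] <- keep[z, x] <- FALSE
    }
    if (abs(ryz) <= eps * abs(rxy) && abs(ryz) <= eps * abs(rxz)) {
      keep[y, z] <- keep[z, y] <- FALSE
    }
  }
  keep
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
oracle_mw_exact_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(y) / 2
  p <- if (u_obs > mu) 2 * mean(u_all >= u_obs) else 2 * mean(u_all <= u_obs)
  min(1, p)
}

# two-sided Fisher p by hypergeometric enumeration
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# random valid correlation matrix (from random data, so PSD)
random_cor <- function(n_var, n_obs = 30) {
  stats::cor(matrix(stats::rnorm(n_obs * n_var), n_obs, n_var))
}

# random abundance vector over the tree's tips, normalized
random_relabund <- function(tips) {
  v <- stats::rexp(length(tips))
  stats::setNames(v / sum(v), tips)
}
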