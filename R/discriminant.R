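#' Mann-Whitney U test (two-sided)
#'
#' Wrapper around [stats::wilcox.test()]: exact enumeration for small
#' samples without ties, normal approximation with tie and continuity
#' correction otherwise. `U` is reported for the first sample, so
#' `U + U' = n_x * n_y`.
#'
#' @param x,y numeric vectors (each non-empty).
#' @return list with `U` and `p` (two-sided).
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop_invalid("both groups must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by summing hypergeometric probabilities no larger than
#' the observed table's (via [stats::fisher.test()]). A table with a zero
#' margin carries no information: p = 1 with a warning.
#'
#' @param tab non-negative integer 2x2 matrix.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0) || any(tab != round(tab))) {
    stop_invalid("'tab' must be a non-negative integer 2x2 table")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin: Fisher p set to 1", call. = FALSE)
    return(1)
  }
  stats::fisher.test(tab)$p.value
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (`adj p_(i) = min_{j >= i} m p_(j) / j`, capped at
#' 1), via [stats::p.adjust()]. `NA` p-values propagate.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, order-preserving.
#' @export
bh_adjust <- function(p) {
  ok <- is.na(p) | (p >= 0 & p <= 1)
  if (!all(ok)) stop_invalid("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential genera between two community types
#'
#' Per genus: a Mann-Whitney U test on relative abundances and a Fisher exact
#' test on presence/absence counts, each family BH-adjusted separately. A
#' genus is flagged significant when either adjusted p-value falls below
#' `alpha` (both p-values are reported, so the stricter both-tests rule can
#' be applied downstream). The signed log fold change of community mean
#' abundances uses a pseudo-abundance to keep exclusive genera finite, and
#' exclusivity (absence from one community) is flagged.
#'
#' @param genus_relabund samples x genera relative-abundance matrix.
#' @param labels two-level community labels aligned with the rows.
#' @param alpha significance level on adjusted p-values.
#' @param pseudo pseudo-abundance added inside the log fold change.
#' @return data.frame: `genus`, `lfc` (natural log, community 1 over 2),
#'   `prevalence_1`, `prevalence_2`, `p_mw`, `p_fisher`, `q_mw`, `q_fisher`,
#'   `significant`, `exclusive_to` (0 = shared).
#' @export
differential_genera <- function(genus_relabund, labels, alpha = 0.05,
                                pseudo = 1e-6) {
  lab <- as.integer(as.factor(labels))
  if (length(unique(lab)) != 2) stop_invalid("exactly two classes required")
  if (min(table(lab)) < 3) stop_invalid("each class needs >= 3 samples")
  g1 <- lab == 1L
  res <- lapply(colnames(genus_relabund), function(g) {
    v <- genus_relabund[, g]
    m1 <- mean(v[g1]); m2 <- mean(v[!g1])
    pres <- v > 0
    constant <- length(unique(v)) == 1L
    p_mw <- if (constant) 1 else mann_whitney_u(v[g1], v[!g1])$p
    tab <- rbind(c(sum(pres[g1]), sum(!pres[g1])),
                 c(sum(pres[!g1]), sum(!pres[!g1])))
    p_f <- if (constant) 1 else suppressWarnings(fisher_exact_2x2(tab))
    data.frame(genus = g,
               lfc = if (constant) 0 else {
                 log(m1 + pseudo) - log(m2 + pseudo)
               },
               prevalence_1 = mean(pres[g1]),
               prevalence_2 = mean(pres[!g1]),
               p_mw = p_mw, p_fisher = p_f,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_mw <- bh_adjust(out$p_mw)
  out$q_fisher <- bh_adjust(out$p_fisher)
  out$significant <- out$q_mw < alpha | out$q_fisher < alpha
  out$exclusive_to <- ifelse(out$prevalence_1 > 0 & out$prevalence_2 == 0, 1L,
                             ifelse(out$prevalence_2 > 0 &
                                      out$prevalence_1 == 0, 2L, 0L))
  out
}

# Center (and optionally unit-variance scale) a matrix, remembering the
# transform for prediction.
scale_train <- function(x, scale) {
  mu <- colMeans(x)
  sdv <- if (scale) apply(x, 2, stats::sd) else rep(1, ncol(x))
  sdv[sdv == 0] <- 1
  list(x = sweep(sweep(x, 2, mu), 2, sdv, "/"), mu = mu, sd = sdv)
}

soft_threshold_keep <- function(w, keep) {
  if (keep >= length(w)) return(w)
  cut <- sort(abs(w), decreasing = TRUE)[keep + 1L]
  sign(w) * pmax(abs(w) - cut, 0)
}

#' PLS-DA genus ranking
#'
#' Two-class partial least squares discriminant analysis fitted by NIPALS
#' against the centered one-hot class matrix, with deflation after each
#' component. Genera are ranked by their maximum absolute loading weight
#' across components. `keepX` soft-thresholds each component's weight vector
#' to retain that many genera (sparse PLS-DA).
#'
#' @param x samples x genera matrix.
#' @param labels two-level class labels.
#' @param n_components number of latent components (default 2).
#' @param scale unit-variance scale the columns (default `TRUE`).
#' @param keepX optional per-component number of genera retained.
#' @return list of class `plsda_model`: `weights` (p x A), `x_loadings`,
#'   `scores` (n x A), `y_loadings`, `coefficients` (for prediction),
#'   `ranking` (genus names, most discriminant first), `levels`, centering
#'   info.
#' @export
plsda_fit <- function(x, labels, n_components = 2, scale = TRUE,
                      keepX = NULL) {
  x <- as.matrix(x)
  f <- as.factor(labels)
  if (nlevels(f) != 2) stop_invalid("exactly two classes required")
  y <- stats::model.matrix(~ f - 1)
  colnames(y) <- levels(f)
  st <- scale_train(x, scale)
  xc <- st$x
  ymu <- colMeans(y)
  yc <- sweep(y, 2, ymu)
  a_max <- min(n_components, nrow(x) - 1L, ncol(x))
  if (a_max < n_components) {
    warning("n_components truncated to ", a_max, call. = FALSE)
  }
  p <- ncol(x)
  W <- P <- matrix(0, p, a_max)
  Q <- matrix(0, ncol(y), a_max)
  TT <- matrix(0, nrow(x), a_max)
  xa <- xc; ya <- yc
  for (a in seq_len(a_max)) {
    u <- ya[, which.max(apply(ya, 2, stats::var))]
    w <- rep(0, p)
    for (it in seq_len(500)) {
      w_new <- drop(crossprod(xa, u))
      if (!is.null(keepX)) w_new <- soft_threshold_keep(w_new, keepX)
      nw <- sqrt(sum(w_new^2))
      if (nw == 0) break
      w_new <- w_new / nw
      tt <- drop(xa %*% w_new)
      q <- drop(crossprod(ya, tt)) / sum(tt^2)
      u <- drop(ya %*% q) / sum(q^2)
      if (sum((w_new - w)^2) < 1e-12) { w <- w_new; break }
      w <- w_new
    }
    tt <- drop(xa %*% w)
    if (sum(tt^2) == 0) { a_max <- a - 1L; break }
    pl <- drop(crossprod(xa, tt)) / sum(tt^2)
    q <- drop(crossprod(ya, tt)) / sum(tt^2)
    xa <- xa - tcrossprod(tt, pl)
    ya <- ya - tcrossprod(tt, q)
    W[, a] <- w; P[, a] <- pl; Q[, a] <- q; TT[, a] <- tt
  }
  W <- W[, seq_len(a_max), drop = FALSE]
  P <- P[, seq_len(a_max), drop = FALSE]
  Q <- Q[, seq_len(a_max), drop = FALSE]
  TT <- TT[, seq_len(a_max), drop = FALSE]
  rot <- W %*% solve(crossprod(P, W))
  coef <- rot %*% t(Q)
  rank_stat <- apply(abs(W), 1, max)
  rownames(W) <- rownames(P) <- colnames(x)
  structure(list(weights = W, x_loadings = P, scores = TT, y_loadings = Q,
                 rotation = rot, coefficients = coef,
                 ranking = colnames(x)[order(rank_stat, decreasing = TRUE)],
                 rank_stat = stats::setNames(rank_stat, colnames(x)),
                 levels = levels(f), x_center = st$mu, x_scale = st$sd,
                 y_center = ymu, n_components = a_max),
            class = "plsda_model")
}

#' @export
predict.plsda_model <- function(object, newdata, ...) {
  xn <- sweep(sweep(as.matrix(newdata), 2, object$x_center), 2,
              object$x_scale, "/")
  yhat <- sweep(xn %*% object$coefficients, 2, object$y_center, "+")
  colnames(yhat) <- object$levels
  list(scores = xn %*% object$rotation,
       y_hat = yhat,
       class = object$levels[max.col(yhat)])
}

# rank-based ROC-AUC of `score` for predicting `positive` class membership
auc_score <- function(score, is_positive) {
  n1 <- sum(is_positive); n0 <- sum(!is_positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[is_positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

stratified_folds <- function(f, folds) {
  id <- integer(length(f))
  for (lv in levels(f)) {
    idx <- sample(which(f == lv))
    id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  id
}

#' Sparse PLS-DA with cross-validated AUC
#'
#' For each sparsity level (number of genera retained per component), fits a
#' sparse PLS-DA on the training folds and scores the held-out samples;
#' out-of-fold predictions are pooled into one ROC-AUC per sparsity level.
#' Returns the smallest level whose AUC is within `tol` of the best, together
#' with the genera selected by refitting at that level on the full data.
#'
#' @param x samples x genera matrix.
#' @param labels two-level class labels.
#' @param sparsity_grid numbers of genera to retain per component.
#' @param folds cross-validation folds (stratified by class; reduced with a
#'   warning if a class is smaller than `folds`).
#' @param n_components latent components.
#' @param seed integer seed for fold assignment.
#' @param tol AUC tolerance for the minimum-size rule.
#' @return list: `selected` (genus names), `keepX`, `auc` (at `keepX`),
#'   `cv_auc` (named vector over the grid), `folds`, `seed`.
#' @export
sparse_plsda_cv <- function(x, labels, sparsity_grid = c(1, 2, 3, 5, 7, 10,
                                                         15, 20),
                            folds = 10, n_components = 2, seed = 1L,
                            tol = 0.01) {
  x <- as.matrix(x)
  f <- as.factor(labels)
  if (nlevels(f) != 2) stop_invalid("exactly two classes required")
  if (min(table(f)) < 2) stop_invalid("degenerate folds: a class has < 2 samples")
  if (folds > min(table(f))) {
    folds <- min(table(f))
    warning("folds reduced to the smallest class size (", folds, ")",
            call. = FALSE)
  }
  sparsity_grid <- sort(unique(pmin(sparsity_grid, ncol(x))))
  with_local_seed(seed, {
    fold_id <- stratified_folds(f, folds)
    cv_auc <- vapply(sparsity_grid, function(keep) {
      score <- numeric(length(f))
      for (k in seq_len(folds)) {
        tr <- fold_id != k
        fit <- plsda_fit(x[tr, , drop = FALSE], f[tr],
                         n_components = n_components, keepX = keep)
        score[!tr] <- predict(fit, x[!tr, , drop = FALSE])$y_hat[, 2]
      }
      auc_score(score, f == levels(f)[2])
    }, numeric(1))
    names(cv_auc) <- sparsity_grid
    best <- max(cv_auc)
    keep <- sparsity_grid[which(cv_auc >= best - tol)[1]]
    full <- plsda_fit(x, f, n_components = n_components, keepX = keep)
    selected <- rownames(full$weights)[rowSums(full$weights != 0) > 0]
    list(selected = selected, keepX = keep,
         auc = unname(cv_auc[as.character(keep)]),
         cv_auc = cv_auc, folds = folds, seed = as.integer(seed))
  })
}

# largest soft-threshold delta so that ||soft(b, delta)||_1 / ||.||_2 <= s
l1_project <- function(b, s) {
  norm_w <- function(delta) {
    w <- pmax(b - delta, 0)
    n2 <- sqrt(sum(w^2))
    if (n2 == 0) return(0)
    sum(w / n2)
  }
  if (norm_w(0) <= s) {
    w <- b
  } else {
    lo <- 0; hi <- max(b)
    for (i in seq_len(60)) {
      mid <- (lo + hi) / 2
      if (norm_w(mid) > s) lo <- mid else hi <- mid
    }
    w <- pmax(b - hi, 0)
  }
  n2 <- sqrt(sum(w^2))
  if (n2 == 0) w else w / n2
}

#' Sparse k-means (Witten-Tibshirani)
#'
#' Alternates (i) k-means on the feature-weighted standardized data and
#' (ii) feature weights maximizing the weighted between-cluster sum of
#' squares subject to `||w||_2 <= 1`, `||w||_1 <= l1_bound`, `w >= 0`
#' (soft-thresholding with an L1 line search). `l1_bound = sqrt(p)` imposes
#' no sparsity and recovers plain k-means.
#'
#' @param x samples x features matrix (standardized internally when
#'   `standardize = TRUE`).
#' @param k number of clusters.
#' @param l1_bound L1 bound on the weight vector, in `[1, sqrt(p)]`.
#' @param seed integer seed.
#' @param standardize center and unit-variance scale columns first.
#' @param max_iter maximum alternations.
#' @param nstart random starts per k-means call.
#' @return list: `labels` (integer), `weights` (L2-normalized, >= 0),
#'   `weights_normalized` (summing to 1), `iterations`, `bcss` (per-feature
#'   between-cluster sum of squares).
#' @export
sparse_kmeans <- function(x, k, l1_bound, seed = 1L, standardize = TRUE,
                          max_iter = 20, nstart = 10) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  orig_names <- colnames(x)
  p_all <- ncol(x)
  if (k < 2) stop_invalid("'k' must be >= 2")
  if (l1_bound < 1 || l1_bound > sqrt(p_all) + 1e-8) {
    stop_invalid("'l1_bound' must lie in [1, sqrt(p)]")
  }
  keep_sd <- rep(TRUE, p_all)
  if (standardize) {
    sdv <- apply(x, 2, stats::sd)
    keep_sd <- sdv > 0
    x <- scale(x[, keep_sd, drop = FALSE])
  }
  p <- ncol(x)
  with_local_seed(seed, {
    w <- rep(1 / sqrt(p), p)
    tot <- colSums(sweep(x, 2, colMeans(x))^2)
    labels <- NULL
    for (iter in seq_len(max_iter)) {
      xw <- sweep(x, 2, sqrt(w), "*")
      km <- tryCatch(
        stats::kmeans(xw, centers = k, nstart = nstart, iter.max = 50),
        error = function(e) {
          message("k-means restart after empty cluster: ", conditionMessage(e))
          stats::kmeans(xw, centers = k, nstart = nstart * 2, iter.max = 50)
        })
      labels <- km$cluster
      within <- colSums((x - rowsum(x, labels)[labels, ,
                                               drop = FALSE] /
                           as.vector(table(labels))[labels])^2)
      bcss <- pmax(tot - within, 0)
      w_new <- l1_project(bcss, l1_bound)
      delta <- sum(abs(w_new - w)) / max(sum(abs(w)), 1e-12)
      w <- w_new
      if (delta < 1e-4) break
    }
    weights <- stats::setNames(numeric(p_all), orig_names)
    weights[keep_sd] <- w
    list(labels = labels, weights = weights,
         weights_normalized = weights / sum(weights),
         iterations = iter, bcss = stats::setNames(bcss, colnames(x)))
  })
}
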