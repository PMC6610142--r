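#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance via [vegan::adonis2()]
#' with sequential (Type I) sums of squares, matching `adonis2` semantics:
#' the pseudo-F is computed from the partitioned sums of squared distances
#' and the p-value uses the add-one permutation rule
#' `p = (1 + #{F* >= F}) / (1 + n_perm)`.
#'
#' @param d a `dist` or square symmetric matrix.
#' @param design a grouping vector/factor, or a data.frame of variables
#'   (tested sequentially in the order given).
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed (recorded in the output attributes).
#' @return data.frame with one row per term: `term`, `df`, `ss`, `r2`,
#'   `pseudo_f`, `p`; attributes `n_perm`, `seed`.
#' @export
permanova <- function(d, design, n_perm = 999, seed = 1L) {
  d <- as_dist_checked(d)
  if (n_perm < 99) stop_invalid("'n_perm' must be >= 99")
  df <- if (is.data.frame(design)) design else data.frame(group = design)
  if (nrow(df) != attr(d, "Size")) {
    stop_invalid("design rows must match the distance matrix")
  }
  for (v in names(df)) {
    if (length(unique(df[[v]])) < 2) {
      stop_invalid("constant design variable: ", v)
    }
    if (!is.numeric(df[[v]])) {
      tab <- table(df[[v]])
      if (any(tab == 1)) {
        warning("variable '", v, "' has a single-sample level", call. = FALSE)
      }
    }
  }
  fit <- with_local_seed(seed, {
    vegan::adonis2(d ~ ., data = df, permutations = n_perm, by = "terms")
  })
  terms <- rownames(fit)
  out <- data.frame(term = terms,
                    df = fit$Df,
                    ss = fit$SumOfSqs,
                    r2 = fit$R2,
                    pseudo_f = fit$F,
                    p = fit$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  out <- out[!terms %in% c("Residual", "Total"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Fit environmental vectors onto an ordination
#'
#' Least-squares fit of each continuous variable onto the ordination axes
#' ([vegan::envfit()]): `r2 = 1 - SS_res / SS_tot`, permutation p-values with
#' the add-one rule, BH adjustment across variables. Constant variables get
#' `r2 = 0`, `p = 1`.
#'
#' @param ordination an `ordination` (from [nmds_ordination()] or
#'   [pcoa_ordination()]) or a samples x axes coordinate matrix.
#' @param variables data.frame or matrix of continuous variables aligned to
#'   the samples.
#' @param n_perm permutations (default 10000).
#' @param seed integer seed.
#' @return data.frame: `variable`, direction cosines (one column per axis),
#'   `r2`, `p`, `q`; attributes `n_perm`, `seed`.
#' @export
envfit_screen <- function(ordination, variables, n_perm = 10000, seed = 1L) {
  pts <- if (inherits(ordination, "ordination")) {
    ordination$points
  } else {
    as.matrix(ordination)
  }
  if (ncol(pts) < 2) stop_invalid("ordination must have >= 2 axes")
  vars <- as.data.frame(variables)
  if (nrow(vars) != nrow(pts)) stop_invalid("variables must align to samples")
  if (!all(vapply(vars, is.numeric, logical(1)))) {
    stop_invalid("envfit_screen expects continuous variables")
  }
  constant <- vapply(vars, function(v) stats::var(v, na.rm = TRUE) == 0,
                     logical(1))
  res <- data.frame(variable = names(vars), stringsAsFactors = FALSE)
  dirs <- matrix(NA_real_, ncol(vars), ncol(pts),
                 dimnames = list(names(vars), colnames(pts)))
  res$r2 <- 0
  res$p <- 1
  if (any(!constant)) {
    ef <- with_local_seed(seed, {
      vegan::envfit(pts, vars[, !constant, drop = FALSE],
                    permutations = n_perm, na.rm = TRUE)
    })
    dirs[!constant, ] <- ef$vectors$arrows
    res$r2[!constant] <- ef$vectors$r
    res$p[!constant] <- ef$vectors$pvals
  }
  res <- cbind(res, as.data.frame(dirs))
  res$q <- bh_adjust(res$p)
  rownames(res) <- NULL
  attr(res, "n_perm") <- n_perm
  attr(res, "seed") <- as.integer(seed)
  res
}

#' Two-way ANOVA with Type II sums of squares
#'
#' Additive two-factor analysis of variance on an unbalanced design (e.g.
#' community type and race distance), with Type II tests via [car::Anova()].
#' An interaction is fitted only on request and dropped with a warning when
#' some cell is empty.
#'
#' @param y continuous response.
#' @param factor_a,factor_b factors (>= 2 levels each).
#' @param interaction include the interaction term.
#' @return data.frame: `term`, `ss`, `df`, `f`, `p`.
#' @export
two_way_anova <- function(y, factor_a, factor_b, interaction = FALSE) {
  a <- as.factor(factor_a)
  b <- as.factor(factor_b)
  if (nlevels(a) < 2 || nlevels(b) < 2) {
    stop_invalid("both factors need >= 2 levels")
  }
  if (interaction && any(table(a, b) == 0)) {
    warning("empty cell: interaction dropped", call. = FALSE)
    interaction <- FALSE
  }
  fml <- if (interaction) y ~ a * b else y ~ a + b
  fit <- stats::lm(fml, data = data.frame(y = y, a = a, b = b))
  av <- car::Anova(fit, type = "II")
  terms <- rownames(av)
  keep <- terms != "Residuals"
  data.frame(term = c(a = "factor_a", b = "factor_b",
                      `a:b` = "interaction")[terms[keep]],
             ss = av$`Sum Sq`[keep],
             df = av$Df[keep],
             f = av$`F value`[keep],
             p = av$`Pr(>F)`[keep],
             stringsAsFactors = FALSE)
}

#' Probabilistic quotient normalization of spectral bins
#'
#' Each spectrum is divided by the median of its bin-wise quotients to the
#' reference spectrum (the bin-wise median across samples); bins where the
#' reference is zero are excluded from the quotient. Removes per-sample
#' dilution effects from NMR-style bin tables.
#'
#' @param spectra samples x bins non-negative matrix (>= 2 spectra).
#' @return normalized matrix with attribute `dilution` (the estimated
#'   per-sample factors).
#' @export
pq_normalize <- function(spectra) {
  m <- as.matrix(spectra)
  if (nrow(m) < 2) stop_invalid("need at least two spectra")
  if (any(m < 0)) stop_invalid("spectral intensities must be non-negative")
  if (any(rowSums(m) == 0)) stop_invalid("all-zero spectrum")
  ref <- apply(m, 2, stats::median)
  use <- ref > 0
  if (!any(use)) stop_invalid("reference spectrum is all zero")
  q <- sweep(m[, use, drop = FALSE], 2, ref[use], "/")
  factors <- apply(q, 1, stats::median)
  out <- m / factors
  attr(out, "dilution") <- factors
  out
}

#' Screen metadata variables against community types
#'
#' Continuous variables are tested with the Mann-Whitney U test, categorical
#' variables with Fisher's exact test (exact for small tables, Monte-Carlo
#' with a recorded seed otherwise), followed by BH adjustment within each
#' declared variable family. Missing values are pairwise-deleted, never
#' imputed; variables with fewer than 3 non-missing values in either
#' community are skipped with a message. Paired race measurements should be
#' passed as pre-computed deltas (T1 - T0).
#'
#' @param labels two-level community labels, named by sample id.
#' @param metadata data.frame of per-sample variables (a `sample_id` column,
#'   if present, is used for alignment).
#' @param alpha significance threshold on adjusted p-values.
#' @param families optional named list mapping family name -> variable names;
#'   default places all variables in one family.
#' @param mc_draws Monte-Carlo draws for large categorical tables.
#' @param seed integer seed for Monte-Carlo Fisher tests.
#' @return data.frame of class `association_report`: `variable`, `family`,
#'   `test`, `statistic`, `direction` (sign of community-1 minus community-2
#'   median, continuous only), `p`, `q`, `n_used`, `significant`.
#' @export
screen_variables <- function(labels, metadata, alpha = 0.05, families = NULL,
                             mc_draws = 1e5, seed = 1L) {
  lab <- as.integer(as.factor(labels))
  if (length(unique(lab)) != 2) stop_invalid("exactly two communities required")
  md <- as.data.frame(metadata)
  if ("sample_id" %in% names(md) && !is.null(names(labels))) {
    md <- md[match(names(labels), md$sample_id), , drop = FALSE]
  }
  if (nrow(md) != length(lab)) stop_invalid("metadata must align to labels")
  vars <- setdiff(names(md), "sample_id")
  if (is.null(families)) families <- list(all = vars)
  fam_of <- stats::setNames(rep(names(families), lengths(families)),
                            unlist(families))
  rows <- lapply(vars, function(v) {
    x <- md[[v]]
    ok <- !is.na(x)
    n_used <- sum(ok)
    g <- lab[ok]
    if (min(table(factor(g, levels = 1:2))) < 3) {
      message("variable '", v, "' skipped: < 3 non-missing per community")
      return(data.frame(variable = v, test = "skipped", statistic = NA_real_,
                        direction = NA_real_, p = NA_real_, n_used = n_used,
                        stringsAsFactors = FALSE))
    }
    if (is.numeric(x)) {
      mw <- mann_whitney_u(x[ok][g == 1], x[ok][g == 2])
      data.frame(variable = v, test = "mann-whitney", statistic = mw$U,
                 direction = sign(stats::median(x[ok][g == 1]) -
                                    stats::median(x[ok][g == 2])),
                 p = mw$p, n_used = n_used, stringsAsFactors = FALSE)
    } else {
      tab <- table(g, as.factor(as.character(x[ok])))
      tab <- tab[, colSums(tab) > 0, drop = FALSE]
      if (ncol(tab) < 2) {
        p <- 1
        or <- NA_real_
      } else if (ncol(tab) <= 5 && sum(tab) <= 60) {
        ft <- stats::fisher.test(tab)
        p <- ft$p.value
        or <- if (!is.null(ft$estimate)) unname(ft$estimate) else NA_real_
      } else {
        ft <- with_local_seed(seed, {
          stats::fisher.test(tab, simulate.p.value = TRUE, B = mc_draws)
        })
        p <- ft$p.value
        or <- NA_real_
      }
      data.frame(variable = v, test = "fisher", statistic = or,
                 direction = NA_real_, p = p, n_used = n_used,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$family <- unname(fam_of[out$variable])
  out$family[is.na(out$family)] <- "unassigned"
  out$q <- NA_real_
  for (f in unique(out$family)) {
    sel <- out$family == f & out$test != "skipped"
    out$q[sel] <- bh_adjust(out$p[sel])
  }
  out$significant <- !is.na(out$q) & out$q < alpha
  out <- out[, c("variable", "family", "test", "statistic", "direction",
                 "p", "q", "n_used", "significant")]
  attr(out, "alpha") <- alpha
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("association_report", "data.frame")
  out
}
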