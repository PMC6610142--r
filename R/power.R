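#' Monte-Carlo power of Fisher's exact test for a community contrast
#'
#' Splits `n_total` into the two community sizes (`n1 = round(n_total *
#' split)`), draws binomial success counts with probabilities `p1` and `p2`,
#' applies the two-sided Fisher exact test at level `alpha` to each
#' replicate, and reports the rejection fraction with its Monte-Carlo
#' standard error. P-values are memoized over the distinct tables, so large
#' replicate counts are cheap.
#'
#' @param n_total total cohort size.
#' @param split proportion of samples in community 1, in `(0, 1)`.
#' @param p1,p2 success probabilities (e.g. race-elimination rates) per
#'   community.
#' @param alpha significance level.
#' @param reps Monte-Carlo replicates.
#' @param seed integer seed.
#' @return list of class `power_estimate`: `power`, `se`, `n1`, `n2`,
#'   `alpha`, `reps`, `seed`, `test`.
#' @export
power_fisher <- function(n_total, split, p1, p2, alpha = 0.05, reps = 10000,
                         seed = 1L) {
  split <- check_probability(split, "split", open_zero = TRUE)
  if (split >= 1) stop_invalid("'split' must lie strictly inside (0, 1)")
  p1 <- check_probability(p1, "p1")
  p2 <- check_probability(p2, "p2")
  n1 <- round(n_total * split)
  n2 <- n_total - n1
  if (n1 < 1 || n2 < 1) stop_invalid("a community is empty at this n_total")
  with_local_seed(seed, {
    x1 <- stats::rbinom(reps, n1, p1)
    x2 <- stats::rbinom(reps, n2, p2)
    key <- paste(x1, x2)
    uniq <- !duplicated(key)
    pv <- vapply(which(uniq), function(i) {
      suppressWarnings(fisher_exact_2x2(
        rbind(c(x1[i], n1 - x1[i]), c(x2[i], n2 - x2[i]))))
    }, numeric(1))
    p <- pv[match(key, key[uniq])]
    pow <- mean(p < alpha)
    structure(list(power = pow, se = sqrt(pow * (1 - pow) / reps),
                   n1 = n1, n2 = n2, alpha = alpha, reps = reps,
                   seed = as.integer(seed), test = "fisher"),
              class = "power_estimate")
  })
}

# Two-sided Mann-Whitney p by the normal approximation with continuity and
# tie corrections; agrees with wilcox.test(correct = TRUE) and avoids its
# per-call overhead inside the Monte-Carlo power loop.
mw_pvalue_normal <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  n <- n1 + n2
  tie_term <- 0
  if (anyDuplicated(r)) {
    nt <- table(r)
    tie_term <- sum(nt^3 - nt) / (n * (n - 1))
  }
  sigma <- sqrt(n1 * n2 / 12 * (n + 1 - tie_term))
  z <- (u - mu - sign(u - mu) * 0.5) / sigma
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Monte-Carlo power of the Mann-Whitney test for a community contrast
#'
#' Group values are drawn from uniform distributions matched to the target
#' mean and standard deviation (support `mean +/- sqrt(3) sd`); a declared
#' floor (e.g. age cannot be negative) truncates the support with a warning.
#' Each replicate is tested with the two-sided Mann-Whitney U test.
#'
#' @param n_total,split,alpha,reps,seed as in [power_fisher()].
#' @param mean1,sd1,mean2,sd2 per-community distribution parameters
#'   (`sd > 0`).
#' @param floor optional lower bound for the support.
#' @return a `power_estimate` (see [power_fisher()]).
#' @export
power_mannwhitney <- function(n_total, split, mean1, sd1, mean2, sd2,
                              alpha = 0.05, reps = 10000, seed = 1L,
                              floor = NULL) {
  split <- check_probability(split, "split", open_zero = TRUE)
  if (split >= 1) stop_invalid("'split' must lie strictly inside (0, 1)")
  if (sd1 <= 0 || sd2 <= 0) stop_invalid("standard deviations must be positive")
  n1 <- round(n_total * split)
  n2 <- n_total - n1
  if (n1 < 1 || n2 < 1) stop_invalid("a community is empty at this n_total")
  lo1 <- mean1 - sqrt(3) * sd1; hi1 <- mean1 + sqrt(3) * sd1
  lo2 <- mean2 - sqrt(3) * sd2; hi2 <- mean2 + sqrt(3) * sd2
  if (!is.null(floor) && (lo1 < floor || lo2 < floor)) {
    warning("uniform support truncated at the declared floor", call. = FALSE)
    lo1 <- max(lo1, floor); lo2 <- max(lo2, floor)
  }
  use_approx <- n1 + n2 > 200 # large samples: direct normal approximation
  with_local_seed(seed, {
    hits <- 0L
    for (i in seq_len(reps)) {
      x <- stats::runif(n1, lo1, hi1)
      y <- stats::runif(n2, lo2, hi2)
      p <- if (use_approx) {
        mw_pvalue_normal(x, y)
      } else {
        suppressWarnings(
          stats::wilcox.test(x, y, alternative = "two.sided",
                             exact = (n1 < 50 && n2 < 50))$p.value)
      }
      if (p < alpha) hits <- hits + 1L
    }
    pow <- hits / reps
    structure(list(power = pow, se = sqrt(pow * (1 - pow) / reps),
                   n1 = n1, n2 = n2, alpha = alpha, reps = reps,
                   seed = as.integer(seed), test = "mann-whitney"),
              class = "power_estimate")
  })
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("power (%s): %.3f +/- %.3f (n = %d + %d, alpha %.3g, %d reps)\n",
              x$test, x$power, x$se, x$n1, x$n2, x$alpha, x$reps))
  invisible(x)
}

#' Smallest cohort size reaching a target power
#'
#' Evaluates `power_fn` along an increasing grid of total sample sizes with
#' common random numbers (the same seed at every size, so the estimated
#' power curve is monotone in expectation without Monte-Carlo crossings),
#' then refines the first bracketing interval by bisection down to `n_tol`.
#'
#' @param power_fn function `(n_total) -> power` (scalar or
#'   `power_estimate`); typically a closure over [power_fisher()] or
#'   [power_mannwhitney()] with `reps` and `seed` fixed.
#' @param target_power target (e.g. 0.9 for a type II error of 0.1).
#' @param n_grid strictly increasing integer grid.
#' @param n_tol bisection stops when the bracket is at most this wide.
#' @return list of class `required_n`: `n` (smallest size found with power >=
#'   target; `Inf` if the target is unreachable on the grid), `interval`
#'   (bracketing `c(lower, upper)`), `evaluations` (data.frame `n`, `power`).
#' @export
required_n <- function(power_fn, target_power = 0.9, n_grid, n_tol = 5) {
  if (is.unsorted(n_grid, strictly = TRUE)) {
    stop_invalid("'n_grid' must be strictly increasing")
  }
  getp <- function(n) {
    res <- power_fn(n)
    if (inherits(res, "power_estimate")) res$power else as.numeric(res)
  }
  evals <- data.frame(n = integer(), power = numeric())
  hi <- NA_integer_
  lo <- NA_integer_
  for (n in n_grid) {
    pw <- getp(n)
    evals <- rbind(evals, data.frame(n = n, power = pw))
    if (pw >= target_power) { hi <- n; break }
    lo <- n
  }
  if (is.na(hi)) {
    return(structure(list(n = Inf, interval = c(max(n_grid), Inf),
                          evaluations = evals, target = target_power),
                     class = "required_n"))
  }
  if (is.na(lo)) { # first grid point already reaches the target
    return(structure(list(n = hi, interval = c(NA_integer_, hi),
                          evaluations = evals, target = target_power),
                     class = "required_n"))
  }
  while (hi - lo > n_tol) {
    mid <- floor((hi + lo) / 2)
    pw <- getp(mid)
    evals <- rbind(evals, data.frame(n = mid, power = pw))
    if (pw >= target_power) hi <- mid else lo <- mid
  }
  structure(list(n = hi, interval = c(lo, hi),
                 evaluations = evals[order(evals$n), ],
                 target = target_power),
            class = "required_n")
}

#' @export
print.required_n <- function(x, ...) {
  cat(sprintf("required n for power %.2f: %s (bracket [%s, %s])\n",
              x$target, format(x$n), format(x$interval[1]),
              format(x$interval[2])))
  invisible(x)
}

#' Power versus effect size at fixed cohort size
#'
#' Scales the observed effect by each multiplier `m` around the null —
#' for Fisher, proportions move around the pooled proportion
#' (`p_i' = p_bar + m (p_i - p_bar)`, clipped to `[0, 1]` with a warning);
#' for Mann-Whitney, the mean ratio scales
#' (`mean1' = mean2 (1 + m (mean1/mean2 - 1))`) — and estimates power at the
#' observed `n_total` for each scaled effect. `m = 1` reproduces the base
#' power; `m = 0` is the null.
#'
#' @param test `"fisher"` or `"mannwhitney"`.
#' @param n_total,split,alpha,reps,seed as in [power_fisher()].
#' @param effect_multipliers non-negative multipliers.
#' @param p1,p2 Fisher base proportions.
#' @param mean1,sd1,mean2,sd2 Mann-Whitney base parameters.
#' @param floor optional support floor for Mann-Whitney draws.
#' @return data.frame of class `power_curve`: `multiplier`, `power`, `se`;
#'   attributes record the full configuration.
#' @export
power_by_effect <- function(test = c("fisher", "mannwhitney"), n_total, split,
                            effect_multipliers, p1 = NULL, p2 = NULL,
                            mean1 = NULL, sd1 = NULL, mean2 = NULL,
                            sd2 = NULL, alpha = 0.05, reps = 10000,
                            seed = 1L, floor = NULL) {
  test <- match.arg(test)
  if (any(effect_multipliers < 0)) {
    stop_invalid("effect multipliers must be non-negative")
  }
  rows <- lapply(effect_multipliers, function(m) {
    if (test == "fisher") {
      pbar <- split * p1 + (1 - split) * p2
      p1m <- pbar + m * (p1 - pbar)
      p2m <- pbar + m * (p2 - pbar)
      if (p1m < 0 || p1m > 1 || p2m < 0 || p2m > 1) {
        warning("scaled proportion clipped to [0, 1]", call. = FALSE)
        p1m <- min(max(p1m, 0), 1)
        p2m <- min(max(p2m, 0), 1)
      }
      est <- power_fisher(n_total, split, p1m, p2m, alpha, reps, seed)
    } else {
      m1 <- mean2 * (1 + m * (mean1 / mean2 - 1))
      est <- power_mannwhitney(n_total, split, m1, sd1, mean2, sd2, alpha,
                               reps, seed, floor = floor)
    }
    data.frame(multiplier = m, power = est$power, se = est$se)
  })
  out <- do.call(rbind, rows)
  attr(out, "test") <- test
  attr(out, "n_total") <- n_total
  attr(out, "split") <- split
  attr(out, "alpha") <- alpha
  attr(out, "reps") <- reps
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("power_curve", "data.frame")
  out
}
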