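# internal helpers shared across modules

# Run `expr` under a local RNG state seeded with `seed`, restoring the global
# state afterwards so library code never clobbers a user's random stream.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

check_scalar_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    stop_invalid(sprintf("'%s' must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_probability <- function(x, name, open_zero = FALSE) {
  lo_ok <- if (open_zero) x > 0 else x >= 0
  if (length(x) != 1L || !is.finite(x) || !lo_ok || x > 1) {
    stop_invalid(sprintf("'%s' must be a single value in %s0, 1]",
                         name, if (open_zero) "(" else "["))
  }
  as.numeric(x)
}

# symmetric matrix (or dist) -> dist with labels preserved
as_dist_checked <- function(d, tol = 1e-12) {
  if (inherits(d, "dist")) return(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop_invalid("distance input must be a 'dist' object or a square matrix")
  }
  if (max(abs(d - t(d))) > tol) stop_invalid("distance matrix is not symmetric")
  if (any(diag(d) != 0)) stop_invalid("distance matrix diagonal must be zero")
  if (any(d < 0)) stop_invalid("distances must be non-negative")
  stats::as.dist(d)
}

dist_labels <- function(d) {
  lab <- attr(d, "Labels")
  if (is.null(lab)) lab <- as.character(seq_len(attr(d, "Size")))
  lab
}

# draw one Dirichlet vector; zero alphas yield structural zeros
rdirichlet1 <- function(alpha) {
  g <- numeric(length(alpha))
  pos <- alpha > 0
  g[pos] <- stats::rgamma(sum(pos), shape = alpha[pos], rate = 1)
  if (sum(g) == 0) g[pos] <- 1 # degenerate guard: uniform over support
  g / sum(g)
}
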