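## Small shared helpers: seeded RNG scoping, index checks, Rand index.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the global \code{.Random.seed}, so seeded package
#' functions never disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @export
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## Derive a reproducible child seed below 2^31 from a parent seed and a tag.
child_seed <- function(seed, k) {
  (as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647
}

#' Rand index between two labelings
#'
#' Fraction of point pairs on which two clusterings agree (same/different
#' cluster). 1 means identical partitions up to relabeling.
#'
#' @param a,b integer label vectors of equal length.
#' @return Rand index in \[0, 1\].
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  (total + 2 * sum_ij - sum_a - sum_b) / total
}

## Row-normalize a nonnegative matrix; rows summing to 0 become uniform.
row_normalize <- function(m) {
  rs <- rowSums(m)
  zero <- rs <= 0
  if (any(zero)) {
    m[zero, ] <- 1
    rs[zero] <- ncol(m)
  }
  m / rs
}

## Categorical sampling for a vector of rows of a probability matrix:
## draw[i] ~ Categorical(P[rows[i], ]). Vectorized over i.
sample_rows <- function(P, rows) {
  cp <- t(apply(P, 1, cumsum))
  u <- runif(length(rows))
  rowSums(u > cp[rows, , drop = FALSE]) + 1L
}

## Symmetric inverse square root with spectral floor (relative to max eigval).
sym_inv_sqrt <- function(S, rel_tol = 1e-10) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  keep <- e$values > rel_tol * max(e$values)
  V <- e$vectors[, keep, drop = FALSE]
  V %*% (t(V) / sqrt(e$values[keep]))
}
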