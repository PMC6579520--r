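## Time-lagged independent component analysis with kinetic and commute
## mappings and kinetic-content truncation.

## Coerce the accepted feature inputs into a list of plain matrices.
feature_matrices <- function(features) {
  if (inherits(features, "trajectory_set")) features <- features$features
  if (inherits(features, "feature_trajectory")) features <- list(features)
  if (is.matrix(features)) features <- list(features)
  lapply(features, function(f)
    if (inherits(f, "feature_trajectory")) f$X else as.matrix(f))
}

#' Fit a tICA model
#'
#' Solves the symmetrized generalized eigenproblem
#' \eqn{C(\tau) v = \lambda C(0) v} on mean-free data pooled over
#' trajectories; lagged pairs never span trajectory boundaries. The
#' time-lagged covariance is symmetrized, \eqn{(C(\tau)+C(\tau)^T)/2}, to
#' enforce a real spectrum on finite data, and \eqn{C(0)} is regularized by
#' discarding covariance eigenpairs below \code{1e-10} of the largest
#' before whitening. Eigenvalues are clipped to (-1, 1].
#'
#' @param features list of feature matrices (frames x features), a
#'   \code{trajectory_set}, or \code{feature_trajectory} objects.
#' @param lag lag time in frames (>= 1).
#' @param mapping \code{"commute"} (default, scales components by
#'   \eqn{\sqrt{t_i/2}}) or \code{"kinetic"} (scales by \eqn{\lambda_i}).
#' @return object of class \code{tica_model}: \code{lag}, \code{mean},
#'   \code{eigenvalues} (descending), \code{components} (columns,
#'   orthonormal w.r.t. C(0)), \code{timescales}, \code{mapping}.
#' @export
fit_tica <- function(features, lag, mapping = c("commute", "kinetic")) {
  mapping <- match.arg(mapping)
  xs <- feature_matrices(features)
  stopifnot(lag >= 1)
  usable <- vapply(xs, nrow, integer(1)) > lag
  if (!any(usable)) stop("every trajectory is shorter than the lag")
  xs <- xs[usable]

  d <- ncol(xs[[1]])
  n_pairs <- 0
  s <- numeric(d)
  for (X in xs) {
    idx0 <- seq_len(nrow(X) - lag)
    s <- s + colSums(X[idx0, , drop = FALSE]) +
      colSums(X[idx0 + lag, , drop = FALSE])
    n_pairs <- n_pairs + length(idx0)
  }
  mu <- s / (2 * n_pairs)

  C0 <- matrix(0, d, d); Ct <- matrix(0, d, d)
  for (X in xs) {
    idx0 <- seq_len(nrow(X) - lag)
    A <- sweep(X[idx0, , drop = FALSE], 2, mu)
    B <- sweep(X[idx0 + lag, , drop = FALSE], 2, mu)
    C0 <- C0 + crossprod(A) + crossprod(B)
    Ct <- Ct + crossprod(A, B)
  }
  C0 <- C0 / (2 * n_pairs)
  Ct <- (Ct + t(Ct)) / (2 * n_pairs)

  ev0 <- eigen((C0 + t(C0)) / 2, symmetric = TRUE)
  keep <- ev0$values > 1e-10 * max(ev0$values)
  if (!any(keep)) stop("all features are constant; nothing to analyse")
  W <- ev0$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(ev0$values[keep]), sum(keep))
  M <- t(W) %*% Ct %*% W
  em <- eigen((M + t(M)) / 2, symmetric = TRUE)
  lam <- pmin(pmax(em$values, -1 + 1e-15), 1)
  ord <- order(lam, decreasing = TRUE)
  lam <- lam[ord]
  comps <- W %*% em$vectors[, ord, drop = FALSE]
  ts <- vapply(lam, function(l) {
    if (l >= 1) Inf else if (l > 0) -lag / log(l) else NA_real_
  }, numeric(1))

  structure(list(lag = lag, mean = mu, eigenvalues = lam,
                 components = comps, timescales = ts, mapping = mapping),
            class = "tica_model")
}

#' @export
print.tica_model <- function(x, ...) {
  cat("tICA model: lag", x$lag, "frames,", length(x$eigenvalues),
      "components,", x$mapping, "mapping\n")
  k <- min(5, length(x$eigenvalues))
  cat("  leading eigenvalues:", signif(x$eigenvalues[seq_len(k)], 4), "\n")
  invisible(x)
}

## Indices of components carrying resolvable kinetics (lambda in (0,1), so
## the timescale is defined); negative-eigenvalue components are dropped.
kinetic_components <- function(model) {
  which(model$eigenvalues > 0 & is.finite(model$timescales))
}

#' Cumulative kinetic-content profile
#'
#' Kinetic content of component i is defined as \eqn{t_i/2} (the
#' commute-map variance), normalized over the components with positive
#' eigenvalue; the profile is its cumulative sum -- nondecreasing, ending
#' at 1.
#'
#' @param model a fitted \code{tica_model}.
#' @return numeric vector of cumulative fractions, one per kinetic
#'   component.
#' @export
kinetic_content_profile <- function(model) {
  idx <- kinetic_components(model)
  if (!length(idx)) stop("model has no components with positive eigenvalue")
  content <- model$timescales[idx] / 2
  cumsum(content) / sum(content)
}

#' Project features onto tICA components
#'
#' Projects mean-free data on the model's components, retaining either the
#' smallest number of components whose cumulative kinetic content reaches
#' \code{kinetic_content}, or exactly \code{n_components}. The kinetic
#' mapping scales component i by \eqn{\lambda_i}; the commute mapping by
#' \eqn{\sqrt{t_i/2}}. Components with non-positive eigenvalue carry no
#' resolvable kinetics and are never retained.
#'
#' @param model a fitted \code{tica_model}.
#' @param features same accepted forms as \code{\link{fit_tica}}.
#' @param kinetic_content fraction of total kinetic content to retain
#'   (default 0.95); ignored when \code{n_components} is given.
#' @param n_components exact number of components to retain (optional).
#' @return list of projected matrices (frames x retained components).
#' @export
tica_transform <- function(model, features, kinetic_content = 0.95,
                           n_components = NULL) {
  xs <- feature_matrices(features)
  if (ncol(xs[[1]]) != length(model$mean))
    stop("feature dimensionality does not match the model")
  idx <- kinetic_components(model)
  if (is.null(n_components)) {
    prof <- kinetic_content_profile(model)
    k <- which(prof >= kinetic_content - 1e-12)[1]
    idx <- idx[seq_len(k)]
  } else {
    if (n_components > length(idx))
      stop("requested more components than have positive eigenvalue")
    idx <- idx[seq_len(n_components)]
  }
  scale_f <- switch(model$mapping,
                    kinetic = model$eigenvalues[idx],
                    commute = sqrt(model$timescales[idx] / 2))
  P <- model$components[, idx, drop = FALSE] *
    rep(scale_f, each = nrow(model$components))
  lapply(xs, function(X) sweep(X, 2, model$mean) %*% P)
}
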