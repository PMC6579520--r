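## Landscape artifacts of a coarse-grained model: equilibrium flux
## matrices, log-inverse-flux MDS embeddings, free energies and flux
## networks.

#' Equilibrium flux matrix between macrostates
#'
#' \eqn{F_{ij} = \pi_i (T^p)_{ij} / (p \, \mathrm{lag})} for \eqn{i \ne j},
#' in inverse time units of \code{lag}. The default third power eliminates
#' sparsity of the one-step matrix; under detailed balance F is symmetric.
#'
#' @param hmm a fitted \code{hmm_model} or \code{generator_model} (or any
#'   list with \code{macro_T}, \code{macro_pi}).
#' @param power matrix power (default 3).
#' @param lag_time physical time per lag step (default the model's
#'   \code{step_time}/\code{lag} when available, else 1).
#' @return symmetric-under-detailed-balance flux matrix with zero diagonal.
#' @export
flux_matrix <- function(hmm, power = 3, lag_time = NULL) {
  if (is.null(lag_time))
    lag_time <- hmm$step_time %||% hmm$lag %||% 1
  Tp <- matrix_power(hmm$macro_T, power)
  F <- (hmm$macro_pi * Tp) / (power * lag_time)
  diag(F) <- 0
  F
}

#' Kinetic 2-D embedding by metric MDS of log-inverse fluxes
#'
#' Dissimilarities \eqn{D_{ij} = \log(1/F_{ij})}, shifted so the smallest
#' off-diagonal value is nonnegative, are embedded in two dimensions by
#' iterative stress majorization (SMACOF), restarted from
#' \code{n_restarts} random initializations; the minimum-stress embedding
#' is returned and every restart's stress is recorded so a user can
#' re-select a projection by other criteria.
#'
#' @param flux flux matrix with positive off-diagonal entries.
#' @param n_restarts random restarts (default 50).
#' @param seed integer seed.
#' @param max_iter majorization iterations per restart (default 300).
#' @return object of class \code{mds_embedding}: \code{coords} (n x 2),
#'   \code{dissimilarity}, \code{stress}, \code{restart_stresses},
#'   \code{n_restarts}, \code{seed}.
#' @export
embed_mds <- function(flux, n_restarts = 50, seed = 1, max_iter = 300) {
  n <- nrow(flux)
  off <- flux[row(flux) != col(flux)]
  if (any(off <= 0))
    stop("all off-diagonal fluxes must be positive (use a matrix power)")
  D <- log(1 / flux)
  shift <- min(D[row(D) != col(D)])
  if (shift < 0) D <- D - shift       # only shift when negative
  diag(D) <- 0
  D <- (D + t(D)) / 2
  if (any(!is.finite(D))) stop("non-finite dissimilarities")

  best <- NULL
  stresses <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    X0 <- with_seed(child_seed(seed, r),
                    matrix(rnorm(2 * n, sd = max(D)), n, 2))
    fit <- smacof_mds(D, X0, max_iter = max_iter)
    stresses[r] <- fit$stress
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  structure(list(coords = best$X, dissimilarity = D, stress = best$stress,
                 restart_stresses = stresses, n_restarts = n_restarts,
                 seed = seed),
            class = "mds_embedding")
}

## One SMACOF run: Guttman-transform majorization of raw stress.
smacof_mds <- function(D, X, max_iter = 300, tol = 1e-10) {
  n <- nrow(D)
  stress_of <- function(X) {
    d <- as.matrix(dist(X))
    sum((D - d)[upper.tri(D)]^2)
  }
  s_old <- stress_of(X)
  for (it in seq_len(max_iter)) {
    d <- as.matrix(dist(X))
    ratio <- ifelse(d > 1e-12, D / d, 0)
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X <- (B %*% X) / n
    s_new <- stress_of(X)
    if (abs(s_old - s_new) < tol * max(s_old, 1e-300)) {
      s_old <- s_new
      break
    }
    s_old <- s_new
  }
  list(X = X, stress = s_old)
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat("MDS embedding:", nrow(x$coords), "states in 2-D; stress",
      format(x$stress, digits = 4), "(best of", x$n_restarts,
      "restarts)\n")
  invisible(x)
}

#' Free energies of states from stationary populations
#'
#' \eqn{\Delta G_i = -kT \log(\pi_i / \max_j \pi_j)}: relative to the most
#' populated state, so the minimum is exactly 0, and invariant to
#' rescaling \eqn{\pi} by a constant.
#'
#' @param pi positive population vector (need not be normalized).
#' @param kT thermal energy unit (default 1, i.e. results in kT).
#' @return numeric vector of free energies.
#' @export
free_energies <- function(pi, kT = 1) {
  if (any(pi <= 0)) stop("zero or negative population has no free energy")
  -kT * log(pi / max(pi))
}

#' Flux network edges above a threshold
#'
#' @param flux flux matrix.
#' @param threshold minimum flux to keep an edge (>= 0).
#' @return data frame with columns \code{from}, \code{to}, \code{flux}
#'   (each undirected pair once, i < j, using the symmetrized flux).
#' @export
flux_network <- function(flux, threshold = 0) {
  stopifnot(threshold >= 0)
  Fs <- (flux + t(flux)) / 2
  iu <- which(upper.tri(Fs), arr.ind = TRUE)
  keep <- Fs[iu] >= threshold & Fs[iu] > 0
  data.frame(from = iu[keep, 1], to = iu[keep, 2], flux = Fs[iu][keep])
}
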