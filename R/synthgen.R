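## Synthetic-data generator: metastable hidden-Markov ground truth with
## known macrostate transition matrix, disjoint microstate emissions and
## Gaussian feature emissions, organized into seed groups (RUNs).

#' Build a reversible metastable generator model
#'
#' Constructs the ground-truth model every downstream stage is tested
#' against: a reversible macrostate transition matrix with prescribed slow
#' relaxation timescales, categorical macrostate-to-microstate emission
#' probabilities with disjoint support (so macrostates are identifiable),
#' and isotropic Gaussian feature emissions around microstate centers.
#'
#' The transition matrix is built by symmetrizing a random count-like
#' matrix (detailed balance by construction), then rescaling its non-unit
#' eigenvalues in the symmetrized basis so the implied timescales
#' \eqn{t_i = -\Delta t / \log \lambda_i} match \code{slow_timescales}
#' exactly. Draws that would produce negative transition probabilities are
#' rejected and retried with a fresh sub-seed.
#'
#' @param n_macro number of macrostates (>= 2).
#' @param n_micro number of microstates (>= n_macro).
#' @param slow_timescales length n_macro-1 vector of relaxation timescales,
#'   in the same time units as \code{step_time}; all must exceed
#'   \code{step_time}.
#' @param seed integer seed; the same seed always yields the same model.
#' @param n_feat feature-space dimensionality (default 2 * n_macro).
#' @param emission_sd isotropic Gaussian feature noise (default 0.25).
#' @param step_time time per Markov step (default 1).
#' @param metastability prior self-transition weight used for the base
#'   count matrix before eigenvalue rescaling (default 20).
#' @return an object of class \code{generator_model} with elements
#'   \code{macro_T}, \code{macro_pi}, \code{emission}, \code{micro_macro}
#'   (owning macrostate of each microstate), \code{micro_centers},
#'   \code{emission_sd}, \code{step_time}, \code{timescales},
#'   \code{micro_T} (the exact microstate-level transition matrix implied
#'   by the disjoint emissions) and \code{micro_pi}.
#' @export
make_generator <- function(n_macro, n_micro = 4L * n_macro, slow_timescales,
                           seed, n_feat = 2L * n_macro, emission_sd = 0.25,
                           step_time = 1, metastability = 20) {
  stopifnot(n_macro >= 2, n_micro >= n_macro, step_time > 0)
  slow_timescales <- sort(as.numeric(slow_timescales), decreasing = TRUE)
  if (length(slow_timescales) != n_macro - 1)
    stop("need exactly n_macro - 1 slow timescales")
  if (any(slow_timescales <= 0))
    stop("timescales must be positive")
  if (any(slow_timescales <= step_time))
    stop("timescales shorter than step_time are not realizable")

  target_ev <- exp(-step_time / slow_timescales)

  macro_T <- NULL
  for (attempt in seq_len(100)) {
    macro_T <- with_seed(child_seed(seed, attempt), {
      C <- matrix(runif(n_macro^2, 0.2, 1), n_macro, n_macro)
      C <- (C + t(C)) / 2 + diag(metastability, n_macro)
      T0 <- C / rowSums(C)
      pi0 <- rowSums(C) / sum(C)           # reversible by symmetry of C
      s <- sqrt(pi0)
      L <- (s * T0) / rep(s, each = n_macro) # diag(s) T0 diag(1/s), symmetric
      e <- eigen((L + t(L)) / 2, symmetric = TRUE)
      lam <- c(1, target_ev)
      Ls <- e$vectors %*% (lam * t(e$vectors))
      Tn <- (Ls / s) * rep(s, each = n_macro) # diag(1/s) Ls diag(s)
      Tn[abs(Tn) < 1e-14] <- pmax(Tn[abs(Tn) < 1e-14], 0)
      if (min(Tn) < 0) NULL else Tn / rowSums(Tn)
    })
    if (!is.null(macro_T)) break
  }
  if (is.null(macro_T)) {
    # deterministic fallback: hierarchical (Haar-like) eigenvector basis
    # with uniform stationary distribution; positive for any descending
    # eigenvalue ladder
    macro_T <- hierarchical_reversible_T(n_macro, target_ev)
    if (min(macro_T) < 0)
      stop("could not realize the requested timescales as a positive ",
           "transition matrix; try milder timescale ratios")
  }

  macro_pi <- stationary_distribution(macro_T)

  # Disjoint emission support: microstates partitioned round-robin across
  # macrostates, Dirichlet-like weights within each block.
  micro_macro <- rep(seq_len(n_macro), length.out = n_micro)
  micro_macro <- sort(micro_macro)
  em <- with_seed(child_seed(seed, 101), {
    emission <- matrix(0, n_macro, n_micro)
    for (m in seq_len(n_macro)) {
      idx <- which(micro_macro == m)
      w <- runif(length(idx), 0.5, 1.5)
      emission[m, idx] <- w / sum(w)
    }
    centers_macro <- matrix(rnorm(n_macro * n_feat, sd = 3), n_macro, n_feat)
    centers <- centers_macro[micro_macro, , drop = FALSE] +
      matrix(rnorm(n_micro * n_feat, sd = 0.6), n_micro, n_feat)
    list(emission = emission, centers = centers)
  })
  emission <- em$emission
  micro_centers <- em$centers

  micro_T <- macro_T[micro_macro, micro_macro] *
    rep(emission[cbind(micro_macro, seq_len(n_micro))], each = n_micro)
  micro_pi <- macro_pi[micro_macro] *
    emission[cbind(micro_macro, seq_len(n_micro))]

  structure(list(
    macro_T = macro_T, macro_pi = macro_pi, emission = emission,
    micro_macro = micro_macro, micro_centers = micro_centers,
    emission_sd = emission_sd, step_time = step_time,
    timescales = slow_timescales, micro_T = micro_T, micro_pi = micro_pi,
    n_macro = n_macro, n_micro = n_micro, n_feat = n_feat
  ), class = "generator_model")
}

#' @export
print.generator_model <- function(x, ...) {
  cat("Metastable generator model:", x$n_macro, "macrostates,",
      x$n_micro, "microstates,", x$n_feat, "features\n")
  cat("  slow timescales:", signif(x$timescales, 4),
      "(time units; step_time =", x$step_time, ")\n")
  cat("  stationary macro distribution:", signif(x$macro_pi, 3), "\n")
  invisible(x)
}

## Reversible transition matrix with uniform stationary distribution whose
## non-unit eigenvalues are exactly target_ev (descending): eigenvectors
## are a Haar-like hierarchical-bisection basis, so off-diagonal entries
## stay nonnegative for any descending ladder in (0, 1).
hierarchical_reversible_T <- function(n, target_ev) {
  V <- matrix(0, n, n - 1)
  queue <- list(seq_len(n))
  k <- 0
  while (length(queue)) {
    S <- queue[[1]]; queue <- queue[-1]
    if (length(S) < 2) next
    k <- k + 1
    A <- S[seq_len(ceiling(length(S) / 2))]
    B <- setdiff(S, A)
    V[A, k] <- sqrt(length(B) / (length(A) * length(S)))
    V[B, k] <- -sqrt(length(A) / (length(B) * length(S)))
    queue <- c(queue, list(A), list(B))
  }
  T <- matrix(1 / n, n, n)
  for (k in seq_len(n - 1))
    T <- T + target_ev[k] * tcrossprod(V[, k])
  T
}

#' Implied relaxation timescales of a transition matrix
#'
#' \eqn{t_i = -\tau / \log \lambda_i} for the non-unit eigenvalues, sorted
#' descending; eigenvalues \eqn{\le 0} yield \code{NA} (undefined, never
#' negative).
#'
#' @param T row-stochastic matrix.
#' @param lag lag time associated with one application of \code{T}.
#' @return numeric vector of length \code{nrow(T) - 1}.
#' @export
transition_timescales <- function(T, lag = 1) {
  ev <- eigen(T)$values
  ev <- Re(ev[abs(Im(ev)) < 1e-8])
  ev <- sort(ev, decreasing = TRUE)
  ev <- ev[-1]                         # drop the stationary eigenvalue
  vapply(ev, function(l)
    if (l > 0 && l < 1) -lag / log(l) else NA_real_, numeric(1))
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Left Perron eigenvector, normalized to sum 1.
#'
#' @param T row-stochastic matrix.
#' @return probability vector.
#' @export
stationary_distribution <- function(T) {
  e <- eigen(t(T))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

#' Sample a trajectory set from a generator model
#'
#' Draws \code{n_traj} hidden-Markov trajectories of \code{length} steps.
#' Macrostate paths start from the stationary distribution; microstates are
#' emitted per step from the model's categorical emissions and features from
#' isotropic Gaussians around the microstate centers. Trajectories are
#' assigned round-robin to \code{n_groups} seed groups (RUNs), the grouping
#' unit for shuffle-split cross-validation.
#'
#' @param model a \code{generator_model}.
#' @param n_traj number of trajectories.
#' @param length frames per trajectory (>= 2).
#' @param n_groups number of seed groups.
#' @param seed integer seed.
#' @param features if \code{FALSE}, skip Gaussian feature emission (label
#'   paths only); saves time when only discrete trajectories are needed.
#' @return an object of class \code{trajectory_set}: list with
#'   \code{features} (list of frames x n_feat matrices or NULL),
#'   \code{group_ids}, \code{true_macro_paths}, \code{true_micro_paths},
#'   \code{step_time}.
#' @export
sample_trajectories <- function(model, n_traj, length, n_groups = 2L, seed,
                                features = TRUE) {
  stopifnot(inherits(model, "generator_model"), length >= 2, n_traj >= 1)
  n_macro <- model$n_macro
  cumT <- t(apply(model$macro_T, 1, cumsum))

  out <- with_seed(child_seed(seed, 1), {
    # macro paths, vectorized across trajectories step by step
    macro <- matrix(0L, n_traj, length)
    macro[, 1] <- sample.int(n_macro, n_traj, replace = TRUE,
                             prob = model$macro_pi)
    for (t in 2:length) {
      u <- runif(n_traj)
      macro[, t] <- rowSums(u > cumT[macro[, t - 1L], , drop = FALSE]) + 1L
    }
    # micro emissions, vectorized per macrostate
    micro <- matrix(0L, n_traj, length)
    for (m in seq_len(n_macro)) {
      idx <- which(macro == m)
      if (length(idx))
        micro[idx] <- sample.int(model$n_micro, length(idx), replace = TRUE,
                                 prob = model$emission[m, ])
    }
    feats <- NULL
    if (features) {
      noise <- matrix(rnorm(n_traj * length * model$n_feat,
                            sd = model$emission_sd),
                      n_traj * length, model$n_feat)
      flat <- model$micro_centers[as.vector(t(micro)), , drop = FALSE] + noise
      feats <- lapply(seq_len(n_traj), function(i) {
        flat[((i - 1L) * length + 1L):(i * length), , drop = FALSE]
      })
    }
    list(macro = macro, micro = micro, feats = feats)
  })

  structure(list(
    features = out$feats,
    group_ids = rep(seq_len(n_groups), length.out = n_traj),
    true_macro_paths = lapply(seq_len(n_traj), function(i) out$macro[i, ]),
    true_micro_paths = lapply(seq_len(n_traj), function(i) out$micro[i, ]),
    step_time = model$step_time,
    n_micro = model$n_micro
  ), class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  n <- length(x$true_macro_paths)
  cat("Trajectory set:", n, "trajectories x",
      length(x$true_macro_paths[[1]]), "frames,",
      length(unique(x$group_ids)), "seed groups",
      if (is.null(x$features)) "(label paths only)" else
        paste0("(", ncol(x$features[[1]]), " features)"), "\n")
  invisible(x)
}
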