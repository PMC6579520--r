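## Microstate discretization and reversible Markov-state-model estimation.

#' k-means microstate discretization
#'
#' k-means++ seeding followed by Lloyd iterations until the relative
#' inertia change drops below 1e-6 or 500 iterations; a cluster that
#' empties is re-seeded from the point farthest from its assigned center.
#' Deterministic for a fixed seed.
#'
#' @param projected list of (frames x dims) matrices (e.g. tICA output), a
#'   \code{trajectory_set}, or a single matrix.
#' @param k number of microstates (<= total frames).
#' @param seed integer seed.
#' @param group_ids optional seed-group labels carried through.
#' @param frame_time time per frame (default 1).
#' @return object of class \code{discrete_trajectory_set}: \code{dtrajs}
#'   (list of integer sequences, states 1..k), \code{n_states},
#'   \code{centers}, \code{inertia}, \code{group_ids}, \code{frame_time}.
#' @export
discretize_kmeans <- function(projected, k, seed, group_ids = NULL,
                              frame_time = 1) {
  xs <- feature_matrices(projected)
  if (inherits(projected, "trajectory_set") && is.null(group_ids))
    group_ids <- projected$group_ids
  lens <- vapply(xs, nrow, integer(1))
  X <- do.call(rbind, xs)
  n <- nrow(X)
  stopifnot(k >= 1, k <= n)

  fit <- with_seed(child_seed(seed, 1), kmeans_lloyd(X, k))
  assign_split <- split(fit$assign, rep(seq_along(lens), lens))
  structure(list(dtrajs = unname(lapply(assign_split, as.integer)),
                 n_states = as.integer(k), centers = fit$centers,
                 inertia = fit$inertia, group_ids = group_ids,
                 frame_time = frame_time),
            class = "discrete_trajectory_set")
}

## squared distances from every row of X to every center (n x k)
dist2_to_centers <- function(X, C) {
  outer(rowSums(X^2), rep(1, nrow(C))) - 2 * X %*% t(C) +
    outer(rep(1, nrow(X)), rowSums(C^2))
}

kmeans_lloyd <- function(X, k, tol = 1e-6, max_iter = 500) {
  n <- nrow(X)
  # k-means++ seeding
  centers <- X[sample.int(n, 1), , drop = FALSE]
  if (k > 1) {
    d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
    for (j in 2:k) {
      pick <- if (sum(d2) > 0) sample.int(n, 1, prob = d2) else
        sample.int(n, 1)
      centers <- rbind(centers, X[pick, , drop = FALSE])
      d2 <- pmin(d2, rowSums(sweep(X, 2, X[pick, ])^2))
    }
  }
  inertia <- Inf
  assign <- integer(n)
  for (it in seq_len(max_iter)) {
    D2 <- dist2_to_centers(X, centers)
    assign <- max.col(-D2, ties.method = "first")
    new_inertia <- sum(D2[cbind(seq_len(n), assign)])
    for (j in seq_len(k)) {
      idx <- which(assign == j)
      if (length(idx)) {
        centers[j, ] <- colMeans(X[idx, , drop = FALSE])
      } else {
        # empty-cluster repair: reseed from the farthest point
        far <- which.max(D2[cbind(seq_len(n), assign)])
        centers[j, ] <- X[far, ]
        assign[far] <- j
      }
    }
    if (is.finite(inertia) &&
        abs(inertia - new_inertia) <= tol * max(inertia, 1e-300)) {
      inertia <- new_inertia
      break
    }
    inertia <- new_inertia
  }
  list(centers = centers, assign = assign, inertia = inertia)
}

#' Assign frames to existing microstate centers
#'
#' Nearest-center assignment, used to transform held-out trajectories with
#' a discretization fitted on training data.
#'
#' @param centers k x dims matrix of cluster centers.
#' @param projected features as in \code{\link{discretize_kmeans}}.
#' @param group_ids,frame_time carried through.
#' @return a \code{discrete_trajectory_set}.
#' @export
assign_microstates <- function(centers, projected, group_ids = NULL,
                               frame_time = 1) {
  xs <- feature_matrices(projected)
  if (inherits(projected, "trajectory_set") && is.null(group_ids))
    group_ids <- projected$group_ids
  dtrajs <- lapply(xs, function(X)
    max.col(-dist2_to_centers(X, centers), ties.method = "first"))
  structure(list(dtrajs = dtrajs, n_states = nrow(centers),
                 centers = centers, inertia = NA_real_,
                 group_ids = group_ids, frame_time = frame_time),
            class = "discrete_trajectory_set")
}

#' Wrap integer label sequences as a discrete trajectory set
#'
#' @param dtrajs list of integer vectors (states 1..n_states).
#' @param n_states total state count (default: max observed).
#' @param group_ids,frame_time optional metadata.
#' @return a \code{discrete_trajectory_set}.
#' @export
discrete_trajectories <- function(dtrajs, n_states = NULL, group_ids = NULL,
                                  frame_time = 1) {
  dtrajs <- lapply(dtrajs, as.integer)
  if (is.null(n_states)) n_states <- max(unlist(dtrajs))
  stopifnot(all(unlist(dtrajs) >= 1), all(unlist(dtrajs) <= n_states),
            all(vapply(dtrajs, length, integer(1)) >= 1))
  structure(list(dtrajs = dtrajs, n_states = as.integer(n_states),
                 centers = NULL, inertia = NA_real_, group_ids = group_ids,
                 frame_time = frame_time),
            class = "discrete_trajectory_set")
}

#' @export
print.discrete_trajectory_set <- function(x, ...) {
  cat("Discrete trajectories:", length(x$dtrajs), "sequences,",
      x$n_states, "states, frame time", x$frame_time, "\n")
  invisible(x)
}

#' Sliding-window transition count matrix
#'
#' \eqn{C_{ij} = \#\{t : s_t = i, s_{t+\mathrm{lag}} = j\}} summed over
#' trajectories; windows never span trajectory boundaries. Total counts
#' equal \eqn{\sum_{traj} (\mathrm{len} - \mathrm{lag})} over trajectories
#' longer than the lag.
#'
#' @param dtrajs a \code{discrete_trajectory_set} or list of integer
#'   vectors.
#' @param lag lag in frames (>= 1).
#' @param n_states state-space size (inferred when a set is passed).
#' @return n_states x n_states count matrix.
#' @export
count_matrix <- function(dtrajs, lag, n_states = NULL) {
  if (inherits(dtrajs, "discrete_trajectory_set")) {
    n_states <- dtrajs$n_states
    dtrajs <- dtrajs$dtrajs
  }
  if (is.null(n_states)) n_states <- max(unlist(dtrajs))
  stopifnot(lag >= 1)
  if (all(vapply(dtrajs, length, integer(1)) <= lag))
    stop("lag is not shorter than any trajectory")
  tab <- numeric(n_states^2)
  for (s in dtrajs) {
    L <- length(s)
    if (L <= lag) next
    i <- s[seq_len(L - lag)]
    j <- s[seq_len(L - lag) + lag]
    tab <- tab + tabulate((j - 1L) * n_states + i, nbins = n_states^2)
  }
  matrix(tab, n_states, n_states)
}

## Largest strongly connected component of the transition-count graph
## (edges where C_ij > 0), by Tarjan-free repeated forward/backward
## reachability. State counts here are small enough for this to be cheap.
largest_scc <- function(C) {
  n <- nrow(C)
  adj <- C > 0
  diag(adj) <- TRUE
  reach <- function(A, start) {
    vis <- logical(n); vis[start] <- TRUE
    frontier <- start
    while (length(frontier)) {
      nxt <- which(colSums(A[frontier, , drop = FALSE]) > 0 & !vis)
      vis[nxt] <- TRUE
      frontier <- nxt
    }
    vis
  }
  remaining <- rep(TRUE, n)
  best <- integer(0)
  while (any(remaining)) {
    v <- which(remaining)[1]
    fwd <- reach(adj & outer(remaining, remaining), v)
    bwd <- reach(t(adj) & outer(remaining, remaining), v)
    scc <- which(fwd & bwd & remaining)
    if (length(scc) > length(best)) best <- scc
    remaining[scc] <- FALSE
  }
  sort(best)
}

#' Reversible maximum-likelihood Markov state model
#'
#' Restricts the counts to their largest strongly connected component and,
#' for \code{reversible = TRUE}, runs the standard self-consistent
#' \eqn{x_{ij}} iteration for the detailed-balance-constrained maximum
#' likelihood: \eqn{x_{ij} \leftarrow (c_{ij}+c_{ji}) /
#' (c_i/x_i + c_j/x_j)}, converged when the largest \eqn{x_{ij}} change is
#' below \code{tol}. The stationary distribution is the fixed point's row
#' sums.
#'
#' @param counts square count matrix (nonnegative).
#' @param reversible enforce detailed balance (default \code{TRUE}).
#' @param lag lag time the counts were harvested at (metadata; default 1).
#' @param tol convergence tolerance on max |x_ij change| (default 1e-12).
#' @param max_sweeps iteration cap (default 1e6).
#' @return object of class \code{markov_model}: \code{T}, \code{pi},
#'   \code{counts}, \code{active_set} (original state indices),
#'   \code{lag}, \code{reversible}.
#' @export
estimate_msm <- function(counts, reversible = TRUE, lag = 1,
                         tol = 1e-12, max_sweeps = 1e6) {
  stopifnot(is.matrix(counts), nrow(counts) == ncol(counts),
            all(counts >= 0))
  active <- largest_scc(counts)
  if (!length(active)) stop("count matrix has no connected states")
  C <- counts[active, active, drop = FALSE]
  ci <- rowSums(C)

  if (!reversible) {
    T <- C / ci
    pi <- stationary_distribution(T)
  } else {
    S <- C + t(C)
    x <- S / sum(S)
    for (sweep in seq_len(max_sweeps)) {
      xi <- rowSums(x)
      xnew <- S / (outer(ci / xi, ci / xi, "+"))
      xnew <- xnew / sum(xnew)
      delta <- max(abs(xnew - x))
      x <- xnew
      if (delta < tol) break
    }
    pi <- rowSums(x)
    T <- x / pi
  }
  structure(list(T = T, pi = pi, counts = counts, active_set = active,
                 lag = lag, reversible = reversible),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat("Markov state model:", length(x$active_set), "active states, lag",
      x$lag, if (x$reversible) "(reversible MLE)" else "(nonreversible)",
      "\n")
  its <- transition_timescales(x$T, x$lag)
  k <- min(3, length(its))
  cat("  slowest implied timescales:", signif(its[seq_len(k)], 4), "\n")
  invisible(x)
}

#' Implied timescales across lag times
#'
#' For each lag, estimates an MSM and reports
#' \eqn{t_i = -\mathrm{lag}/\log\lambda_i} for the top non-unit
#' eigenvalues. Non-positive eigenvalues yield \code{NA} (undefined, never
#' negative).
#'
#' @param dtrajs a \code{discrete_trajectory_set} or list of integer
#'   vectors.
#' @param lags integer vector of lags (frames).
#' @param n_its number of timescales to report (default 5).
#' @param reversible passed to \code{\link{estimate_msm}}.
#' @return data frame with columns \code{lag}, \code{index},
#'   \code{timescale}.
#' @export
implied_timescales <- function(dtrajs, lags, n_its = 5, reversible = TRUE) {
  res <- lapply(lags, function(l) {
    m <- estimate_msm(count_matrix(dtrajs, l), reversible = reversible,
                      lag = l)
    its <- transition_timescales(m$T, l)
    k <- min(n_its, length(its))
    data.frame(lag = l, index = seq_len(k), timescale = its[seq_len(k)])
  })
  do.call(rbind, res)
}

#' Group-level 50:50 shuffle splits
#'
#' Randomly partitions seed groups (RUNs), never individual trajectories,
#' into train/test sets at the requested ratio; repeated \code{n_splits}
#' times. A fixed seed yields identical splits.
#'
#' @param groups group label per trajectory.
#' @param ratio train fraction of the groups (default 0.5).
#' @param n_splits number of splits (default 5).
#' @param seed integer seed.
#' @return list of \code{n_splits} lists with integer trajectory index
#'   vectors \code{train} and \code{test} plus the group partitions.
#' @export
shuffle_split <- function(groups, ratio = 0.5, n_splits = 5, seed = 1) {
  ug <- unique(groups)
  if (length(ug) < 2) stop("a single group cannot be split")
  n_train <- max(1, min(length(ug) - 1, round(length(ug) * ratio)))
  lapply(seq_len(n_splits), function(s) {
    tg <- with_seed(child_seed(seed, s), sample(ug, n_train))
    list(train = which(groups %in% tg),
         test = which(!groups %in% tg),
         train_groups = sort(tg),
         test_groups = sort(setdiff(ug, tg)))
  })
}
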