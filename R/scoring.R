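## Cross-validated VAMP-2 scoring and model validation: Chapman-Kolmogorov
## self-consistency and macrostate escape probabilities with Beta CIs.

## pi-orthonormal right eigenvectors of a reversible transition matrix,
## sorted by descending eigenvalue (stationary eigenfunction first).
reversible_eigs <- function(T, pi) {
  s <- sqrt(pi)
  L <- (s * T) / rep(s, each = length(pi))
  e <- eigen((L + t(L)) / 2, symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)
  list(values = e$values[ord],
       psi = e$vectors[, ord, drop = FALSE] / s)   # Psi' diag(pi) Psi = I
}

## Map test dtrajs onto a model's active set: states outside the active set
## are dropped frame-wise and trajectories split at the gaps. Returns the
## mapped segment list and the dropped-frame fraction.
map_to_active <- function(dtrajs, active_set) {
  if (inherits(dtrajs, "discrete_trajectory_set")) dtrajs <- dtrajs$dtrajs
  lookup <- rep(NA_integer_, max(active_set, unlist(dtrajs)))
  lookup[active_set] <- seq_along(active_set)
  total <- 0L; dropped <- 0L
  segs <- list()
  for (s in dtrajs) {
    m <- lookup[s]
    total <- total + length(m)
    dropped <- dropped + sum(is.na(m))
    ok <- !is.na(m)
    if (!any(ok)) next
    runs <- rle(ok)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in which(runs$values)) {
      if (runs$lengths[r] >= 2)
        segs[[length(segs) + 1L]] <- m[starts[r]:ends[r]]
    }
  }
  list(segments = segs, dropped_fraction = dropped / max(total, 1L))
}

#' Rank-capped VAMP-2 score
#'
#' In-sample (no test data) the score is \eqn{1 + \sum_{i=2}^{rank}
#' \lambda_i^2} of the model's transition matrix. Out-of-sample, test
#' correlation operators are assembled in the train model's top-rank
#' eigenfunction basis: a reversible MSM is estimated from the test counts
#' (restricted to the train active set, unseen states dropped frame-wise
#' with the dropped fraction attached), giving \eqn{C_{00} = C_{tt} =
#' \Psi^T \mathrm{diag}(\hat\pi) \Psi} and \eqn{C_{0t} = \Psi^T
#' \mathrm{diag}(\hat\pi) \hat T \Psi}; the score is the squared Frobenius
#' norm of \eqn{C_{00}^{-1/2} C_{0t} C_{tt}^{-1/2}}, capped at
#' \code{rank}. For test = train this reduces exactly to the in-sample
#' value.
#'
#' @param train_model a \code{markov_model}.
#' @param test_dtrajs optional test trajectories (a
#'   \code{discrete_trajectory_set} or list of integer vectors).
#' @param rank number of eigenfunctions scored (default 10).
#' @return numeric score in \[1, rank\]; for out-of-sample scores the
#'   dropped-state frame fraction is attached as attribute
#'   \code{"dropped_fraction"}.
#' @export
vamp2_score <- function(train_model, test_dtrajs = NULL, rank = 10) {
  lam <- reversible_eigs(train_model$T, train_model$pi)$values
  k <- min(rank, length(lam))
  if (is.null(test_dtrajs))
    return(sum(lam[seq_len(k)]^2))

  eg <- reversible_eigs(train_model$T, train_model$pi)
  Psi <- eg$psi[, seq_len(k), drop = FALSE]

  mp <- map_to_active(test_dtrajs, train_model$active_set)
  if (!length(mp$segments))
    stop("test set has no transitions mappable onto the train active set")
  Ctest <- count_matrix(mp$segments, train_model$lag,
                        n_states = length(train_model$active_set))
  mtest <- estimate_msm(Ctest, reversible = TRUE, lag = train_model$lag)
  sub <- mtest$active_set                 # indices into train active set
  PsiS <- Psi[sub, , drop = FALSE]
  D <- mtest$pi
  C00 <- crossprod(PsiS, PsiS * D)
  C0t <- crossprod(PsiS, (D * mtest$T) %*% PsiS)
  W <- sym_inv_sqrt(C00)
  K <- W %*% C0t %*% W
  score <- min(sum(K^2), rank)
  attr(score, "dropped_fraction") <- mp$dropped_fraction
  score
}

#' Chapman-Kolmogorov test
#'
#' Compares the set-persistence probabilities predicted by propagating the
#' lag-\eqn{\tau} model, \eqn{T(\tau)^k}, against models re-estimated at
#' lag \eqn{k\tau}, aggregated over metastable sets. Error bars are
#' count-based binomial standard errors of the re-estimated persistence.
#'
#' @param model a \code{markov_model} at the base lag.
#' @param dtrajs the discrete trajectories the model was (or is to be)
#'   validated on.
#' @param n_sets number of metastable sets; used when \code{sets} is
#'   \code{NULL}, in which case sets are the argmax partition of
#'   \code{\link{pcca_init}} memberships.
#' @param factors integer lag multipliers (>= 2 recommended; factor 1 is
#'   the trivial identity check).
#' @param sets optional explicit list of state-index vectors (indices into
#'   the model's active set ordering).
#' @return data frame with columns \code{set}, \code{factor},
#'   \code{predicted}, \code{estimated}, \code{se}, \code{within}; the
#'   overall pass flag (all |predicted - estimated| <= 1.96 se) is attached
#'   as attribute \code{"pass"}.
#' @export
ck_test <- function(model, dtrajs, n_sets = 2, factors = 2:5, sets = NULL) {
  stopifnot(all(factors >= 1))
  if (is.null(sets)) {
    memb <- pcca_init(model, n_sets)
    lab <- max.col(memb, ties.method = "first")
    sets <- split(seq_along(lab), lab)
  }
  n_active <- length(model$active_set)
  rows <- list()
  for (f in factors) {
    lag_f <- model$lag * f
    Cf <- count_matrix(map_to_active(dtrajs, model$active_set)$segments,
                       lag_f, n_states = n_active)
    if (sum(Cf) == 0) stop("insufficient counts at lag factor ", f)
    Tf_pred <- matrix_power(model$T, f)
    for (si in seq_along(sets)) {
      A <- sets[[si]]
      w <- model$pi[A] / sum(model$pi[A])
      pred <- sum(w * rowSums(Tf_pred[A, A, drop = FALSE]))
      nA <- sum(Cf[A, , drop = FALSE])
      est <- if (nA > 0) sum(Cf[A, A, drop = FALSE]) / nA else NA_real_
      # effective independent counts: sliding-window overlap corrected
      neff <- max(nA / lag_f, 1)
      se <- sqrt(max(est * (1 - est), 1e-12) / neff)
      rows[[length(rows) + 1L]] <- data.frame(
        set = si, factor = f, predicted = pred, estimated = est, se = se,
        within = is.finite(est) & abs(pred - est) <= 1.96 * se)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "pass") <- all(out$within)
  out
}

matrix_power <- function(M, k) {
  R <- diag(nrow(M))
  P <- M
  while (k > 0) {
    if (k %% 2 == 1) R <- R %*% P
    P <- P %*% P
    k <- k %/% 2
  }
  R
}

#' Macrostate escape probabilities with Beta confidence intervals
#'
#' For each macrostate and lag, the probability of remaining in the state,
#' \eqn{f = M/N}, is estimated from sliding-window self-transition counts
#' \eqn{M} and total counts \eqn{N}; the 95\% interval comes from
#' \eqn{\mathrm{Beta}(N_{eff} f, N_{eff}(1-f))} with \eqn{N_{eff} = N/\tau}
#' uncorrelated counts correcting the sliding-window overlap. With
#' \code{n_boot > 0} the procedure is bootstrapped over whole trajectories,
#' estimates are averaged, and the reported CI bounds are the 2.5th/97.5th
#' percentiles of the per-replicate CI bounds.
#'
#' @param macro_dtrajs macrostate label sequences (a
#'   \code{discrete_trajectory_set} or list of integer vectors).
#' @param lags integer vector of lags (frames).
#' @param n_boot bootstrap replicates (default 40; 0 disables).
#' @param seed integer seed for the bootstrap.
#' @param states states to report (default all).
#' @return data frame with columns \code{state}, \code{lag}, \code{M},
#'   \code{N}, \code{f}, \code{Neff}, \code{ci_low}, \code{ci_high}.
#' @export
escape_probability <- function(macro_dtrajs, lags, n_boot = 40, seed = 1,
                               states = NULL) {
  if (inherits(macro_dtrajs, "discrete_trajectory_set"))
    macro_dtrajs <- macro_dtrajs$dtrajs
  n_states <- max(unlist(macro_dtrajs))
  if (is.null(states)) states <- seq_len(n_states)

  one_estimate <- function(dtrajs, lag) {
    C <- count_matrix(dtrajs, lag, n_states = n_states)
    M <- diag(C)
    N <- rowSums(C)
    f <- ifelse(N > 0, M / N, NA_real_)
    neff <- N / lag
    ci <- t(vapply(seq_len(n_states), function(i) {
      if (N[i] == 0) return(c(NA_real_, NA_real_))
      a <- neff[i] * f[i]; b <- neff[i] * (1 - f[i])
      if (b <= 0) return(c(1, 1))
      if (a <= 0) return(c(0, 0))
      qbeta(c(0.025, 0.975), a, b)
    }, numeric(2)))
    data.frame(state = seq_len(n_states), M = M, N = N, f = f, Neff = neff,
               ci_low = ci[, 1], ci_high = ci[, 2])
  }

  rows <- list()
  for (lag in lags) {
    if (n_boot == 0) {
      est <- one_estimate(macro_dtrajs, lag)
      est$lag <- lag
      rows[[length(rows) + 1L]] <- est[est$state %in% states, ]
    } else {
      reps <- lapply(seq_len(n_boot), function(b) {
        idx <- with_seed(child_seed(seed, 1000 * lag + b),
                         sample.int(length(macro_dtrajs),
                                    length(macro_dtrajs), replace = TRUE))
        one_estimate(macro_dtrajs[idx], lag)
      })
      for (st in states) {
        g <- do.call(rbind, lapply(reps, function(r) r[r$state == st, ]))
        rows[[length(rows) + 1L]] <- data.frame(
          state = st, lag = lag,
          M = mean(g$M), N = mean(g$N),
          f = mean(g$f, na.rm = TRUE), Neff = mean(g$Neff),
          ci_low = quantile(g$ci_low, 0.025, na.rm = TRUE, names = FALSE),
          ci_high = quantile(g$ci_high, 0.975, na.rm = TRUE, names = FALSE))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("state", "lag", "M", "N", "f", "Neff", "ci_low", "ci_high")]
}

#' Cross-validated hyperparameter search
#'
#' Runs the full pipeline -- tICA projection, k-means discretization, MSM
#' estimation on the training groups, rank-capped VAMP-2 scoring on the
#' held-out groups -- for every grid point over the same group shuffle
#' splits, and returns mean and sd scores ranked best-first. Individual
#' grid-point failures are recorded (NA score) and skipped, not fatal.
#'
#' @param dataset a \code{trajectory_set} with features and group ids.
#' @param grid list of configurations; each a list with elements
#'   \code{tica_lag}, \code{mapping} ("commute"/"kinetic"), \code{k}
#'   (microstates), \code{msm_lag}, and optionally \code{kinetic_content}
#'   (default 0.95).
#' @param seed integer seed controlling splits and k-means.
#' @param n_splits shuffle splits (default 5).
#' @param ratio train group fraction (default 0.5).
#' @param rank VAMP-2 rank (default 10).
#' @return data frame with one row per grid point: the configuration
#'   columns, \code{mean_score}, \code{sd_score}, \code{error} (message or
#'   NA), ranked by decreasing mean score.
#' @export
hyperparameter_search <- function(dataset, grid, seed, n_splits = 5,
                                  ratio = 0.5, rank = 10) {
  stopifnot(length(grid) >= 1)
  splits <- shuffle_split(dataset$group_ids, ratio = ratio,
                          n_splits = n_splits, seed = child_seed(seed, 1))
  rows <- lapply(seq_along(grid), function(gi) {
    cfg <- grid[[gi]]
    kc <- cfg$kinetic_content %||% 0.95
    scores <- rep(NA_real_, length(splits))
    err <- NA_character_
    for (si in seq_along(splits)) {
      sp <- splits[[si]]
      res <- tryCatch({
        tica <- fit_tica(dataset$features[sp$train], lag = cfg$tica_lag,
                         mapping = cfg$mapping)
        proj_train <- tica_transform(tica, dataset$features[sp$train],
                                     kinetic_content = kc)
        proj_test <- tica_transform(tica, dataset$features[sp$test],
                                    kinetic_content = kc)
        dtr_train <- discretize_kmeans(proj_train, k = cfg$k,
                                       seed = child_seed(seed, 100 + si))
        dtr_test <- assign_microstates(dtr_train$centers, proj_test)
        m <- estimate_msm(count_matrix(dtr_train, cfg$msm_lag),
                          lag = cfg$msm_lag)
        as.numeric(vamp2_score(m, dtr_test, rank = rank))
      }, error = function(e) conditionMessage(e))
      if (is.character(res)) err <- res else scores[si] <- res
    }
    data.frame(grid_point = gi, tica_lag = cfg$tica_lag,
               mapping = cfg$mapping, k = cfg$k, msm_lag = cfg$msm_lag,
               kinetic_content = kc,
               mean_score = if (all(is.na(scores))) NA_real_ else
                 mean(scores, na.rm = TRUE),
               sd_score = sd(scores[!is.na(scores)]),
               error = err, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$mean_score, decreasing = TRUE, na.last = TRUE), ]
}
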