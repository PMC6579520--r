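## Two-step (induced-fit) ligand-binding kinetics: trace simulation,
## global and conventional fits, dilution fits, and equilibrium constants
## with error propagation.
##
## Model (two-step, induced fit):   E + S <=> ES <=> E'S
##   d[E]/dt   = -k1 [S][E] + k_1 [ES]
##   d[ES]/dt  =  k1 [S][E] - (k_1 + k2)[ES] + k_2 [E'S]
##   d[E'S]/dt =  k2 [ES] - k_2 [E'S]
## Observable: F = a [E] + b [ES] + c [E'S] + bkg.
## Alternative (conformational selection): E <=> E',  E' + S <=> E'S.

#' Two-step binding rate constants
#'
#' @param k1 association rate of the first step (uM^-1 s^-1).
#' @param k_1 dissociation rate of the first step (s^-1).
#' @param k2,k_2 forward/backward isomerization rates (s^-1).
#' @return list of class \code{two_step_rates}.
#' @export
two_step_rates <- function(k1, k_1, k2, k_2) {
  stopifnot(k1 >= 0, k_1 >= 0, k2 >= 0, k_2 >= 0)
  structure(list(k1 = k1, k_1 = k_1, k2 = k2, k_2 = k_2),
            class = "two_step_rates")
}

#' Fluorescence observable coefficients
#'
#' \eqn{F = a[E] + b[ES] + c[E'S] + bkg} (for the conformational-selection
#' model the species are E, E', E'S).
#'
#' @param a,b,c fluorescence coefficients per species (a.u. per uM).
#' @param bkg background intensity (a.u.).
#' @return list of class \code{observable_model}.
#' @export
observable_model <- function(a, b, c, bkg = 0) {
  stopifnot(is.finite(a), is.finite(b), is.finite(c), is.finite(bkg))
  structure(list(a = a, b = b, c = c, bkg = bkg),
            class = "observable_model")
}

## Rate matrix (columns sum to zero) of the pseudo-first-order linear
## system dy/dt = A y for the given model at ligand concentration S.
kinetic_rate_matrix <- function(model, rates, S) {
  if (model == "two_step") {
    with(rates, matrix(c(
      -k1 * S,        k_1,            0,
       k1 * S,       -(k_1 + k2),     k_2,
       0,             k2,            -k_2), 3, 3, byrow = TRUE))
  } else {  # conformational selection: rates k_f, k_b, k_on, k_off
    with(rates, matrix(c(
      -k_f,           k_b,            0,
       k_f,          -(k_b + k_on * S), k_off,
       0,             k_on * S,      -k_off), 3, 3, byrow = TRUE))
  }
}

## Species concentrations over t_grid. Pseudo-first-order regime
## ([S] >= 10x enzyme): exact solution by eigen-decomposition of the 3x3
## rate matrix (chain topology -> real spectrum). Otherwise the full
## bimolecular system with ligand depletion is integrated stiff-safe
## (lsoda, atol 1e-12).
simulate_species <- function(rates, S, E_tot, t_grid,
                             model = c("two_step",
                                       "conformational_selection")) {
  model <- match.arg(model)
  y0 <- if (model == "two_step") c(E_tot, 0, 0) else {
    pE <- rates$k_b / (rates$k_f + rates$k_b)   # pre-equilibrated apo enzyme
    c(E_tot * pE, E_tot * (1 - pE), 0)
  }
  if (S >= 10 * E_tot || model == "conformational_selection") {
    A <- kinetic_rate_matrix(model, rates, S)
    e <- eigen(A)
    co <- solve(e$vectors, y0)
    Y <- Re(t(e$vectors %*% (co * exp(outer(e$values, t_grid)))))
  } else {
    deriv <- function(t, y, p) {
      E <- y[1]; ES <- y[2]; EpS <- y[3]; Sfree <- y[4]
      v1 <- rates$k1 * Sfree * E - rates$k_1 * ES
      v2 <- rates$k2 * ES - rates$k_2 * EpS
      list(c(-v1, v1 - v2, v2, -v1))
    }
    sol <- deSolve::lsoda(c(y0, S), t_grid, deriv, NULL,
                          atol = 1e-12, rtol = 1e-10)
    Y <- unname(sol[, 2:4, drop = FALSE])
  }
  colnames(Y) <- if (model == "two_step") c("E", "ES", "EpS") else
    c("E", "Ep", "EpS")
  Y
}

#' Simulate a stopped-flow dataset
#'
#' Integrates the two-step (or conformational-selection) scheme for each
#' ligand concentration and returns noisy fluorescence traces
#' \eqn{F = a[E] + b[ES] + c[E'S] + bkg}. Species trajectories conserve
#' total enzyme exactly.
#'
#' @param rates a \code{two_step_rates} (or, for the alternative model, a
#'   list with \code{k_f}, \code{k_b}, \code{k_on}, \code{k_off}).
#' @param observable an \code{observable_model}.
#' @param concentrations ligand concentrations (uM); a warning is issued
#'   outside the pseudo-first-order regime.
#' @param t_grid time points (s), starting at 0.
#' @param noise_sd Gaussian noise sd (a.u.; default 0).
#' @param seed integer seed for the noise.
#' @param enzyme_conc total enzyme (uM, default 1).
#' @param model kinetic scheme (default two-step).
#' @return object of class \code{stopped_flow_dataset}: \code{traces}
#'   (list of data frames time/intensity, one per concentration),
#'   \code{concentrations}, \code{enzyme_conc}, plus the true species
#'   matrices in \code{species}.
#' @export
simulate_traces <- function(rates, observable, concentrations, t_grid,
                            noise_sd = 0, seed = 1, enzyme_conc = 1,
                            model = c("two_step",
                                      "conformational_selection")) {
  model <- match.arg(model)
  stopifnot(all(concentrations > 0), t_grid[1] == 0,
            all(diff(t_grid) > 0))
  if (any(concentrations < 10 * enzyme_conc))
    warning("some concentrations are outside the pseudo-first-order ",
            "regime ([S] < 10x enzyme); ligand depletion is integrated ",
            "explicitly there")
  traces <- vector("list", length(concentrations))
  species <- vector("list", length(concentrations))
  for (ci in seq_along(concentrations)) {
    Y <- simulate_species(rates, concentrations[ci], enzyme_conc, t_grid,
                          model)
    f <- Y %*% c(observable$a, observable$b, observable$c) + observable$bkg
    if (noise_sd > 0)
      f <- f + with_seed(child_seed(seed, ci),
                         rnorm(length(f), sd = noise_sd))
    traces[[ci]] <- data.frame(time = t_grid, intensity = as.numeric(f))
    species[[ci]] <- Y
  }
  structure(list(traces = traces, concentrations = concentrations,
                 enzyme_conc = enzyme_conc, species = species,
                 model = model),
            class = "stopped_flow_dataset")
}

#' @export
print.stopped_flow_dataset <- function(x, ...) {
  cat("Stopped-flow dataset:", length(x$traces), "traces,",
      nrow(x$traces[[1]]), "points each; [S] =",
      paste(x$concentrations, collapse = ", "), "uM;",
      x$enzyme_conc, "uM enzyme\n")
  invisible(x)
}

## Per-model fluorescence design matrix. For the two-step scheme each
## species has its own coefficient. In the conformational-selection scheme
## the two unbound conformers E and E' hold the fluorophore in the same
## (ligand-free) environment, so they share a single coefficient -- the
## physical constraint that lets the data discriminate the two schemes.
fluor_design <- function(Y, model) {
  if (model == "two_step") cbind(Y, 1) else
    cbind(Y[, 1] + Y[, 2], Y[, 3], 1)
}

## Residuals of all traces for given rates, with the linear fluorescence
## coefficients profiled out by least squares.
profiled_residuals <- function(rate_vec, dataset, model, t_mask) {
  rates <- if (model == "two_step")
    list(k1 = rate_vec[1], k_1 = rate_vec[2], k2 = rate_vec[3],
         k_2 = rate_vec[4])
  else
    list(k_f = rate_vec[1], k_b = rate_vec[2], k_on = rate_vec[3],
         k_off = rate_vec[4])
  G <- NULL; y <- NULL
  for (ci in seq_along(dataset$traces)) {
    tr <- dataset$traces[[ci]]
    keep <- t_mask[[ci]]
    Y <- simulate_species(rates, dataset$concentrations[ci],
                          dataset$enzyme_conc, tr$time[keep], model)
    G <- rbind(G, fluor_design(Y, model))
    y <- c(y, tr$intensity[keep])
  }
  beta <- qr.coef(qr(G), y)
  beta[is.na(beta)] <- 0
  list(resid = y - G %*% beta, beta = beta)
}

#' Global fit of stopped-flow traces
#'
#' Simultaneously fits all concentration traces to the two-step
#' (induced-fit) or conformational-selection scheme by
#' Levenberg-Marquardt nonlinear least squares on the four rate
#' constants, with the shared fluorescence coefficients (a, b, c, bkg)
#' profiled out linearly at every step (variable projection). In the
#' conformational-selection scheme the two unbound conformers E and E'
#' share one fluorescence coefficient (the fluorophore environment without
#' ligand is the same), which is what gives the data power to discriminate
#' the schemes. Restarted
#' from \code{n_starts} log-uniform draws within the bounds; the best fit
#' is kept. Asymptotic standard errors come from the Jacobian of the full
#' (rates + coefficients) residual at the optimum.
#'
#' @param dataset a \code{stopped_flow_dataset} (>= 2 concentrations).
#' @param model \code{"two_step"} (default) or
#'   \code{"conformational_selection"}.
#' @param init optional numeric length-4 vector of starting rates (first
#'   start).
#' @param lower,upper rate bounds (default 1e-4 and 1e4).
#' @param n_starts multi-start draws (default 20).
#' @param seed integer seed for the starts.
#' @param dead_time instrument dead time (s): points earlier than this are
#'   excluded from the fit (default 0.005).
#' @return object of class \code{kinetic_fit}: \code{rates} (named),
#'   \code{observable}, \code{se} (rate standard errors),
#'   \code{covariance} (4x4, rates), \code{residual_norm} (sqrt of the sum
#'   of squared residuals), \code{model}, \code{at_bound},
#'   \code{converged}, \code{n_obs}.
#'
#'   Note that under pseudo-first-order conditions the species sum to the
#'   constant total enzyme, so the background is not separately
#'   identifiable from the species coefficients: the profiled solution
#'   reports \code{bkg = 0} with the background absorbed into a, b, c
#'   (differences such as a - c are identified; the rates are
#'   unaffected).
#' @export
global_fit <- function(dataset, model = c("two_step",
                                          "conformational_selection"),
                       init = NULL, lower = rep(1e-4, 4),
                       upper = rep(1e4, 4), n_starts = 20, seed = 1,
                       dead_time = 0.005) {
  model <- match.arg(model)
  stopifnot(length(dataset$traces) >= 2)
  t_mask <- lapply(dataset$traces, function(tr) tr$time >= dead_time)

  obj <- function(logp) profiled_residuals(exp(logp), dataset, model,
                                           t_mask)$resid
  starts <- with_seed(child_seed(seed, 1), {
    lapply(seq_len(n_starts), function(i)
      runif(4, log(lower), log(upper)))
  })
  # data-driven start from biphasic pre-fits of the extreme concentrations
  heur <- tryCatch(heuristic_rates(dataset, model, dead_time), error =
                     function(e) rep(1, 4))
  starts <- c(list(log(pmin(pmax(heur, lower), upper))), starts)
  if (!is.null(init)) starts[[1]] <- log(pmin(pmax(init, lower), upper))

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = obj, lower = log(lower),
                         upper = log(upper),
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("global fit failed to converge from any start")

  rates_hat <- exp(best$fit$par)
  pr <- profiled_residuals(rates_hat, dataset, model, t_mask)
  n_obs <- length(pr$resid)

  # standard errors from the full 8-parameter Jacobian in natural units
  full_resid <- function(theta) {
    rates <- if (model == "two_step")
      list(k1 = theta[1], k_1 = theta[2], k2 = theta[3], k_2 = theta[4])
    else
      list(k_f = theta[1], k_b = theta[2], k_on = theta[3],
           k_off = theta[4])
    r <- NULL
    for (ci in seq_along(dataset$traces)) {
      tr <- dataset$traces[[ci]]
      keep <- t_mask[[ci]]
      Y <- simulate_species(rates, dataset$concentrations[ci],
                            dataset$enzyme_conc, tr$time[keep], model)
      f <- fluor_design(Y, model) %*% theta[-(1:4)]
      r <- c(r, tr$intensity[keep] - f)
    }
    r
  }
  theta_hat <- c(rates_hat, pr$beta)
  J <- numeric_jacobian(full_resid, theta_hat)
  dof <- max(n_obs - length(theta_hat), 1)
  sigma2 <- best$rss / dof
  JtJ <- crossprod(J)
  cov_full <- tryCatch(sigma2 * solve(JtJ), error = function(e)
    sigma2 * pseudo_inverse(JtJ))
  se_full <- sqrt(pmax(diag(cov_full), 0))

  rate_names <- if (model == "two_step") c("k1", "k_1", "k2", "k_2") else
    c("k_f", "k_b", "k_on", "k_off")
  at_bound <- rates_hat <= lower * (1 + 1e-6) |
    rates_hat >= upper * (1 - 1e-6)
  if (any(at_bound))
    warning("fitted parameter at a bound: ",
            paste(rate_names[at_bound], collapse = ", "))
  obs_fit <- if (model == "two_step")
    observable_model(pr$beta[1], pr$beta[2], pr$beta[3], pr$beta[4])
  else                      # shared unbound-conformer coefficient
    observable_model(pr$beta[1], pr$beta[1], pr$beta[2], pr$beta[3])
  structure(list(
    rates = stats::setNames(as.list(rates_hat), rate_names),
    observable = obs_fit,
    se = stats::setNames(se_full[1:4], rate_names),
    covariance = cov_full[1:4, 1:4, drop = FALSE],
    residual_norm = sqrt(best$rss), model = model,
    at_bound = at_bound, converged = best$fit$info %in% 1:4,
    n_obs = n_obs
  ), class = "kinetic_fit")
}

## Starting rates from conventional biphasic pre-fits of every trace: the
## fast observed rate is linear in [S] (slope = association rate,
## intercept = sum of the other three rates), and the S-independent part
## of the slow rate seeds the isomerization pair.
heuristic_rates <- function(dataset, model, dead_time) {
  pre <- lapply(dataset$traces, function(tr)
    tryCatch(double_exp_fit(tr, n_starts = 4, seed = 1,
                            dead_time = dead_time),
             error = function(e) NULL))
  # discard prefits whose fast rate exceeds what the sampling resolves
  dt <- stats::median(diff(dataset$traces[[1]]$time))
  ok <- vapply(pre, function(p)
    !is.null(p) && p$kobs_fast < 2 / dt, logical(1))
  S <- dataset$concentrations[ok]
  kf <- vapply(pre[ok], `[[`, numeric(1), "kobs_fast")
  ks <- vapply(pre[ok], `[[`, numeric(1), "kobs_slow")
  if (length(S) < 2) stop("too few pre-fittable traces")
  line <- stats::coef(stats::lm(kf ~ S))
  slope <- max(line[2], 1e-4)
  intercept <- max(line[1], 1e-3)
  plateau <- max(min(stats::median(ks), intercept * 0.9), 1e-3)
  if (model == "two_step")
    c(slope, max(intercept - plateau, intercept / 2), plateau / 2,
      plateau / 2)
  else
    c(plateau / 2, plateau / 2, slope, intercept / 2)
}

numeric_jacobian <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(abs(x[j]), 1e-8)
    xp <- x; xp[j] <- xp[j] + h
    J[, j] <- (f(xp) - f0) / h
  }
  J
}

## Moore-Penrose fallback for a singular normal matrix.
pseudo_inverse <- function(X, tol = 1e-12) {
  s <- svd(X)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*% ((1 / s$d[keep]) *
                                   t(s$u[, keep, drop = FALSE]))
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("Global", x$model, "fit over", length(x$se), "rate constants,",
      x$n_obs, "points\n")
  for (nm in names(x$rates))
    cat(sprintf("  %-6s = %10.4g +/- %.3g\n", nm, x$rates[[nm]],
                x$se[[nm]]))
  cat("  residual norm:", format(x$residual_norm, digits = 5), "\n")
  invisible(x)
}

#' Conventional double-exponential fit of one trace
#'
#' Fits \eqn{F = A_1 e^{-k_{obs}^{fast} t} + A_2 e^{-k_{obs}^{slow} t} + C}
#' with \eqn{k_{obs}^{fast} \ge k_{obs}^{slow} > 0} enforced by a sorted
#' reparameterization (the fast rate is the slow rate plus a positive
#' increment).
#'
#' @param trace data frame with \code{time} and \code{intensity} (>= 6
#'   points).
#' @param n_starts multi-start draws (default 10).
#' @param seed integer seed.
#' @param dead_time trace truncation (s, default 0.005).
#' @return object of class \code{double_exp_fit}: \code{A1}, \code{A2},
#'   \code{kobs_fast}, \code{kobs_slow}, \code{C}, \code{residual_norm},
#'   \code{degenerate} (amplitude ratio < 1e-3).
#' @export
double_exp_fit <- function(trace, n_starts = 10, seed = 1,
                           dead_time = 0.005) {
  tr <- trace[trace$time >= dead_time, ]
  stopifnot(nrow(tr) >= 6)
  t <- tr$time; y <- tr$intensity
  span <- max(t) - min(t)

  resid <- function(p) {
    ks <- exp(p[1]); kf <- ks + exp(p[2])
    G <- cbind(exp(-kf * t), exp(-ks * t), 1)
    beta <- qr.coef(qr(G), y)
    beta[is.na(beta)] <- 0
    y - G %*% beta
  }
  # deterministic log-spaced grid over the decades the window resolves,
  # plus optional random extras
  grid <- expand.grid(ks = c(0.2, 1, 5, 25) / span,
                      inc = c(2, 20, 200) / span)
  starts <- lapply(seq_len(nrow(grid)),
                   function(i) log(as.numeric(grid[i, ])))
  if (n_starts > 0)
    starts <- c(starts, with_seed(child_seed(seed, 1),
      lapply(seq_len(n_starts), function(i)
        log(exp(runif(2, log(c(0.1, 1) / span), log(c(50, 500) / span)))))))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(minpack.lm::nls.lm(
      par = st, fn = resid,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                           ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("double-exponential fit failed")
  ks <- exp(best$fit$par[1]); kf <- ks + exp(best$fit$par[2])
  G <- cbind(exp(-kf * t), exp(-ks * t), 1)
  beta <- qr.coef(qr(G), y)
  amp <- abs(beta[1:2])
  structure(list(A1 = beta[1], A2 = beta[2], kobs_fast = kf,
                 kobs_slow = ks, C = beta[3],
                 residual_norm = sqrt(best$rss),
                 degenerate = min(amp) / max(amp) < 1e-3),
            class = "double_exp_fit")
}

#' Observed-rate predictions of the two-step model
#'
#' \eqn{k_{obs}^{fast} = k_1 [S] + k_{-1} + k_2 + k_{-2}} and
#' \eqn{k_{obs}^{slow} \approx k_1[S] + (k_{-2} + k_2) + k_{-1} k_{-2} /
#' (k_1 [S] + k_{-1} + k_2 + k_{-2})} as printed for the biphasic decay,
#' with the S-independent plateau constant \eqn{k_{-2} + k_2} exposed
#' alongside the full expression.
#'
#' @param rates a \code{two_step_rates}.
#' @param S ligand concentration (uM, >= 0).
#' @return list with \code{kobs_fast}, \code{kobs_slow}, \code{plateau}.
#' @export
kobs_predictions <- function(rates, S) {
  stopifnot(all(S >= 0))
  with(rates, {
    fast <- k1 * S + k_1 + k2 + k_2
    slow <- k1 * S + (k_2 + k2) + k_1 * k_2 / fast
    list(kobs_fast = fast, kobs_slow = slow, plateau = k_2 + k2)
  })
}

#' Dissociation-rate estimate from a dilution trace
#'
#' Fits \eqn{F = A_1 e^{-k_{-1} t} + C} to a dissociation-dominated
#' dilution trace; with several traces the per-trace estimates are
#' averaged. A flat (non-decaying) trace raises an error.
#'
#' @param traces one data frame (time/intensity) or a list of them.
#' @param dead_time truncation (s, default 0.005).
#' @return list with \code{k_1} (mean), \code{per_trace} estimates.
#' @export
dilution_fit <- function(traces, dead_time = 0.005) {
  if (is.data.frame(traces)) traces <- list(traces)
  ks <- vapply(traces, function(trace) {
    tr <- trace[trace$time >= dead_time, ]
    t <- tr$time; y <- tr$intensity
    if (sd(y) < 1e-12 * max(abs(y), 1))
      stop("flat trace: no decay to fit")
    resid <- function(p) {
      G <- cbind(exp(-exp(p) * t), 1)
      beta <- qr.coef(qr(G), y)
      beta[is.na(beta)] <- 0
      y - G %*% beta
    }
    span <- max(t) - min(t)
    fit <- minpack.lm::nls.lm(par = log(2 / span), fn = resid,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 200, ftol = 1e-15, ptol = 1e-15))
    k <- exp(fit$par)
    G <- cbind(exp(-k * t), 1)
    beta <- qr.coef(qr(G), y)
    if (!is.finite(beta[1]) || abs(beta[1]) < 1e-9 * max(abs(y), 1))
      stop("non-decaying trace")
    k
  }, numeric(1))
  list(k_1 = mean(ks), per_trace = ks)
}

#' Equilibrium constants of the two-step model with error propagation
#'
#' \eqn{K_{d1} = k_{-1}/k_1}, \eqn{K_{eq} = k_{-2}/k_2},
#' \eqn{K_d = K_{d1} K_{eq}/(1 + K_{eq})} (always below \eqn{K_{d1}});
#' standard errors by first-order (delta-method) propagation through the
#' rate covariance. The binding free energy is reported in kT units for
#' \eqn{K_d} converted to molar.
#'
#' @param rates a \code{two_step_rates} (k1 in uM^-1 s^-1, others s^-1)
#'   or a fitted \code{kinetic_fit}.
#' @param covariance 4x4 covariance of (k1, k_1, k2, k_2); defaults to the
#'   fit's covariance or zero.
#' @return list of class \code{equilibrium_constants}: \code{Kd1},
#'   \code{Keq}, \code{Kd} (uM), \code{se_Kd1}, \code{se_Keq},
#'   \code{se_Kd}, \code{dG_kT}.
#' @export
equilibrium_constants <- function(rates, covariance = NULL) {
  if (inherits(rates, "kinetic_fit")) {
    if (is.null(covariance)) covariance <- rates$covariance
    rates <- do.call(two_step_rates, rates$rates)
  }
  if (is.null(covariance)) covariance <- matrix(0, 4, 4)
  with(rates, {
    if (k1 <= 0 || k2 <= 0) stop("zero denominator rate constant")
    Kd1 <- k_1 / k1
    Keq <- k_2 / k2
    g <- Keq / (1 + Keq)
    Kd <- Kd1 * g
    # gradients w.r.t. (k1, k_1, k2, k_2)
    grad_Kd1 <- c(-k_1 / k1^2, 1 / k1, 0, 0)
    grad_Keq <- c(0, 0, -k_2 / k2^2, 1 / k2)
    dKd_dKeq <- Kd1 / (1 + Keq)^2
    grad_Kd <- g * grad_Kd1 + dKd_dKeq * grad_Keq
    se_of <- function(gr) sqrt(max(gr %*% covariance %*% gr, 0))
    structure(list(Kd1 = Kd1, Keq = Keq, Kd = Kd,
                   se_Kd1 = se_of(grad_Kd1), se_Keq = se_of(grad_Keq),
                   se_Kd = se_of(grad_Kd),
                   dG_kT = log(Kd * 1e-6)),
              class = "equilibrium_constants")
  })
}

#' @export
print.equilibrium_constants <- function(x, ...) {
  cat(sprintf("Kd1 = %.4g +/- %.2g uM;  Keq = %.4g +/- %.2g;  ",
              x$Kd1, x$se_Kd1, x$Keq, x$se_Keq))
  cat(sprintf("Kd = %.4g +/- %.2g uM (dG = %.2f kT)\n",
              x$Kd, x$se_Kd, x$dG_kT))
  invisible(x)
}

#' Write a stopped-flow dataset to CSV
#'
#' Long format with columns \code{time_s}, \code{intensity},
#' \code{concentration_uM}.
#'
#' @param dataset a \code{stopped_flow_dataset}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_traces_csv <- function(dataset, path) {
  rows <- do.call(rbind, lapply(seq_along(dataset$traces), function(ci)
    data.frame(time_s = dataset$traces[[ci]]$time,
               intensity = dataset$traces[[ci]]$intensity,
               concentration_uM = dataset$concentrations[ci])))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read a stopped-flow dataset from CSV
#'
#' @param path CSV written by \code{\link{write_traces_csv}}.
#' @param enzyme_conc total enzyme concentration (uM, default 1).
#' @return a \code{stopped_flow_dataset}.
#' @export
read_traces_csv <- function(path, enzyme_conc = 1) {
  d <- utils::read.csv(path)
  concs <- sort(unique(d$concentration_uM))
  traces <- lapply(concs, function(cc) {
    g <- d[d$concentration_uM == cc, ]
    data.frame(time = g$time_s, intensity = g$intensity)
  })
  structure(list(traces = traces, concentrations = concs,
                 enzyme_conc = enzyme_conc, species = NULL,
                 model = "unknown"),
            class = "stopped_flow_dataset")
}
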