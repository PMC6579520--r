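test_that("in-sample VAMP-2 equals 1 + sum of squared eigenvalues and the
           out-of-sample estimator reduces to it for test = train", {
  d <- fixture_dtrajs(n_traj = 10, length = 1000)
  m <- estimate_msm(count_matrix(d, 1), lag = 1)
  lam <- sort(Re(eigen(m$T)$values), decreasing = TRUE)
  expected <- sum(lam[1:min(10, length(lam))]^2)
  expect_equal(vamp2_score(m, rank = 10), expected, tolerance = 1e-10)
  oos <- vamp2_score(m, d, rank = 10)
  expect_equal(as.numeric(oos), expected, tolerance = 1e-8)
  expect_equal(attr(oos, "dropped_fraction"), 0)
})

test_that("identity-like chains score at the rank cap", {
  # near-identity 10-state chain: all eigenvalues ~1, score capped at rank
  C <- diag(1e6, 10) + 1
  m <- estimate_msm(C, lag = 1)
  expect_equal(as.numeric(vamp2_score(m, rank = 10)), 10, tolerance = 1e-2)
})

test_that("in-sample score never increases under lumping a perfect
           partition refinement", {
  g <- fixture_generator()
  d <- fixture_dtrajs(g, n_traj = 20, length = 1500)
  m_full <- estimate_msm(count_matrix(d, 1), lag = 1)
  # lump microstates into their owning macrostates (the exact coarse
  # partition of the generator)
  lumped <- lapply(d$dtrajs, function(s) g$micro_macro[s])
  m_lump <- estimate_msm(count_matrix(lumped, 1, n_states = 3), lag = 1)
  expect_gte(vamp2_score(m_full, rank = 10), vamp2_score(m_lump, rank = 10))
})

test_that("cross-validated scoring prefers the true resolution over a
           2-state lumping", {
  g <- fixture_generator()
  d <- fixture_dtrajs(g, n_traj = 24, length = 1500, seed = 31)
  splits <- shuffle_split(d$group_ids, n_splits = 5, seed = 17)
  wins <- 0
  for (sp in splits) {
    sub <- function(idx, traj) discrete_trajectories(
      traj$dtrajs[idx], n_states = traj$n_states)
    m_true <- estimate_msm(count_matrix(sub(sp$train, d), 1), lag = 1)
    s_true <- vamp2_score(m_true, sub(sp$test, d), rank = 10)
    # mis-lumped alternative: merge all microstates of two macrostates
    bad <- lapply(d$dtrajs, function(s)
      ifelse(g$micro_macro[s] == 3L, 2L, 1L))
    dbad <- discrete_trajectories(bad, n_states = 2)
    m_bad <- estimate_msm(count_matrix(dbad$dtrajs[sp$train], 1,
                                       n_states = 2), lag = 1)
    s_bad <- vamp2_score(m_bad, dbad$dtrajs[sp$test], rank = 10)
    if (s_true > s_bad) wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("Chapman-Kolmogorov passes on Markovian data and fails on a
           constructed non-Markovian counterexample", {
  g <- fixture_generator()
  d <- fixture_dtrajs(g, n_traj = 30, length = 2000, seed = 23)
  macro <- lapply(d$dtrajs, function(s) g$micro_macro[s])
  m <- estimate_msm(count_matrix(macro, 1, n_states = 3), lag = 1)
  ck <- ck_test(m, macro, n_sets = 3, factors = 2:5)
  expect_true(attr(ck, "pass"))
  expect_equal(nrow(ck), 12)

  # counterexample: lump a fast/slow 3-state hidden chain to 2 observed
  # states; the lumped process has a mixture dwell law and is not Markov
  T3 <- matrix(c(0.995, 0.005, 0,
                 0.005, 0.595, 0.4,
                 0,     0.4,   0.6), 3, 3, byrow = TRUE)
  paths <- lapply(1:30, function(i) {
    p <- oracle_markov_path(T3, 2000, seed = 400 + i)
    ifelse(p <= 2, 1L, 2L)
  })
  m_bad <- estimate_msm(count_matrix(paths, 1, n_states = 2), lag = 1)
  ck_bad <- ck_test(m_bad, paths, factors = 2:5,
                    sets = list(1L, 2L))
  expect_false(attr(ck_bad, "pass"))

  # factor 1 reproduces the estimation identity
  ck1 <- ck_test(m, macro, n_sets = 3, factors = 1)
  expect_true(all(abs(ck1$predicted - ck1$estimated) < 0.02))
})

test_that("escape probability matches the Beta quantile oracle", {
  # known-count path; CI must equal Beta(N f, N (1 - f)) quantiles at lag 1
  path <- c(rep(1L, 51), rep(2L, 26), rep(1L, 24))
  C <- count_matrix(list(path), 1, n_states = 2)
  est <- escape_probability(list(path), lags = 1, n_boot = 0)
  i1 <- which(est$state == 1)
  expect_equal(est$N[i1], sum(C[1, ]))
  expect_equal(est$f[i1], C[1, 1] / sum(C[1, ]))
  a <- est$N[i1] * est$f[i1]; b <- est$N[i1] * (1 - est$f[i1])
  expect_equal(c(est$ci_low[i1], est$ci_high[i1]),
               qbeta(c(0.025, 0.975), a, b), tolerance = 1e-12)

  # all self-transitions: f = 1 with upper bound 1
  est1 <- escape_probability(list(rep(1L, 50)), lags = 1, n_boot = 0)
  expect_equal(est1$f, 1)
  expect_equal(est1$ci_high, 1)

  # CI width shrinks as N grows at fixed lag
  g <- make_generator(2, 4, slow_timescales = 20, seed = 2)
  widths <- vapply(c(500, 5000), function(n) {
    ts <- sample_trajectories(g, 5, n, seed = 3, features = FALSE)
    e <- escape_probability(ts$true_macro_paths, lags = 1, n_boot = 0,
                            states = 1)
    e$ci_high - e$ci_low
  }, numeric(1))
  expect_lt(widths[2], widths[1])
})

test_that("bootstrapped escape estimates average over replicates", {
  g <- make_generator(2, 4, slow_timescales = 25, seed = 4)
  ts <- sample_trajectories(g, 10, 500, seed = 5, features = FALSE)
  est <- escape_probability(ts$true_macro_paths, lags = c(1, 3),
                            n_boot = 10, seed = 9)
  expect_equal(nrow(est), 4)
  expect_true(all(est$ci_low <= est$f + 1e-9))
  expect_true(all(est$ci_high >= est$f - 1e-9))
  # longer lag lowers the self-transition probability toward stationarity
  expect_lt(est$f[est$state == 1 & est$lag == 3],
            est$f[est$state == 1 & est$lag == 1])
})

test_that("hyperparameter search ranks the honest resolution first and is
           reproducible", {
  g <- make_generator(2, 6, slow_timescales = 40, seed = 19)
  ts <- sample_trajectories(g, n_traj = 12, length = 800, n_groups = 4,
                            seed = 21)
  grid <- list(
    list(tica_lag = 2, mapping = "commute", k = 6, msm_lag = 2),
    list(tica_lag = 2, mapping = "commute", k = 2, msm_lag = 2))
  tab <- hyperparameter_search(ts, grid, seed = 5, n_splits = 3)
  expect_equal(nrow(tab), 2)
  expect_true(all(is.na(tab$error)))
  expect_equal(tab$k[1], 6)    # the resolved model outranks the 2-lump
  tab2 <- hyperparameter_search(ts, grid, seed = 5, n_splits = 3)
  expect_equal(tab, tab2)
  # single-point grid still reports sd over splits
  tab1 <- hyperparameter_search(ts, grid[1], seed = 5, n_splits = 3)
  expect_equal(nrow(tab1), 1)
  expect_true(is.finite(tab1$sd_score))
})
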