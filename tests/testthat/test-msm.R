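test_that("count matrix matches hand counts and conserves totals", {
  expect_equal(count_matrix(list(c(1L, 2L, 1L, 2L)), 1, n_states = 2),
               matrix(c(0, 1, 2, 0), 2, 2))
  # lag = length - 1 gives exactly one count per trajectory
  d <- list(c(1L, 2L, 2L, 1L), c(2L, 2L, 1L, 2L))
  C <- count_matrix(d, 3, n_states = 2)
  expect_equal(sum(C), 2)
  # conservation: total counts = sum(len - lag)
  set.seed(1)
  d2 <- lapply(1:5, function(i) sample.int(4, 60, replace = TRUE))
  for (lag in c(1, 7)) {
    expect_equal(sum(count_matrix(d2, lag, n_states = 4)),
                 sum(lengths(d2) - lag))
  }
  expect_error(count_matrix(list(1:3), 5), "lag")
})

test_that("reversible MLE satisfies detailed balance and matches a grid
           oracle on two states", {
  C <- matrix(c(90, 10, 20, 80), 2, 2, byrow = TRUE)
  m <- estimate_msm(C, lag = 1)
  expect_equal(rowSums(m$T), c(1, 1), tolerance = 1e-10)
  expect_equal(m$pi %*% m$T, t(m$pi), tolerance = 1e-8, ignore_attr = TRUE)
  D <- m$pi * m$T
  expect_equal(D, t(D), tolerance = 1e-10)
  # brute-force likelihood maximization over the 2-state reversible family
  # parameterized by (pi1, p12) with p21 = pi1 p12 / (1 - pi1)
  grid_ll <- function(pi1, p12) {
    p21 <- pi1 * p12 / (1 - pi1)
    if (p21 >= 1) return(-Inf)
    C[1, 1] * log(1 - p12) + C[1, 2] * log(p12) +
      C[2, 1] * log(p21) + C[2, 2] * log(1 - p21)
  }
  pars <- expand.grid(pi1 = seq(0.01, 0.99, by = 0.002),
                      p12 = seq(0.005, 0.5, by = 0.002))
  ll <- mapply(grid_ll, pars$pi1, pars$p12)
  best <- pars[which.max(ll), ]
  # agreement to within the grid resolution
  expect_lt(abs(m$pi[1] - best$pi1), 0.003)
  expect_lt(abs(m$T[1, 2] - best$p12), 0.0015)
})

test_that("symmetric counts give the row-normalized matrix exactly", {
  C <- matrix(c(40, 6, 2, 6, 50, 4, 2, 4, 30), 3, 3)
  m <- estimate_msm(C, lag = 1)
  expect_equal(m$T, C / rowSums(C), tolerance = 1e-9)
})

test_that("disconnected states are excluded from the active set", {
  C <- matrix(0, 4, 4)
  C[1:2, 1:2] <- matrix(c(50, 5, 5, 40), 2, 2)
  C[3, 3] <- 10           # isolated self-looping state
  C[4, 4] <- 2
  m <- estimate_msm(C, lag = 1)
  expect_equal(m$active_set, 1:2)
})

test_that("estimator converges to the generator truth with data size", {
  g <- fixture_generator()
  errs <- vapply(c(2e3, 2e4, 2e5), function(n) {
    meds <- vapply(1:5, function(s) {
      ts <- sample_trajectories(g, n_traj = 4, length = ceiling(n / 4),
                                seed = 100 * s + n, features = FALSE)
      d <- discrete_trajectories(ts$true_micro_paths, n_states = g$n_micro)
      m <- estimate_msm(count_matrix(d, 1), lag = 1)
      Tfull <- matrix(NA_real_, g$n_micro, g$n_micro)
      Tfull[m$active_set, m$active_set] <- m$T
      max(abs(Tfull - g$micro_T), na.rm = TRUE)
    }, numeric(1))
    median(meds)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("implied timescales are flat in lag for Markovian data and use
           the closed form on two states", {
  T2 <- fixture_two_state_T(0.1, 0.2)
  lam2 <- 1 - 0.1 - 0.2
  paths <- lapply(1:10, function(i)
    oracle_markov_path(T2, 3000, seed = i))
  its <- implied_timescales(lapply(paths, as.integer), lags = c(1, 2, 5),
                            n_its = 1)
  for (r in seq_len(nrow(its))) {
    expect_equal(its$timescale[r], -1 / log(lam2), tolerance = 0.15)
  }
  # exact closed form when the chain is fed its own transition matrix
  m <- estimate_msm(matrix(c(900, 100, 200, 800), 2, 2, byrow = TRUE))
  expect_equal(transition_timescales(m$T, lag = 3)[1],
               -3 / log(1 - m$T[1, 2] - m$T[2, 1]), tolerance = 1e-8)
})

test_that("k-means recovers well-separated blobs deterministically", {
  set.seed(5)
  X <- rbind(matrix(rnorm(400, 0), 200, 2),
             matrix(rnorm(400, 8), 200, 2))
  d <- discretize_kmeans(list(X), k = 2, seed = 3)
  lab <- d$dtrajs[[1]]
  expect_equal(rand_index(lab, rep(1:2, each = 200)), 1)
  d2 <- discretize_kmeans(list(X), k = 2, seed = 3)
  expect_identical(d$dtrajs, d2$dtrajs)
  # k = number of distinct points -> zero inertia
  Xs <- matrix(c(0, 0, 1, 1, 5, 5), 3, 2, byrow = TRUE)
  d3 <- discretize_kmeans(list(Xs), k = 3, seed = 1)
  expect_equal(d3$inertia, 0)
  # cross-check against the stock Lloyd implementation given our centers
  km <- suppressWarnings(stats::kmeans(X, centers = d$centers,
                                       iter.max = 1, algorithm = "Lloyd"))
  expect_equal(rand_index(lab, km$cluster), 1)
})

test_that("shuffle splits partition groups, never trajectories", {
  groups <- rep(1:9, times = 3)
  splits <- shuffle_split(groups, ratio = 0.5, n_splits = 5, seed = 4)
  for (sp in splits) {
    expect_true(length(sp$train_groups) %in% 4:5)
    expect_setequal(c(sp$train_groups, sp$test_groups), 1:9)
    expect_length(intersect(sp$train_groups, sp$test_groups), 0)
    expect_setequal(c(sp$train, sp$test), seq_along(groups))
    # no group straddles the split
    expect_length(intersect(groups[sp$train], groups[sp$test]), 0)
  }
  expect_identical(splits, shuffle_split(groups, 0.5, 5, seed = 4))
  expect_error(shuffle_split(rep(1, 5)), "single group")
  sp2 <- shuffle_split(c(1, 1, 2, 2), n_splits = 1, seed = 1)[[1]]
  expect_length(sp2$train_groups, 1)
})

test_that("dtrajs round-trip through CSV", {
  d <- fixture_dtrajs(n_traj = 3, length = 40)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dtrajs_csv(d, path)
  back <- read_dtrajs_csv(path, n_states = d$n_states)
  expect_equal(back$dtrajs, d$dtrajs)
  expect_equal(back$group_ids, d$group_ids)
})
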