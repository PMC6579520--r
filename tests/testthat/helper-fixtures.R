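# Shared fixtures, built in code at test time.

# small metastable generator reused across modules
fixture_generator <- function(seed = 42) {
  make_generator(3, 12, slow_timescales = c(80, 15), seed = seed)
}

# moderate dataset of discrete trajectories from the fixture generator
fixture_dtrajs <- function(g = fixture_generator(), n_traj = 20,
                           length = 2000, seed = 7) {
  ts <- sample_trajectories(g, n_traj = n_traj, length = length,
                            n_groups = 4, seed = seed, features = FALSE)
  discrete_trajectories(ts$true_micro_paths, n_states = g$n_micro,
                        group_ids = ts$group_ids)
}

# hand-checkable two-state chain
fixture_two_state_T <- function(p = 0.1, q = 0.2) {
  matrix(c(1 - p, p, q, 1 - q), 2, 2, byrow = TRUE)
}

# sample a Markov chain path from a transition matrix (independent of the
# package's samplers; used as an oracle data source)
oracle_markov_path <- function(T, n, seed, start = 1L) {
  set.seed(seed)
  path <- integer(n)
  path[1] <- start
  cum <- t(apply(T, 1, cumsum))
  u <- runif(n - 1)
  for (t in 2:n) path[t] <- sum(u[t - 1] > cum[path[t - 1], ]) + 1L
  path
}

# brute-force mean contact map oracle (frame-wise loop, no shared code)
oracle_contact_map <- function(frames, cutoff = 0.4, min_seq_sep = 3) {
  n <- nrow(frames[[1]])
  M <- matrix(0, n, n)
  for (X in frames) {
    D <- as.matrix(dist(X))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (j - i >= min_seq_sep && D[i, j] < cutoff) {
        M[i, j] <- M[i, j] + 1
        M[j, i] <- M[j, i] + 1
      }
    }
  }
  M / length(frames)
}
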