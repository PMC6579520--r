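test_that("eligible pair enumeration follows the sequence-separation rule", {
  # pair-enumeration oracle for a 5-residue chain with |i-j| >= 3
  be <- make_bead_chain_ensemble(5, n_frames_base = 2, seed = 1)
  ft <- pairwise_min_distances(be)
  expect_equal(unname(ft$pairs), rbind(c(1L, 4L), c(1L, 5L), c(2L, 5L)))
  expect_equal(ncol(ft$X), 3)
  expect_equal(nrow(ft$X), 2)
})

test_that("distances are exact and rotation invariant", {
  # two point-residues 0.7 nm apart among a 4-bead chain
  frames <- list(rbind(c(0, 0, 0), c(0.35, 0, 0), c(0.7, 0, 0),
                       c(0.7, 0.35, 0)))
  ens <- list(frames = frames, residue_ids = 1:4)
  ft <- pairwise_min_distances(ens)
  expect_equal(unname(ft$pairs), rbind(c(1L, 4L)))
  expect_equal(as.numeric(ft$X),
               sqrt(0.7^2 + 0.35^2))
  # rigid rotation + translation leaves distances unchanged
  th <- 0.83
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  ens_rot <- list(frames = list(frames[[1]] %*% R + 1.5), residue_ids = 1:4)
  expect_equal(pairwise_min_distances(ens_rot)$X, ft$X, tolerance = 1e-12)
})

test_that("minimum heavy-atom distance is used for multi-atom residues", {
  # residue 1: two atoms; residue 4: one atom; min distance wins
  ens <- list(
    frames = list(rbind(c(0, 0, 0), c(0.2, 0, 0),        # residue 1
                        c(0.5, 0, 0), c(0.9, 0, 0),       # residues 2, 3
                        c(1.0, 0, 0))),                   # residue 4
    atom_residue = c(1L, 1L, 2L, 3L, 4L), residue_ids = 1:4)
  ft <- pairwise_min_distances(ens)
  expect_equal(as.numeric(ft$X[1, 1]), 0.8)  # from atom at 0.2, not 0.0
})

test_that("dynamic-pair selection matches a brute-force scan", {
  g <- with_seed(1, NULL)
  set.seed(10)
  X1 <- matrix(runif(200, 0.2, 0.8), 20, 10)
  X2 <- matrix(runif(100, 0.2, 0.8), 10, 10)
  # pin two degenerate columns: always below / always above the cutoff
  X1[, 1] <- 0.3; X2[, 1] <- 0.35
  X1[, 2] <- 0.45; X2[, 2] <- 0.6
  trs <- list(structure(list(X = X1), class = "feature_trajectory"),
              structure(list(X = X2), class = "feature_trajectory"))
  sel <- select_dynamic_pairs(trs, cutoff = 0.4)
  # brute force over every frame of both trajectories
  allX <- rbind(X1, X2)
  brute <- which(vapply(seq_len(10), function(j)
    any(allX[, j] < 0.4) && any(allX[, j] >= 0.4), logical(1)))
  expect_identical(sel, brute)
  expect_false(1 %in% sel)
  expect_false(2 %in% sel)
  # a single crossing in either direction suffices
  tr <- structure(list(X = matrix(c(0.35, 0.45), 2, 1)),
                  class = "feature_trajectory")
  expect_identical(select_dynamic_pairs(tr, 0.4), 1L)
})

test_that("logistic transform matches its closed form and is monotone", {
  cfg <- featurization_config()
  expect_equal(logistic_transform(0.5, cfg), 0.5)
  expect_equal(logistic_transform(0.3, cfg), 1 / (1 + exp(-1)),
               tolerance = 1e-12)
  expect_equal(logistic_transform(1e6, cfg), 0)
  d <- seq(0, 2, by = 0.01)
  expect_true(all(diff(logistic_transform(d, cfg)) < 0))
  # center maps to 1/2 for any steepness
  for (s in c(0.5, 5, 50)) {
    cfg_s <- featurization_config(steepness = s, center = 0.7)
    expect_equal(logistic_transform(0.7, cfg_s), 0.5)
  }
})

test_that("dihedral features are unit-norm sin/cos pairs", {
  be <- make_bead_chain_ensemble(7, n_frames_base = 3, seed = 2)
  ft <- dihedral_features(be)
  expect_equal(ncol(ft$X), 2 * 4)   # 4 quadruplets on 7 beads
  sums <- ft$X[, seq(1, 8, by = 2)]^2 + ft$X[, seq(2, 8, by = 2)]^2
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-10)
})

test_that("planar zig-zag chain has 180-degree torsions", {
  # geometry oracle: all-trans planar chain -> phi = 180, features (0, -1)
  n <- 6
  X <- cbind(seq_len(n) * 0.3, rep(c(0, 0.2), length.out = n), 0)
  ft <- dihedral_features(list(frames = list(X)))
  expect_equal(ft$X[1, seq(1, ncol(ft$X), by = 2)],
               rep(0, (n - 3)), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(ft$X[1, seq(2, ncol(ft$X), by = 2)],
               rep(-1, (n - 3)), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("mean contact map equals the brute-force frame average", {
  be <- make_bead_chain_ensemble(8, base_contacts = rbind(c(2, 7)),
                                 perturbed_contacts = rbind(c(1, 8)),
                                 n_frames_base = 3, n_frames_perturbed = 7,
                                 seed = 5)
  cm <- mean_contact_map(be)
  expect_equal(cm$matrix, oracle_contact_map(be$frames), ignore_attr = TRUE)
  # contact present in 3 of 10 frames
  expect_equal(cm$matrix[2, 7], 0.3)
  expect_equal(cm$matrix[1, 8], 0.7)
  # symmetry and near-diagonal exclusion
  expect_equal(cm$matrix, t(cm$matrix))
  for (i in 1:7) for (j in (i + 1):min(i + 2, 8))
    expect_equal(cm$matrix[i, j], 0)
})
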