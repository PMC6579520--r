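test_that("differential contact maps apply both thresholds and the
           zero-division rule", {
  W <- matrix(0, 6, 6); M <- matrix(0, 6, 6)
  W[1, 4] <- W[4, 1] <- 0.1;  M[1, 4] <- M[4, 1] <- 0.5   # selected
  W[2, 5] <- W[5, 2] <- 0.4;  M[2, 5] <- M[5, 2] <- 0.65  # rel too small
  W[3, 6] <- W[6, 3] <- 0;    M[3, 6] <- M[6, 3] <- 0.5   # WT zero rule
  d <- differential_contact_map(M, W)
  expect_equal(d$absolute[1, 4], 0.4)
  expect_equal(d$relative[1, 4], 4)
  expect_equal(d$relative[3, 6], 0)
  expect_equal(unname(d$selected_pairs), cbind(1L, 4L), ignore_attr = TRUE)
  # identical maps: all zero, nothing selected
  d0 <- differential_contact_map(W, W)
  expect_equal(max(abs(d0$absolute)), 0)
  expect_equal(nrow(d0$selected_pairs), 0)
  # swapped arguments negate the absolute map
  expect_equal(differential_contact_map(W, M)$absolute, -d$absolute)
  # residue deletion zeroes its row and column
  ddel <- differential_contact_map(M, W, deletion = 1)
  expect_equal(nrow(ddel$selected_pairs), 0)
  expect_equal(max(abs(ddel$absolute[1, ])), 0)
  expect_error(differential_contact_map(matrix(0, 3, 3), W), "shape")
})

test_that("candidate frame extraction applies the qualification and
           stride rules", {
  # synthetic qualification via a two-condition bead ensemble: perturbed
  # frames form the positive contact
  be <- make_bead_chain_ensemble(8, base_contacts = rbind(c(1, 6)),
                                 perturbed_contacts = rbind(c(2, 8)),
                                 n_frames_base = 60, n_frames_perturbed = 45,
                                 seed = 13)
  cm_b <- mean_contact_map(be, frames = which(be$condition == "base"))
  cm_p <- mean_contact_map(be, frames = which(be$condition == "perturbed"))
  diffm <- differential_contact_map(cm_p, cm_b)
  # top positive contact is (2,8), top negative (1,6); qualifying frames
  # are those with (2,8) formed OR (1,6) absent = the perturbed frames
  got <- extract_candidate_frames(be, diffm, burn_in = 0)
  qual <- which(be$condition == "perturbed")
  expect_equal(got, qual[seq(1, length(qual), by = 10)])
  # burn-in removal
  got_b <- extract_candidate_frames(be, diffm, burn_in = 70)
  expect_true(all(got_b > 70))
  # counting oracle: contiguous block 100-199 qualifying
  expect_equal(length(got), ceiling(45 / 10))
})

test_that("stride switches to 20 beyond 7,500 qualifying frames", {
  # exercise the rule on a synthetic qualification mask through a tiny
  # shim ensemble: many perturbed frames
  be <- make_bead_chain_ensemble(8, base_contacts = rbind(c(1, 6)),
                                 perturbed_contacts = rbind(c(2, 8)),
                                 n_frames_base = 2, n_frames_perturbed = 2,
                                 seed = 14)
  # inflate by repeating the perturbed frame 8000 times
  pert <- be$frames[[3]]
  big <- list(frames = c(be$frames[1:2], rep(list(pert), 8000)),
              residue_ids = 1:8)
  cm_b <- mean_contact_map(be, frames = 1:2)
  cm_p <- mean_contact_map(be, frames = 3:4)
  diffm <- differential_contact_map(cm_p, cm_b)
  got <- extract_candidate_frames(big, diffm)
  expect_equal(length(got), ceiling(8000 / 20))
  # and stride 10 below the threshold
  small <- list(frames = c(be$frames[1:2], rep(list(pert), 500)),
                residue_ids = 1:8)
  expect_equal(length(extract_candidate_frames(small, diffm)),
               ceiling(500 / 10))
  # no qualifying contacts: empty result, not an error
  d_empty <- differential_contact_map(cm_b, cm_b)
  expect_length(extract_candidate_frames(be, d_empty), 0)
})

test_that("RMSD cluster expansion matches a brute-force scan", {
  be <- make_bead_chain_ensemble(7, base_contacts = rbind(c(1, 5)),
                                 perturbed_contacts = rbind(c(3, 7)),
                                 n_frames_base = 12, n_frames_perturbed = 12,
                                 seed = 15, jitter_sd = 0.01)
  cluster <- be$frames[be$condition == "perturbed"][1:3]
  got <- expand_cluster_by_rmsd(cluster, be$frames, threshold = 0.3,
                                stride = 2)
  scan <- as.integer(seq(1, length(be$frames), by = 2))
  brute <- scan[vapply(scan, function(fi)
    min(vapply(cluster, function(cf)
      superpose_rmsd(be$frames[[fi]], cf), numeric(1))) < 0.3,
    logical(1))]
  expect_identical(got, brute)
  # a cluster frame present in the scan selects itself even at tiny
  # threshold
  got0 <- expand_cluster_by_rmsd(be$frames[13], be$frames,
                                 threshold = 1e-9, stride = 1)
  expect_true(13 %in% got0)
  # extraction -> expansion is idempotent on its own output
  sel_frames <- be$frames[got]
  again <- expand_cluster_by_rmsd(sel_frames, sel_frames, threshold = 0.3,
                                  stride = 1)
  expect_equal(again, seq_along(sel_frames))
})
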