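## Rigid-body superposition (Kabsch) and RMSD-based structural summaries.

kabsch_rotation <- function(P, Q) {
  # optimal proper rotation R with P %*% R ~ Q (both pre-centered)
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(rep(1, ncol(P) - 1), d)) %*% t(s$v)
}

#' Superposition configuration
#'
#' Which atoms drive the rigid-body fit and which enter the RMSD. The
#' defaults name the conformationally homogeneous SET motifs of the SETD8
#' catalytic domain (residues 257-290 and 327-376); for synthetic bead
#' chains pass explicit indices or \code{NULL} for all atoms.
#'
#' @param fit_atoms integer indices of atoms used for the superposition fit,
#'   or \code{NULL} for all atoms.
#' @param rmsd_atoms integer indices of atoms entering the RMSD, or
#'   \code{NULL} for all atoms.
#' @return a list of class \code{superposition_config}.
#' @export
superposition_config <- function(fit_atoms = NULL, rmsd_atoms = NULL) {
  structure(list(fit_atoms = fit_atoms, rmsd_atoms = rmsd_atoms),
            class = "superposition_config")
}

#' Default SET-motif residue ranges used for superposition fits
#'
#' @return integer vector of residue numbers 257-290 and 327-376.
#' @export
set_motif_residues <- function() c(257:290, 327:376)

#' RMSD after optimal rigid-body superposition
#'
#' Each mobile frame is superposed onto the reference by the Kabsch
#' algorithm using \code{config$fit_atoms} only, then the RMSD is computed
#' over \code{config$rmsd_atoms}. Invariant under any rigid transform of the
#' mobile frame.
#'
#' @param frames a single n_atoms x 3 matrix or a list of them (nm).
#' @param reference n_atoms x 3 reference coordinates.
#' @param config a \code{superposition_config}.
#' @return numeric vector, one RMSD (nm) per frame.
#' @export
superpose_rmsd <- function(frames, reference,
                           config = superposition_config()) {
  if (is.matrix(frames)) frames <- list(frames)
  fit <- config$fit_atoms %||% seq_len(nrow(reference))
  rms <- config$rmsd_atoms %||% seq_len(nrow(reference))
  if (max(fit) > nrow(reference) || max(rms) > nrow(reference))
    stop("selection indices exceed the reference")
  ref_fit <- reference[fit, , drop = FALSE]
  ref_fit_c <- scale(ref_fit, scale = FALSE)
  ref_center <- attr(ref_fit_c, "scaled:center")
  vapply(frames, function(X) {
    if (!identical(dim(X), dim(reference)))
      stop("frame/reference atom count mismatch")
    mob_fit <- X[fit, , drop = FALSE]
    mc <- colMeans(mob_fit)
    R <- kabsch_rotation(sweep(mob_fit, 2, mc), ref_fit_c)
    Xs <- sweep(X, 2, mc) %*% R
    Xs <- sweep(Xs, 2, ref_center, "+")
    d <- Xs[rms, , drop = FALSE] - reference[rms, , drop = FALSE]
    sqrt(mean(rowSums(d^2)))
  }, numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Macrostate RMSD as an observation-probability-weighted mean
#'
#' Per-macrostate RMSD = sum over microstates of the HMM observation
#' probability times the microstate's mean RMSD.
#'
#' @param micro_rmsds numeric vector, mean RMSD per microstate (indexed by
#'   the HMM's observed microstates).
#' @param hmm a fitted \code{hmm_model} (or any list with an \code{obs}
#'   matrix of n_macro x n_micro observation probabilities).
#' @return numeric vector of length n_macro.
#' @export
state_rmsd_summary <- function(micro_rmsds, hmm) {
  obs <- hmm$obs
  if (ncol(obs) != length(micro_rmsds))
    stop("micro_rmsds must cover all observed microstates")
  as.numeric(obs %*% micro_rmsds)
}

#' Structural diversity of a frame sample
#'
#' For each frame in the sample, the mean superposition RMSD to all other
#' frames is computed; the minimum of these means over reference frames is
#' returned (0 for identical frames; r for two frames at RMSD r).
#'
#' @param frames list of n_atoms x 3 coordinate matrices (>= 2 frames).
#' @param config a \code{superposition_config}.
#' @return single numeric diversity score (nm).
#' @export
structural_diversity <- function(frames, config = superposition_config()) {
  n <- length(frames)
  stopifnot(n >= 2)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    D[i, others] <- superpose_rmsd(frames[others], frames[[i]], config)
  }
  # superposition RMSD is symmetric up to numerics; use the row means of
  # each reference frame's distances to the other n-1 frames
  min(rowSums(D) / (n - 1))
}

#' Weighted macrostate frame sampling for diversity estimates
#'
#' Draws frames from a macrostate with probability proportional to the
#' macrostate's observation probability of the frame's microstate divided by
#' the number of frames in that microstate.
#'
#' @param frame_micro integer vector, microstate label of each candidate
#'   frame.
#' @param obs_row numeric vector of observation probabilities for one
#'   macrostate (length n_micro).
#' @param n_sample frames to draw (default 100).
#' @param seed integer seed.
#' @return integer indices into \code{frame_micro}.
#' @export
sample_macrostate_frames <- function(frame_micro, obs_row, n_sample = 100,
                                     seed = 1) {
  counts <- tabulate(frame_micro, nbins = length(obs_row))
  w <- obs_row[frame_micro] / pmax(counts[frame_micro], 1L)
  if (all(w == 0)) stop("macrostate observes none of the supplied frames")
  with_seed(seed, sample.int(length(frame_micro), size = n_sample,
                             replace = n_sample > sum(w > 0), prob = w))
}
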