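## Featurization of structural trajectories: residue-residue minimum
## distances, the logistic contact-emphasis transform, dihedral sin/cos
## features, and binary/mean contact maps.

#' Featurization configuration
#'
#' Collects the thresholds of the distance-based featurizations: the
#' logistic transform parameters (steepness 5 nm^-1, center 0.5 nm), the
#' 0.4 nm contact cutoffs used both for dynamic-pair selection and for
#' binary contact maps, and the sequence-separation rule |i - j| >= 3 (two
#' residues strictly between).
#'
#' @param mode one of \code{"distances"}, \code{"logistic_distances"},
#'   \code{"dihedrals"}.
#' @param contact_select_cutoff cutoff (nm) a pair must cross to count as
#'   dynamic (default 0.4).
#' @param steepness logistic steepness (nm^-1, default 5).
#' @param center logistic midpoint (nm, default 0.5).
#' @param min_seq_sep minimum sequence separation |i - j| (default 3).
#' @param contact_map_cutoff binary contact threshold (nm, default 0.4).
#' @return list of class \code{featurization_config}.
#' @export
featurization_config <- function(mode = c("distances", "logistic_distances",
                                          "dihedrals"),
                                 contact_select_cutoff = 0.4,
                                 steepness = 5, center = 0.5,
                                 min_seq_sep = 3L,
                                 contact_map_cutoff = 0.4) {
  mode <- match.arg(mode)
  stopifnot(contact_select_cutoff > 0, steepness > 0, center > 0,
            min_seq_sep >= 1, contact_map_cutoff > 0)
  structure(list(mode = mode,
                 contact_select_cutoff = contact_select_cutoff,
                 steepness = steepness, center = center,
                 min_seq_sep = as.integer(min_seq_sep),
                 contact_map_cutoff = contact_map_cutoff),
            class = "featurization_config")
}

## Eligible residue pairs under the sequence-separation rule, in canonical
## column order (i < j, ordered by i then j). Returned as a 2-column matrix.
eligible_pairs <- function(residue_ids, min_seq_sep = 3L) {
  n <- length(residue_ids)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pr <- pr[abs(residue_ids[pr[, 2]] - residue_ids[pr[, 1]]) >= min_seq_sep, ,
           drop = FALSE]
  pr <- pr[order(pr[, 1], pr[, 2]), , drop = FALSE]
  colnames(pr) <- c("i", "j")
  pr
}

## Per-frame minimum inter-residue distance for the given pairs. Supports
## multiple atoms per residue through atom_residue (atom -> residue index).
frame_min_distances <- function(X, pairs, atom_residue) {
  vapply(seq_len(nrow(pairs)), function(p) {
    ai <- which(atom_residue == pairs[p, 1])
    aj <- which(atom_residue == pairs[p, 2])
    d2 <- outer(rowSums(X[ai, , drop = FALSE]^2),
                rowSums(X[aj, , drop = FALSE]^2), "+") -
      2 * X[ai, , drop = FALSE] %*% t(X[aj, , drop = FALSE])
    sqrt(max(min(d2), 0))
  }, numeric(1))
}

#' Residue-residue minimum-distance features
#'
#' One feature column per eligible residue pair (sequence separation
#' |i - j| >= \code{min_seq_sep}); the value is the minimum heavy-atom
#' distance between the two residues in each frame, in nm. For one-bead
#' residues this is the bead distance.
#'
#' @param ensemble a \code{bead_ensemble}, or a list with \code{frames}
#'   (list of n_atom x 3 matrices) and optionally \code{atom_residue}
#'   (atom-to-residue index map; default one atom per residue) and
#'   \code{residue_ids}.
#' @param config a \code{featurization_config}.
#' @return list of class \code{feature_trajectory}: \code{X} (frames x
#'   pairs matrix), \code{pairs} (2-column residue index matrix),
#'   \code{colnames} like \code{"d_3_8"}.
#' @export
pairwise_min_distances <- function(ensemble, config = featurization_config()) {
  frames <- ensemble$frames
  stopifnot(length(frames) >= 1)
  n_atom <- nrow(frames[[1]])
  atom_residue <- ensemble$atom_residue %||% seq_len(n_atom)
  residue_ids <- ensemble$residue_ids %||% sort(unique(atom_residue))
  if (any(tabulate(atom_residue) == 0 & seq_along(tabulate(atom_residue))
          %in% residue_ids))
    stop("residues with no heavy atoms are not featurizable")
  pairs <- eligible_pairs(residue_ids, config$min_seq_sep)
  X <- t(vapply(frames, frame_min_distances, numeric(nrow(pairs)),
                pairs = pairs, atom_residue = atom_residue))
  if (nrow(pairs) == 1L) X <- matrix(X, ncol = 1L)
  structure(list(X = X, pairs = pairs,
                 colnames = sprintf("d_%d_%d", residue_ids[pairs[, 1]],
                                    residue_ids[pairs[, 2]])),
            class = "feature_trajectory")
}

#' Select dynamic residue pairs
#'
#' Keeps a pair iff, across every frame of every supplied distance
#' trajectory, its distance takes values both below and at-or-above the
#' cutoff -- i.e. the pair crosses the contact threshold in either
#' direction at least once.
#'
#' @param distances a \code{feature_trajectory} or list of them (distance
#'   featurization).
#' @param cutoff contact threshold in nm (default 0.4).
#' @return integer vector of retained column indices.
#' @export
select_dynamic_pairs <- function(distances, cutoff = 0.4) {
  if (inherits(distances, "feature_trajectory")) distances <- list(distances)
  stopifnot(length(distances) >= 1)
  below <- Reduce(`|`, lapply(distances, function(tr)
    apply(tr$X < cutoff, 2, any)))
  above <- Reduce(`|`, lapply(distances, function(tr)
    apply(tr$X >= cutoff, 2, any)))
  which(below & above)
}

#' Logistic contact-emphasis transform
#'
#' \eqn{1 / (1 + \exp(\mathrm{steepness} \times (d - \mathrm{center})))}:
#' strictly decreasing in d, equal to 0.5 at the center, emphasizing
#' short-range distances near residue-residue contact.
#'
#' @param d distance(s) in nm.
#' @param config a \code{featurization_config} (uses steepness and center).
#' @return values in (0, 1), same shape as \code{d}.
#' @export
logistic_transform <- function(d, config = featurization_config()) {
  1 / (1 + exp(config$steepness * (d - config$center)))
}

#' Dihedral angle features (sine/cosine pairs)
#'
#' Computes the torsion angle of every declared atom quadruplet per frame
#' and featurizes each angle as (sin, cos). Angles are never imputed: the
#' feature count is exactly twice the number of defined angles.
#'
#' @param ensemble structure ensemble with \code{frames}.
#' @param angle_defs 4-column integer matrix of atom quadruplets; default
#'   every run of 4 consecutive beads (the backbone torsions of a bead
#'   chain).
#' @return a \code{feature_trajectory} with columns
#'   \code{sin_k, cos_k} per angle.
#' @export
dihedral_features <- function(ensemble, angle_defs = NULL) {
  frames <- ensemble$frames
  n_atom <- nrow(frames[[1]])
  if (is.null(angle_defs)) {
    if (n_atom < 4) stop("no dihedral angles are defined")
    angle_defs <- cbind(1:(n_atom - 3), 2:(n_atom - 2),
                        3:(n_atom - 1), 4:n_atom)
  }
  angle_defs <- matrix(as.integer(angle_defs), ncol = 4)
  if (nrow(angle_defs) == 0) stop("no dihedral angles are defined")
  n_ang <- nrow(angle_defs)
  X <- t(vapply(frames, function(P) {
    ang <- vapply(seq_len(n_ang), function(k) {
      torsion_angle(P[angle_defs[k, 1], ], P[angle_defs[k, 2], ],
                    P[angle_defs[k, 3], ], P[angle_defs[k, 4], ])
    }, numeric(1))
    as.vector(rbind(sin(ang), cos(ang)))
  }, numeric(2 * n_ang)))
  if (2 * n_ang == 1L) X <- matrix(X, ncol = 1L)
  structure(list(X = X, angle_defs = angle_defs,
                 colnames = as.vector(rbind(sprintf("sin_%d", seq_len(n_ang)),
                                            sprintf("cos_%d", seq_len(n_ang))))),
            class = "feature_trajectory")
}

## Signed torsion angle of four points, in radians in (-pi, pi].
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

#' Mean residue contact map of an ensemble
#'
#' Scores each eligible residue pair 1 in a frame if its minimum heavy-atom
#' distance is below the contact cutoff (0.4 nm = 4.0 A), else 0, and
#' averages over frames. Pairs closer in sequence than \code{min_seq_sep}
#' are fixed at 0.
#'
#' @param ensemble structure ensemble (see \code{pairwise_min_distances}).
#' @param config a \code{featurization_config}.
#' @param frames optional integer subset of frames to average over.
#' @return list of class \code{contact_map}: symmetric \code{matrix} of
#'   contact fractions, \code{n_frames}, \code{residue_index}.
#' @export
mean_contact_map <- function(ensemble, config = featurization_config(),
                             frames = NULL) {
  dtr <- pairwise_min_distances(ensemble, config)
  X <- dtr$X
  if (!is.null(frames)) X <- X[frames, , drop = FALSE]
  stopifnot(nrow(X) >= 1)
  frac <- colMeans(X < config$contact_map_cutoff)
  residue_ids <- ensemble$residue_ids %||%
    seq_len(nrow(ensemble$frames[[1]]))
  n <- length(residue_ids)
  M <- matrix(0, n, n, dimnames = list(residue_ids, residue_ids))
  M[dtr$pairs] <- frac
  M <- M + t(M)
  structure(list(matrix = M, n_frames = nrow(X),
                 residue_index = residue_ids),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("Contact map:", nrow(x$matrix), "residues, averaged over",
      x$n_frames, "frames;", sum(x$matrix[upper.tri(x$matrix)] > 0),
      "pairs with nonzero contact fraction\n")
  invisible(x)
}

#' Write a contact map to TSV
#'
#' @param cm a \code{contact_map} (or \code{diff_contact_map} matrix slot).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_contact_map <- function(cm, path) {
  M <- if (inherits(cm, "contact_map")) cm$matrix else cm
  utils::write.table(M, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}
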