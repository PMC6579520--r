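## Mutant-versus-wild-type differential contact analysis and extraction of
## candidate new-conformation frames.

#' Differential residue contact map
#'
#' Subtracts the wild-type mean contact map from the mutant map (absolute
#' change in \[-1, 1\]), computes the relative change as |absolute| divided
#' by the wild-type value (forced to 0 where the wild-type value is 0), and
#' selects the pairs whose absolute change exceeds \code{abs_thresh} AND
#' whose relative change exceeds \code{rel_thresh} (both strict). For a
#' residue deletion, all contact changes involving that residue position
#' are zeroed before selection.
#'
#' @param mutant,wildtype \code{contact_map} objects on the same residue
#'   indexing (after deletion alignment).
#' @param abs_thresh absolute-change threshold (default 0.2).
#' @param rel_thresh relative-change threshold (default 3).
#' @param deletion optional residue position (index into the map) whose
#'   changes are zeroed.
#' @return list of class \code{diff_contact_map}: \code{absolute},
#'   \code{relative}, \code{selected_pairs} (2-column index matrix),
#'   \code{deletion_residue}.
#' @export
differential_contact_map <- function(mutant, wildtype, abs_thresh = 0.2,
                                     rel_thresh = 3, deletion = NULL) {
  M <- if (inherits(mutant, "contact_map")) mutant$matrix else mutant
  W <- if (inherits(wildtype, "contact_map")) wildtype$matrix else wildtype
  if (!identical(dim(M), dim(W)))
    stop("mutant and wild-type contact maps differ in shape")
  absolute <- M - W
  if (!is.null(deletion)) {
    absolute[deletion, ] <- 0
    absolute[, deletion] <- 0
  }
  relative <- ifelse(W > 0, abs(absolute) / W, 0)
  sel <- which(abs(absolute) > abs_thresh & relative > rel_thresh &
                 upper.tri(absolute), arr.ind = TRUE)
  colnames(sel) <- c("i", "j")
  structure(list(absolute = absolute, relative = relative,
                 selected_pairs = sel,
                 deletion_residue = deletion),
            class = "diff_contact_map")
}

#' @export
print.diff_contact_map <- function(x, ...) {
  cat("Differential contact map:", nrow(x$absolute), "residues;",
      nrow(x$selected_pairs), "selected pairs",
      if (!is.null(x$deletion_residue))
        paste0("(deletion at residue ", x$deletion_residue, ")"), "\n")
  invisible(x)
}

## Top +/- contact pairs of a differential map: up to n_top most positive
## and most negative absolute changes beyond the threshold.
top_changed_contacts <- function(diff, n_top = 5, abs_thresh = 0.2) {
  A <- diff$absolute
  iu <- which(upper.tri(A), arr.ind = TRUE)
  v <- A[iu]
  pos <- iu[v > abs_thresh, , drop = FALSE]
  pos <- pos[order(-v[v > abs_thresh]), , drop = FALSE]
  neg <- iu[v < -abs_thresh, , drop = FALSE]
  neg <- neg[order(v[v < -abs_thresh]), , drop = FALSE]
  list(positive = head(pos, n_top), negative = head(neg, n_top))
}

#' Extract candidate new-conformation frames
#'
#' After discarding the burn-in, keeps the frames in which all
#' top-positive contacts are formed OR none of the top-negative contacts
#' are formed (under the 0.4 nm rule), then strides by 10 -- or by 20 when
#' more than 7,500 frames qualify.
#'
#' @param ensemble structure ensemble of the mutant (frames +
#'   residue geometry, see \code{\link{pairwise_min_distances}}).
#' @param diff a \code{diff_contact_map} for this mutant.
#' @param burn_in number of initial frames discarded (default 0).
#' @param n_top maximum positive/negative contacts tracked (default 5).
#' @param config featurization config supplying the contact cutoff.
#' @param stride_base,stride_crowded,crowded_above stride rules: every
#'   \code{stride_base}-th qualifying frame, or every
#'   \code{stride_crowded}-th when more than \code{crowded_above} qualify
#'   (defaults 10, 20, 7500).
#' @return integer frame indices (into the original ensemble); empty when
#'   nothing qualifies.
#' @export
extract_candidate_frames <- function(ensemble, diff, burn_in = 0,
                                     n_top = 5,
                                     config = featurization_config(),
                                     stride_base = 10, stride_crowded = 20,
                                     crowded_above = 7500) {
  tops <- top_changed_contacts(diff, n_top = n_top)
  if (nrow(tops$positive) == 0 && nrow(tops$negative) == 0)
    return(integer(0))
  n_frames <- length(ensemble$frames)
  frames_kept <- setdiff(seq_len(n_frames), seq_len(burn_in))
  if (!length(frames_kept)) return(integer(0))

  dtr <- pairwise_min_distances(ensemble, config)
  in_contact <- dtr$X < config$contact_map_cutoff   # frames x pairs
  pair_col <- function(p) which(dtr$pairs[, 1] == min(p) &
                                  dtr$pairs[, 2] == max(p))
  qual <- rep(FALSE, n_frames)
  if (nrow(tops$positive)) {
    cols <- apply(tops$positive, 1, pair_col)
    qual <- qual | apply(in_contact[, cols, drop = FALSE], 1, all)
  }
  if (nrow(tops$negative)) {
    cols <- apply(tops$negative, 1, pair_col)
    qual <- qual | apply(!in_contact[, cols, drop = FALSE], 1, all)
  }
  hits <- intersect(which(qual), frames_kept)
  if (!length(hits)) return(integer(0))
  stride <- if (length(hits) > crowded_above) stride_crowded else stride_base
  hits[seq(1, length(hits), by = stride)]
}

#' Expand a conformational cluster by RMSD
#'
#' Returns every \code{stride}-th frame of the full ensemble whose minimum
#' superposition RMSD to any cluster frame is below the threshold
#' (0.3 nm by default, the value that balances structural similarity
#' against false positives).
#'
#' @param cluster_frames list of n_atom x 3 matrices (nonempty).
#' @param all_frames list of n_atom x 3 matrices to scan.
#' @param threshold RMSD threshold in nm (default 0.3).
#' @param stride keep every \code{stride}-th scanned frame (default 10).
#' @param config a \code{superposition_config}.
#' @return integer indices into \code{all_frames}.
#' @export
expand_cluster_by_rmsd <- function(cluster_frames, all_frames,
                                   threshold = 0.3, stride = 10,
                                   config = superposition_config()) {
  stopifnot(length(cluster_frames) >= 1)
  scan <- as.integer(seq(1, length(all_frames), by = stride))
  keep <- vapply(scan, function(fi) {
    rmsds <- vapply(cluster_frames, function(cf)
      superpose_rmsd(all_frames[[fi]], cf, config), numeric(1))
    min(rmsds) < threshold
  }, logical(1))
  scan[keep]
}
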