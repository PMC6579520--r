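## Toy bead-chain structural ensembles with controllable residue contacts:
## the fixture generator for contact-map and RMSD operations. One bead per
## residue; coordinates in nm.

#' Build a bead-chain ensemble with a prescribed contact truth table
#'
#' Generates a two-condition structural ensemble of an n-residue bead chain
#' in which, under the 0.4 nm contact rule, \code{base_contacts} are formed
#' (and \code{perturbed_contacts} broken) in the base frames, and vice versa
#' in the perturbed frames; every other eligible residue pair stays out of
#' contact in all frames. Geometry is found by seeded penalty minimization
#' (target 0.30 nm for formed contacts, >= 0.55 nm for non-contacts,
#' 0.38 nm consecutive bonds); an unsatisfiable specification raises an
#' error after repeated restarts.
#'
#' @param n_residue number of beads.
#' @param base_contacts,perturbed_contacts 2-column matrices (or lists of
#'   pairs) of 1-based residue indices; every pair must satisfy the
#'   sequence-separation rule |i - j| >= 3.
#' @param n_frames_base,n_frames_perturbed frames per condition.
#' @param seed integer seed.
#' @param jitter_sd per-coordinate Gaussian jitter applied per frame
#'   (default 0.005 nm, small enough never to flip the contact rule).
#' @return object of class \code{bead_ensemble}: list with \code{frames}
#'   (list of n_residue x 3 matrices), \code{residue_ids},
#'   \code{condition} ("base"/"perturbed" per frame) and the contact spec.
#' @export
make_bead_chain_ensemble <- function(n_residue, base_contacts = NULL,
                                     perturbed_contacts = NULL,
                                     n_frames_base = 10,
                                     n_frames_perturbed = 0,
                                     seed = 1, jitter_sd = 0.005) {
  base_contacts <- as_pair_matrix(base_contacts)
  perturbed_contacts <- as_pair_matrix(perturbed_contacts)
  check_pairs <- function(p) {
    if (nrow(p) == 0) return(invisible())
    if (any(p < 1 | p > n_residue)) stop("contact pair index out of range")
    if (any(abs(p[, 1] - p[, 2]) < 3))
      stop("contact pairs must be separated in sequence by at least two ",
           "residues (|i - j| >= 3)")
  }
  check_pairs(base_contacts); check_pairs(perturbed_contacts)
  if (nrow(base_contacts) && nrow(perturbed_contacts)) {
    overlap <- intersect(
      paste(base_contacts[, 1], base_contacts[, 2]),
      paste(perturbed_contacts[, 1], perturbed_contacts[, 2]))
    if (length(overlap))
      stop("geometrically unsatisfiable contact specification: pair(s) ",
           paste(overlap, collapse = "; "),
           " required both formed and broken in the same frames")
  }

  base_geom <- solve_chain_geometry(n_residue, base_contacts,
                                    forbid = perturbed_contacts,
                                    seed = child_seed(seed, 1))
  pert_geom <- if (n_frames_perturbed > 0)
    solve_chain_geometry(n_residue, perturbed_contacts,
                         forbid = base_contacts,
                         seed = child_seed(seed, 2)) else NULL

  frames <- with_seed(child_seed(seed, 3), {
    c(
      lapply(seq_len(n_frames_base), function(i)
        base_geom + matrix(rnorm(3 * n_residue, sd = jitter_sd),
                           n_residue, 3)),
      lapply(seq_len(n_frames_perturbed), function(i)
        pert_geom + matrix(rnorm(3 * n_residue, sd = jitter_sd),
                           n_residue, 3))
    )
  })

  structure(list(
    frames = frames,
    residue_ids = seq_len(n_residue),
    condition = rep(c("base", "perturbed"),
                    c(n_frames_base, n_frames_perturbed)),
    base_contacts = base_contacts,
    perturbed_contacts = perturbed_contacts
  ), class = "bead_ensemble")
}

as_pair_matrix <- function(p) {
  if (is.null(p) || (is.matrix(p) && nrow(p) == 0))
    return(matrix(integer(), 0, 2))
  if (is.list(p)) p <- do.call(rbind, lapply(p, as.integer))
  p <- matrix(as.integer(p), ncol = 2)
  t(apply(p, 1, sort))                 # canonical i < j
}

## Penalty minimization over bead coordinates. Formed contacts are pulled to
## 0.30 nm, bonds to 0.38 nm, all other |i-j|>=2 pairs pushed beyond 0.55 nm
## (a margin over the 0.4 nm rule that per-frame jitter cannot erode).
solve_chain_geometry <- function(n_residue, contacts, forbid, seed,
                                 d_contact = 0.30, d_bond = 0.38,
                                 d_clear = 0.55, max_restarts = 25) {
  is_contact <- matrix(FALSE, n_residue, n_residue)
  if (nrow(contacts)) is_contact[contacts] <- TRUE
  is_contact <- is_contact | t(is_contact)

  penalty <- function(x) {
    X <- matrix(x, n_residue, 3)
    D <- as.matrix(stats::dist(X))
    p <- 0
    bd <- D[cbind(seq_len(n_residue - 1), seq_len(n_residue - 1) + 1L)]
    p <- p + sum((bd - d_bond)^2) * 50
    iu <- which(upper.tri(D), arr.ind = TRUE)
    sep <- iu[, 2] - iu[, 1]
    far <- sep >= 2 & !is_contact[iu]
    near <- is_contact[iu]
    dv <- D[iu]
    p <- p + sum(pmax(d_clear - dv[far], 0)^2) * 50
    p <- p + sum((dv[near] - d_contact)^2) * 50
    p
  }

  for (r in seq_len(max_restarts)) {
    x0 <- with_seed(child_seed(seed, r), {
      # start from a loose helix plus noise: bonded, mostly clear
      t <- seq_len(n_residue)
      cbind(0.45 * cos(t), 0.45 * sin(t), 0.12 * t) +
        matrix(rnorm(3 * n_residue, sd = 0.05), n_residue, 3)
    })
    opt <- stats::optim(as.vector(x0), penalty, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-12))
    X <- matrix(opt$par, n_residue, 3)
    if (chain_satisfies(X, is_contact, d_bond)) return(X)
  }
  stop("geometrically unsatisfiable contact specification")
}

chain_satisfies <- function(X, is_contact, d_bond, cutoff = 0.4,
                            clear_margin = 0.45, bond_tol = 0.08) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  bd <- D[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)]
  if (any(abs(bd - d_bond) > bond_tol)) return(FALSE)
  iu <- which(upper.tri(D), arr.ind = TRUE)
  sep <- iu[, 2] - iu[, 1]
  dv <- D[iu]
  ok_contact <- all(dv[is_contact[iu]] < cutoff - 0.05)
  ok_clear <- all(dv[sep >= 2 & !is_contact[iu]] > clear_margin)
  ok_contact && ok_clear
}

#' @export
print.bead_ensemble <- function(x, ...) {
  cat("Bead-chain ensemble:", length(x$residue_ids), "residues,",
      length(x$frames), "frames (",
      sum(x$condition == "base"), "base /",
      sum(x$condition == "perturbed"), "perturbed )\n")
  invisible(x)
}

#' Write a bead ensemble as a multi-model PDB file
#'
#' One CA pseudo-atom per bead, coordinates converted from nm to Angstrom,
#' one MODEL block per frame.
#'
#' @param ensemble a \code{bead_ensemble}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_bead_pdb <- function(ensemble, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(ensemble$frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    X <- ensemble$frames[[f]] * 10       # nm -> Angstrom
    for (i in seq_len(nrow(X))) {
      writeLines(sprintf(
        "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        i, i, X[i, 1], X[i, 2], X[i, 3]), con)
    }
    writeLines("ENDMDL", con)
  }
  invisible(path)
}
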