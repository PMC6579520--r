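## Microstate coverage across seed structures and simulation budgets:
## Venn-style set logic, trajectory-number x trajectory-length contour
## grids, minimal time to coverage, and new-state discovery curves.

visited_states <- function(dtrajs) sort(unique(unlist(dtrajs)))

#' Microstate coverage under set expressions
#'
#' Evaluates union/intersection/difference expressions over the
#' visited-state sets of labeled trajectory sets. The expression uses set
#' labels with the operators \code{|} (union), \code{&} (intersection) and
#' \code{-} (difference), e.g. \code{"(A | B) - C"}.
#'
#' @param dtraj_sets named list of \code{discrete_trajectory_set}s (or
#'   lists of integer vectors) with a common state space.
#' @param expression character set expression over the names.
#' @param n_total total number of microstates (default: max state across
#'   sets).
#' @return list of class \code{coverage_result}: \code{set_expression},
#'   \code{covered_states}, \code{n_covered}, \code{n_total}.
#' @export
coverage_by_sets <- function(dtraj_sets, expression, n_total = NULL) {
  sets <- lapply(dtraj_sets, function(d) {
    if (inherits(d, "discrete_trajectory_set")) d <- d$dtrajs
    visited_states(d)
  })
  if (is.null(n_total)) n_total <- max(unlist(sets))
  env <- new.env(parent = baseenv())
  for (nm in names(sets)) assign(nm, sets[[nm]], envir = env)
  assign("|", function(a, b) union(a, b), envir = env)
  assign("&", function(a, b) intersect(a, b), envir = env)
  assign("-", function(a, b) setdiff(a, b), envir = env)
  assign("(", function(x) x, envir = env)
  expr <- tryCatch(parse(text = expression)[[1]],
                   error = function(e) stop("unparsable set expression"))
  check_labels <- function(e) {
    if (is.name(e)) {
      if (!as.character(e) %in% names(sets))
        stop("unknown set label: ", as.character(e))
    } else if (is.call(e)) {
      op <- as.character(e[[1]])
      if (!op %in% c("|", "&", "-", "(")) stop("unsupported operator: ", op)
      for (a in as.list(e)[-1]) check_labels(a)
    }
  }
  check_labels(expr)
  covered <- sort(eval(expr, env))
  structure(list(set_expression = expression, covered_states = covered,
                 n_covered = length(covered), n_total = n_total),
            class = "coverage_result")
}

#' All Venn regions of labeled trajectory sets
#'
#' Enumerates every membership combination of the sets and counts the
#' microstates exclusive to each region.
#'
#' @param dtraj_sets named list as in \code{\link{coverage_by_sets}}.
#' @param n_total total microstates (default max observed).
#' @return data frame with one logical column per set, plus
#'   \code{n_states} per exclusive region (the all-FALSE row counts states
#'   never visited).
#' @export
venn_regions <- function(dtraj_sets, n_total = NULL) {
  sets <- lapply(dtraj_sets, function(d) {
    if (inherits(d, "discrete_trajectory_set")) d <- d$dtrajs
    visited_states(d)
  })
  if (is.null(n_total)) n_total <- max(unlist(sets))
  k <- length(sets)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  names(combos) <- names(sets)
  member <- vapply(sets, function(s) seq_len(n_total) %in% s, logical(n_total))
  combos$n_states <- apply(combos, 1, function(row)
    sum(apply(member, 1, function(m) all(m == as.logical(row)))))
  combos
}

#' Coverage contour over trajectory number and length
#'
#' For each grid point (number of trajectories, maximum trajectory
#' length), draws that many trajectories without replacement, truncates
#' them, counts distinct visited microstates, and averages over
#' \code{n_draws} draws. The grid axes step in \code{traj_step}
#' trajectories and \code{length_step} frames, mirroring how coverage is
#' mapped against simulation budget.
#'
#' @param dtrajs a \code{discrete_trajectory_set} or list of integer
#'   vectors (the pooled trajectory combination).
#' @param traj_step grid step in trajectory count (default 50).
#' @param length_step grid step in frames (default 50).
#' @param n_draws random draws averaged per grid point (default 5).
#' @param seed integer seed.
#' @param n_total total microstates (default max observed).
#' @return list of class \code{coverage_grid}: \code{grid} (matrix, rows =
#'   trajectory counts, cols = lengths, mean distinct states),
#'   \code{n_traj_axis}, \code{length_axis}, \code{n_total},
#'   \code{n_draws}.
#' @export
coverage_contour <- function(dtrajs, traj_step = 50, length_step = 50,
                             n_draws = 5, seed = 1, n_total = NULL) {
  if (inherits(dtrajs, "discrete_trajectory_set")) {
    if (is.null(n_total)) n_total <- dtrajs$n_states
    dtrajs <- dtrajs$dtrajs
  }
  if (is.null(n_total)) n_total <- max(unlist(dtrajs))
  n_pool <- length(dtrajs)
  if (!n_pool) stop("empty trajectory combination")
  max_len <- max(vapply(dtrajs, length, integer(1)))
  n_axis <- unique(c(seq(0, n_pool, by = traj_step), n_pool))
  l_axis <- unique(c(seq(0, max_len, by = length_step), max_len))

  G <- matrix(0, length(n_axis), length(l_axis),
              dimnames = list(n_axis, l_axis))
  for (d in seq_len(n_draws)) {
    perm <- with_seed(child_seed(seed, d), sample.int(n_pool))
    for (ni in seq_along(n_axis)) {
      nt <- n_axis[ni]
      if (nt == 0) next
      chosen <- dtrajs[perm[seq_len(nt)]]
      # count distinct states under each truncation in one pass per draw:
      # first-visit time of each state across the chosen trajectories
      first_visit <- rep(Inf, n_total)
      for (s in chosen) {
        fv <- match(seq_len(n_total), s)
        upd <- which(!is.na(fv) & fv < first_visit)
        first_visit[upd] <- fv[upd]
      }
      G[ni, ] <- G[ni, ] + vapply(l_axis, function(L)
        sum(first_visit <= L), numeric(1))
    }
  }
  structure(list(grid = G / n_draws, n_traj_axis = n_axis,
                 length_axis = l_axis, n_total = n_total,
                 n_draws = n_draws),
            class = "coverage_grid")
}

#' Minimal simulation budget to reach a coverage fraction
#'
#' Minimum of (number of trajectories x maximum length) over grid points
#' whose mean coverage reaches \code{fraction} of the total microstates.
#'
#' @param grid a \code{coverage_grid}.
#' @param fraction target coverage fraction in \[0, 1\].
#' @return minimal aggregate simulation budget in trajectory-frames, or
#'   \code{NA} with a warning when the fraction is never attained.
#' @export
minimal_time_to_coverage <- function(grid, fraction) {
  stopifnot(fraction >= 0, fraction <= 1)
  target <- fraction * grid$n_total
  budget <- outer(grid$n_traj_axis, grid$length_axis)
  ok <- grid$grid >= target
  if (!any(ok)) {
    warning("target coverage fraction never reached on the grid")
    return(NA_real_)
  }
  min(budget[ok])
}

#' New-state discovery curve of a query cohort
#'
#' Cumulative count of microstates first visited by the query cohort and
#' never visited by the reference cohort, as a function of aggregate
#' query simulation time. Trajectories contribute in the given order,
#' frame by frame.
#'
#' @param query_dtrajs,reference_dtrajs discrete trajectories on a joint
#'   discretization.
#' @param frame_time time per frame (default 1).
#' @return data frame with \code{time} (aggregate query time) and
#'   \code{n_new} (cumulative newly discovered states), one row per
#'   discovery event plus the endpoint.
#' @export
discovery_curve <- function(query_dtrajs, reference_dtrajs, frame_time = 1) {
  if (inherits(query_dtrajs, "discrete_trajectory_set"))
    query_dtrajs <- query_dtrajs$dtrajs
  if (inherits(reference_dtrajs, "discrete_trajectory_set"))
    reference_dtrajs <- reference_dtrajs$dtrajs
  ref <- visited_states(reference_dtrajs)
  concat <- unlist(query_dtrajs)
  fresh <- !(concat %in% ref) & !duplicated(concat)
  t_new <- which(fresh)
  data.frame(time = c(t_new, length(concat)) * frame_time,
             n_new = c(seq_along(t_new), length(t_new)))
}
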