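## Plain-text persistence of trajectory sets and discrete trajectories.

#' Write a trajectory set's features and group table
#'
#' Features go to one CSV per trajectory (\code{traj_<i>.csv}, one row per
#' frame) under \code{dir}; the group table (\code{traj_id, group_id}) to
#' \code{groups.csv}.
#'
#' @param ts a \code{trajectory_set} with features.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_trajectory_set <- function(ts, dir) {
  stopifnot(!is.null(ts$features))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(ts$features))
    utils::write.csv(ts$features[[i]],
                     file.path(dir, sprintf("traj_%04d.csv", i)),
                     row.names = FALSE)
  utils::write.csv(data.frame(traj_id = seq_along(ts$features),
                              group_id = ts$group_ids),
                   file.path(dir, "groups.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a trajectory set written by \code{write_trajectory_set}
#'
#' @param dir directory containing \code{traj_*.csv} and
#'   \code{groups.csv}.
#' @return a \code{trajectory_set} (features and group ids only).
#' @export
read_trajectory_set <- function(dir) {
  groups <- utils::read.csv(file.path(dir, "groups.csv"))
  features <- lapply(groups$traj_id, function(i)
    as.matrix(utils::read.csv(file.path(dir,
                                        sprintf("traj_%04d.csv", i)))))
  structure(list(features = features, group_ids = groups$group_id,
                 true_macro_paths = NULL, true_micro_paths = NULL,
                 step_time = 1),
            class = "trajectory_set")
}

#' Write discrete trajectories to CSV
#'
#' Long format: \code{traj_id, frame, state} (plus \code{group_id} when
#' available).
#'
#' @param dtrajs a \code{discrete_trajectory_set}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_dtrajs_csv <- function(dtrajs, path) {
  rows <- do.call(rbind, lapply(seq_along(dtrajs$dtrajs), function(i)
    data.frame(traj_id = i, frame = seq_along(dtrajs$dtrajs[[i]]),
               state = dtrajs$dtrajs[[i]],
               group_id = if (is.null(dtrajs$group_ids)) NA else
                 dtrajs$group_ids[i])))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read discrete trajectories from CSV
#'
#' @param path CSV written by \code{\link{write_dtrajs_csv}}.
#' @param n_states state-space size (default max observed).
#' @return a \code{discrete_trajectory_set}.
#' @export
read_dtrajs_csv <- function(path, n_states = NULL) {
  d <- utils::read.csv(path)
  ids <- sort(unique(d$traj_id))
  dtrajs <- lapply(ids, function(i)
    d$state[d$traj_id == i][order(d$frame[d$traj_id == i])])
  groups <- if (all(is.na(d$group_id))) NULL else
    vapply(ids, function(i) d$group_id[d$traj_id == i][1], d$group_id[1])
  discrete_trajectories(dtrajs, n_states = n_states, group_ids = groups)
}
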