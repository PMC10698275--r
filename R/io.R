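## File formats: trajectory / label / prediction / segment CSVs, YAML
## configs and JSON run manifests. All CSV dialects use 0-based frame
## indices and are round-trip stable.

#' Read trajectories from CSV
#'
#' Expects columns `traj_id, frame, x, y` with 0-based integer frames sorted
#' within each trajectory. In strict mode (default) a gap in the frame
#' numbering is an error naming the trajectory and frame; with
#' `strict = FALSE` gaps are filled by linear interpolation.
#'
#' @param path CSV file.
#' @param dt frame interval attached to every trajectory.
#' @param strict reject frame gaps instead of interpolating.
#' @return named list of `traj` objects (possibly empty, with a warning).
#' @export
read_trajectories <- function(path, dt = 1, strict = TRUE) {
  df <- utils::read.csv(path)
  need <- c("traj_id", "frame", "x", "y")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  if (nrow(df) == 0L) {
    warning("empty trajectory file: ", path)
    return(list())
  }
  if (any(!is.finite(df$x)) || any(!is.finite(df$y)))
    stop("non-finite coordinates in ", path)
  out <- lapply(split(df, df$traj_id), function(g) {
    if (is.unsorted(g$frame, strictly = TRUE))
      stop(sprintf("trajectory %s: frames not strictly increasing",
                   g$traj_id[1L]))
    gaps <- which(diff(g$frame) != 1L)
    if (length(gaps)) {
      if (strict)
        stop(sprintf("trajectory %s: frame gap after frame %d",
                     g$traj_id[1L], g$frame[gaps[1L]]))
      full <- seq(g$frame[1L], g$frame[nrow(g)])
      g <- data.frame(traj_id = g$traj_id[1L], frame = full,
                      x = stats::approx(g$frame, g$x, full)$y,
                      y = stats::approx(g$frame, g$y, full)$y)
    }
    trajectory(cbind(g$x, g$y), dt = dt, id = g$traj_id[1L])
  })
  out[order(names(out))]
}

#' Write trajectories to CSV
#'
#' @param trajs list of `traj` objects (ids default to the list position).
#' @param path output CSV.
#' @return the path, invisibly.
#' @export
write_trajectories <- function(trajs, path) {
  rows <- lapply(seq_along(trajs), function(i) {
    tr <- trajs[[i]]
    id <- if (is.null(tr$id)) i else tr$id
    data.frame(traj_id = id, frame = seq_len(n_steps(tr)) - 1L,
               x = tr$positions[, 1L], y = tr$positions[, 2L])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write per-step ground-truth labels to CSV
#' @param dataset list of `list(traj =, gt =)` pairs.
#' @param path output CSV (`traj_id, frame, D_true, alpha_true, model_tag`).
#' @return the path, invisibly.
#' @export
write_labels <- function(dataset, path) {
  rows <- lapply(seq_along(dataset), function(i) {
    d <- dataset[[i]]
    id <- if (is.null(d$traj$id)) i else d$traj$id
    data.frame(traj_id = id, frame = seq_along(d$gt$D) - 1L,
               D_true = d$gt$D, alpha_true = d$gt$alpha,
               model_tag = d$gt$model)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write pointwise profiles to the predictions CSV dialect
#' @param profiles list of [pointwise_profile()]s.
#' @param ids trajectory identifiers.
#' @param path output CSV (`traj_id, frame, value, target`).
#' @return the path, invisibly.
#' @export
write_predictions <- function(profiles, ids = seq_along(profiles), path) {
  rows <- lapply(seq_along(profiles), function(i)
    data.frame(traj_id = ids[i],
               frame = seq_along(profiles[[i]]$values) - 1L,
               value = profiles[[i]]$values,
               target = profiles[[i]]$target))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a segment table to CSV
#' @param segment_table a `segment_table` (or rbind of several).
#' @param path output CSV.
#' @return the path, invisibly.
#' @export
write_segments <- function(segment_table, path) {
  utils::write.csv(as.data.frame(segment_table), path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Every artifact directory gets a YAML manifest sufficient to regenerate
#' it: the configuration, the seed and the package version.
#'
#' @param path output YAML file.
#' @param config a configuration object (coerced to plain lists).
#' @param seed the seed used.
#' @return the path, invisibly.
#' @export
write_manifest <- function(path, config, seed) {
  yaml::write_yaml(list(
    package = "pointdiff",
    version = as.character(utils::packageVersion("pointdiff")),
    seed = seed,
    config = rapply(unclass(config), identity, how = "replace")), path)
  invisible(path)
}
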