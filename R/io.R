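# Trajectory serialization: a counts CSV (with the configuration echoed as a
# YAML comment header), an events CSV, and an optional JSON-lines file of
# agent snapshots.

#' Write a trajectory to disk
#'
#' Writes `<prefix>_counts.csv` (long-format alive counts and cumulative
#' deaths by cause, with the run configuration echoed as a `#`-prefixed YAML
#' header), `<prefix>_events.csv`, and, when agent snapshots were recorded,
#' `<prefix>_agents.jsonl` with one JSON object per agent per emit time
#' (`time_h`, `id`, `class`, `phenotype`, `x_um`, `y_um`, `diameter_um`).
#'
#' @param traj a `simTrajectory` from [runExperiment()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return (invisibly) the paths written.
#' @export
writeTrajectory <- function(traj, dir, prefix = "run") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  counts <- countsByPhenotype(traj)
  cpath <- file.path(dir, paste0(prefix, "_counts.csv"))
  header <- character(0)
  if (!is.null(traj$config)) {
    hdr <- c(traj$config, list(run_seed = traj$seed))
    header <- paste0("# ", strsplit(yaml::as.yaml(hdr), "\n")[[1]])
  }
  con <- file(cpath, "w")
  writeLines(header, con)
  utils::write.csv(counts, con, row.names = FALSE)
  close(con)
  paths <- c(paths, cpath)
  epath <- file.path(dir, paste0(prefix, "_events.csv"))
  utils::write.csv(traj$events, epath, row.names = FALSE)
  paths <- c(paths, epath)
  if (length(traj$snapshots)) {
    apath <- file.path(dir, paste0(prefix, "_agents.jsonl"))
    con <- file(apath, "w")
    times <- traj$summary$time_h
    for (k in seq_along(traj$snapshots)) {
      snap <- traj$snapshots[[k]]
      sp <- snap$space
      for (store in names(snap$stores)) {
        tab <- snap$stores[[store]]
        n <- tblN(tab)
        if (!n) next
        cls <- basename(store)
        row <- match(tab$id, sp$id)
        for (i in seq_len(n)) {
          writeLines(jsonlite::toJSON(list(
            time_h = times[k], id = tab$id[i], class = cls,
            phenotype = tab$phenotype[i],
            x_um = sp$x[row[i]], y_um = sp$y[row[i]],
            diameter_um = 2 * sp$radius[row[i]]), auto_unbox = TRUE), con)
        }
      }
    }
    close(con)
    paths <- c(paths, apath)
  }
  invisible(paths)
}

#' Read a counts CSV written by [writeTrajectory()]
#' @param path file path.
#' @return data.frame of counts (YAML header skipped).
#' @export
readTrajectoryCounts <- function(path) {
  utils::read.csv(path, comment.char = "#")
}
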