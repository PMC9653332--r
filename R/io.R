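# File output: trajectories, event logs, point-cloud snapshots, run bundles.
# CSV dialect: comma separator, '.' decimal, header row, UTF-8; a leading
# '#'-comment states the units (times min, lengths um, volumes um^3,
# forces pN, pressure Pa).

units_comment <- "# units: t min; lengths um; volumes um^3; forces pN; pressure Pa"

write_csv_units <- function(df, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(units_comment, con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_csv_units <- function(path) {
  read.csv(path, comment.char = "#")
}

#' Write a trajectory table to CSV
#' @param trajectory the per-tick observable table of a run
#' @param path output path
#' @return `path`, invisibly
#' @export
write_trajectory <- function(trajectory, path) {
  invisible(write_csv_units(trajectory, path))
}

#' Read a trajectory table written by [write_trajectory()]
#' @param path CSV path
#' @return data frame
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("no such trajectory file: ", path)
  read_csv_units(path)
}

#' Write the agents of a state as an ASCII PLY point cloud
#'
#' One vertex per agent with properties x, y, z, radius, type (0 cell,
#' 1 particle) and lumen id (-1 when unset); readable by ParaView and
#' common mesh tools.
#'
#' @param state a `sim_state`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_snapshot_ply <- function(state, path) {
  nc <- nrow(state$cells); np <- nrow(state$particles)
  n <- nc + np
  hdr <- c("ply", "format ascii 1.0",
           sprintf("comment lumensim snapshot t=%g min", state$t),
           sprintf("element vertex %d", n),
           "property float x", "property float y", "property float z",
           "property float radius", "property int type", "property int lumen",
           "end_header")
  cell_lines <- if (nc) sprintf("%.6g %.6g %.6g %.6g 0 %d",
    state$cells$x, state$cells$y, state$cells$z, state$cells$radius,
    ifelse(is.na(state$cells$lumen_id), -1L, state$cells$lumen_id)) else character(0)
  part_lines <- if (np) sprintf("%.6g %.6g %.6g %.6g 1 %d",
    state$particles$x, state$particles$y, state$particles$z,
    rep(state$config$R_p, np), state$particles$lumen_id) else character(0)
  writeLines(c(hdr, cell_lines, part_lines), path)
  invisible(path)
}

#' Write a complete run bundle to a directory
#'
#' Writes `trajectory.csv`, `lumen_obs.csv`, `volumetry.csv`, the event logs,
#' the resolved configuration (`config.yaml`, sufficient to replay the run)
#' and a final-state snapshot.
#'
#' @param sim a `lumen_sim` object
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_run <- function(sim, dir) {
  stopifnot(inherits(sim, "lumen_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trajectory(sim$trajectory, file.path(dir, "trajectory.csv"))
  if (!is.null(sim$lumen_obs))
    write_csv_units(sim$lumen_obs, file.path(dir, "lumen_obs.csv"))
  if (!is.null(sim$volumetry))
    write_csv_units(sim$volumetry, file.path(dir, "volumetry.csv"))
  for (ev in names(sim$events)) {
    if (!is.null(sim$events[[ev]]))
      write_csv_units(sim$events[[ev]], file.path(dir, paste0(ev, ".csv")))
  }
  write_config(sim$config, file.path(dir, "config.yaml"))
  write_snapshot_ply(sim$state, file.path(dir, "final_state.ply"))
  invisible(dir)
}
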