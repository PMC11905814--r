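# Interchange readers/writers. CSV dialect: comma-separated, UTF-8, dot
# decimal, mandatory header row. World-space mm everywhere at the file
# boundary; voxel space never crosses it except inside NIfTI.

#' Read / write a trajectory CSV
#'
#' Columns: `electrode_id`, `entry_x_mm`, `entry_y_mm`, `entry_z_mm`,
#' `target_x_mm`, `target_y_mm`, `target_z_mm`, and optional
#' `target_zone`, `approach`. Malformed input errors with the offending
#' row and column named; no partial object is returned.
#'
#' @param path File path.
#' @return `read_trajectories_csv` returns a trajectory data frame.
#' @export
read_trajectories_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.traj_cols[1:7], names(df))
  if (length(missing) > 0)
    stop(sprintf("trajectory CSV %s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")))
  for (col in .traj_cols[2:7]) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad) > 0)
      stop(sprintf("trajectory CSV %s: row %d, column %s: expected a finite number, got '%s'",
                   path, bad[1], col, df[[col]][bad[1]]))
    df[[col]] <- v
  }
  for (col in c("target_zone", "approach"))
    if (col %in% names(df)) df[[col]][!is.na(df[[col]]) & df[[col]] == ""] <- NA
  if (anyDuplicated(df$electrode_id))
    stop(sprintf("trajectory CSV %s: duplicated electrode_id '%s'",
                 path, df$electrode_id[duplicated(df$electrode_id)][1]))
  .as_traj_table(df)
}

#' @param trajectories Trajectory data frame.
#' @rdname read_trajectories_csv
#' @export
write_trajectories_csv <- function(trajectories, path) {
  trajectories <- .as_traj_table(trajectories)
  write.csv(trajectories[, intersect(.traj_cols, names(trajectories))],
            path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write / read an implantation plan as JSON
#'
#' The plan JSON carries the placements table, the pairwise spacing
#' matrix, and an echo of the constraints/config it was produced with.
#'
#' @param plan An `implantation_plan`.
#' @param path File path.
#' @export
write_plan_json <- function(plan, path) {
  obj <- list(placements = plan$placements,
              spacing = plan$spacing,
              constraints = unclass(plan$constraints),
              config = unclass(plan$config),
              backend = plan$backend)
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_plan_json
#' @export
read_plan_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  placements <- obj$placements
  spacing <- if (!is.null(obj$spacing) && length(obj$spacing) > 0)
    as.matrix(obj$spacing) else NULL
  if (!is.null(spacing)) {
    auto_ids <- placements$electrode_id[placements$status == "auto"]
    if (nrow(spacing) == length(auto_ids))
      dimnames(spacing) <- list(auto_ids, auto_ids)
  }
  structure(list(placements = placements, spacing = spacing,
                 constraints = do.call(plan_constraints, obj$constraints),
                 config = do.call(risk_config, obj$config),
                 backend = obj$backend),
            class = "implantation_plan")
}
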