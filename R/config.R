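#' Risk-score configuration
#'
#' Parameters of the vessel-proximity risk score: the safety margin
#' `d_min`, the risk margin `d_max`, and the number of nodes sampled
#' along each trajectory. The defaults (3 mm, 10 mm, 128 nodes) are the
#' standard planning settings; both margins are surgeon-adjustable.
#'
#' @param d_min Safety margin in mm (default 3). Trajectories whose minimum
#'   vessel distance falls below `d_min` score in the (1, 2] regime.
#' @param d_max Risk margin in mm (default 10). Distances at or beyond
#'   `d_max` contribute zero risk.
#' @param n_nodes Number of evenly spaced nodes sampled along the
#'   trajectory, endpoints included (default 128).
#' @return An object of class `risk_config`.
#' @export
#' @examples
#' cfg <- risk_config()
#' cfg$d_min
risk_config <- function(d_min = 3, d_max = 10, n_nodes = 128L) {
  stopifnot(is.numeric(d_min), is.numeric(d_max), is.numeric(n_nodes))
  if (!(d_min > 0 && d_max > d_min))
    stop("risk_config: need 0 < d_min < d_max")
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 2L) stop("risk_config: n_nodes must be >= 2")
  structure(list(d_min = as.numeric(d_min), d_max = as.numeric(d_max),
                 n_nodes = n_nodes),
            class = "risk_config")
}

#' @export
print.risk_config <- function(x, ...) {
  cat(sprintf("risk_config: d_min = %g mm, d_max = %g mm, n_nodes = %d\n",
              x$d_min, x$d_max, x$n_nodes))
  invisible(x)
}

#' Hard feasibility constraints for trajectory planning
#'
#' Thresholds applied to every candidate trajectory: the vessel safety
#' margin, the maximum drilling angle from the skull-surface normal, the
#' maximum intracranial length, and the minimum spacing between the
#' intracranial segments of distinct electrodes. `resolution` controls the
#' candidate lattice density (points per ellipsoid axis).
#'
#' `safety_margin` defaults to the risk score's `d_min` (3 mm). The other
#' defaults bracket typical adult SEEG practice (drilling angles around
#' 19--20 degrees from the normal and intracranial lengths around 54--56 mm)
#' and are all configurable.
#'
#' @param safety_margin Minimum allowed vessel distance in mm (default 3).
#' @param max_angle Maximum drilling angle from the outward skull normal,
#'   degrees (default 30).
#' @param max_length Maximum intracranial length in mm (default 90).
#' @param min_spacing Minimum distance between intracranial segments of
#'   different electrodes, mm (default 5).
#' @param resolution Candidate lattice points per ellipsoid axis (default 5).
#' @return An object of class `plan_constraints`.
#' @export
plan_constraints <- function(safety_margin = 3, max_angle = 30,
                             max_length = 90, min_spacing = 5,
                             resolution = 5L) {
  vals <- c(safety_margin, max_angle, max_length, min_spacing, resolution)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("plan_constraints: all thresholds must be finite and > 0")
  structure(list(safety_margin = as.numeric(safety_margin),
                 max_angle = as.numeric(max_angle),
                 max_length = as.numeric(max_length),
                 min_spacing = as.numeric(min_spacing),
                 resolution = as.integer(resolution)),
            class = "plan_constraints")
}

#' @export
print.plan_constraints <- function(x, ...) {
  cat(sprintf(paste0("plan_constraints: safety_margin = %g mm, max_angle = ",
                     "%g deg, max_length = %g mm, min_spacing = %g mm, ",
                     "resolution = %d\n"),
              x$safety_margin, x$max_angle, x$max_length, x$min_spacing,
              x$resolution))
  invisible(x)
}

# strict config reader used by the CLI; unknown keys are rejected
.read_tool_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("d_min", "d_max", "n_nodes", "safety_margin", "max_angle",
             "max_length", "min_spacing", "resolution", "k_sd",
             "outlier_threshold", "backend", "seed")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0)
    stop(sprintf("config %s: unknown key(s): %s", path,
                 paste(extra, collapse = ", ")))
  if (!is.null(cfg$backend) &&
      !cfg$backend %in% c("polyline", "distance_field"))
    stop(sprintf("config %s: backend must be 'polyline' or 'distance_field'",
                 path))
  cfg
}

.tool_config_objects <- function(cfg) {
  rc <- risk_config(d_min = cfg$d_min %||% 3, d_max = cfg$d_max %||% 10,
                    n_nodes = cfg$n_nodes %||% 128L)
  pc <- plan_constraints(
    safety_margin = cfg$safety_margin %||% rc$d_min,
    max_angle = cfg$max_angle %||% 30,
    max_length = cfg$max_length %||% 90,
    min_spacing = cfg$min_spacing %||% 5,
    resolution = cfg$resolution %||% 5L)
  list(risk = rc, constraints = pc,
       k_sd = cfg$k_sd %||% 1,
       outlier_threshold = cfg$outlier_threshold %||% 4,
       backend = cfg$backend %||% "distance_field",
       seed = cfg$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
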